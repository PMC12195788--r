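# Brute-force nearest-neighbour imputation oracle: for every cell of the
# item x month grid, scan all observed months of that item and take the value
# at minimal temporal distance, averaging the two neighbours on a tie.
# Independent of the package's impute_missing() internals.
nn_oracle <- function(panel, months) {
  out <- list()
  for (it in unique(panel$item)) {
    rows <- panel[panel$item == it, ]
    oym <- ym(rows$year, rows$month)
    for (m in months) {
      if (m %in% oym) {
        val <- rows$min_price[oym == m][1]
      } else {
        d <- abs(oym - m)
        val <- mean(rows$min_price[d == min(d)])
      }
      out[[length(out) + 1L]] <- data.frame(item = it, ym = m, min_price = val)
    }
  }
  do.call(rbind, out)
}

# random small monthly min-price panel with gaps (>= 1 observed month/item)
random_gappy_panel <- function(n_items, n_months, seed) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_items)) {
    keep <- which(runif(n_months) > 0.4)
    if (!length(keep)) keep <- sample.int(n_months, 1L)
    p <- round(runif(length(keep), 50, 500), 2)
    rows[[i]] <- data.frame(item = paste0("it", i),
                            year = 2020, month = keep,
                            min_price = p, mean_price = p * 1.1,
                            n_obs = 1L, status = "observed")
  }
  structure(do.call(rbind, rows), class = c("price_panel", "data.frame"))
}

# toy consumption records for one stratum
toy_records <- function(q, subgroup = "veg", stratum = "Q1") {
  data.frame(item = names(q), stratum = stratum, subgroup = subgroup,
             quantity_g = as.numeric(q))
}

# basket built from the packaged composition fixture
fixture_basket <- function() {
  t2 <- hsbfb_table2()
  fti <- data.frame(item = t2$item, subgroup = t2$subgroup, factor = t2$fti)
  build_basket(hsbfb_targets(), hsbfb_shares(), fti)
}
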