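#' Standardize item names and splice price segments across base years
#'
#' Consumer-price-index microdata arrive in segments, each collected under one
#' base-year item portfolio. This step (1) maps raw item labels to canonical
#' names and (2) links the segments into one continuous series per item by
#' ratio splicing: within each pair of chronologically adjacent segments, the
#' later segment is authoritative, and every price of the earlier segment is
#' rescaled by the ratio of the two segments' monthly mean prices over their
#' overlap months. Segments are chained pairwise from the latest backwards, so
#' the whole series ends up on the latest segment's level. Earlier-segment
#' observations in overlap months are dropped (the later segment wins); an
#' item with no overlap in a pair is passed through unscaled.
#'
#' @param obs data frame of price observations
#'   (`item, year, month, price, segment, obs_id`); if a `name_map` is given
#'   the raw labels are expected in `item_raw` (or `item`, which is then
#'   treated as raw).
#' @param name_map optional data frame `raw, canonical`. Raw labels without a
#'   mapping are dropped with a warning and reported in the `rejected`
#'   attribute of the result — never silently.
#' @return the observation data frame with spliced prices, ordered by item and
#'   month; attributes `rejected` (character) and `splice_ratios` (data frame
#'   `segment, item, ratio`).
#' @examples
#' obs <- data.frame(item = "a", year = 2013, month = c(1, 2, 2, 3),
#'                   price = c(100, 100, 110, 112),
#'                   segment = c("s1", "s1", "s2", "s2"),
#'                   obs_id = 1:4)
#' standardize_and_splice(obs)  # s1 prices rescaled by 110/100
#' @export
standardize_and_splice <- function(obs, name_map = NULL) {
  rejected <- character()
  if (!is.null(name_map)) {
    stopifnot(all(c("raw", "canonical") %in% names(name_map)))
    raw <- if ("item_raw" %in% names(obs)) obs$item_raw else obs$item
    canon <- name_map$canonical[match(raw, name_map$raw)]
    rejected <- sort(unique(raw[is.na(canon)]))
    if (length(rejected)) {
      warning("unmapped raw item label(s) rejected: ",
              paste(rejected, collapse = ", "))
    }
    obs <- obs[!is.na(canon), , drop = FALSE]
    obs$item <- canon[!is.na(canon)]
  }
  stopifnot(all(c("item", "year", "month", "price", "segment") %in% names(obs)))
  if (!"obs_id" %in% names(obs)) obs$obs_id <- seq_len(nrow(obs))
  obs$.ym <- ym(obs$year, obs$month)

  seg_end <- tapply(obs$.ym, obs$segment, max)
  seg_order <- names(sort(seg_end))     # chronological, latest last
  n_seg <- length(seg_order)
  ratios <- NULL

  if (n_seg > 1L) {
    # Chain backwards. The later segment's prices in `obs` have already been
    # brought to the final (latest-segment) level by previous iterations, so
    # the pair ratio computed against them is directly the cumulative scale.
    for (i in seq(n_seg - 1L, 1L)) {
      earlier <- seg_order[i]; later <- seg_order[i + 1L]
      e <- obs[obs$segment == earlier, ]
      l <- obs[obs$segment == later, ]
      items_e <- unique(e$item)
      scale_this <- stats::setNames(rep(1, length(items_e)), items_e)
      for (it in items_e) {
        em <- e[e$item == it, ]; lm <- l[l$item == it, ]
        common <- intersect(em$.ym, lm$.ym)
        if (length(common)) {
          scale_this[[it]] <-
            mean(tapply(lm$price[lm$.ym %in% common], lm$.ym[lm$.ym %in% common], mean)) /
            mean(tapply(em$price[em$.ym %in% common], em$.ym[em$.ym %in% common], mean))
          # later segment authoritative in overlap months
          drop <- obs$segment == earlier & obs$item == it & obs$.ym %in% common
          obs <- obs[!drop, , drop = FALSE]
        }
        ratios <- rbind(ratios, data.frame(segment = earlier, item = it,
                                           ratio = unname(scale_this[[it]])))
      }
      sel <- obs$segment == earlier
      obs$price[sel] <- obs$price[sel] * scale_this[obs$item[sel]]
    }
  }
  obs <- obs[order(obs$item, obs$.ym, obs$obs_id), ]
  obs$.ym <- NULL
  rownames(obs) <- NULL
  attr(obs, "rejected") <- rejected
  attr(obs, "splice_ratios") <- ratios
  obs
}

#' Flag price observations outside an admissible range
#'
#' Screens each observation against an item's admissible price range. Where an
#' explicit range (from reference guides such as national agricultural price
#' monitors) is available it is used directly; otherwise a robust self-range
#' is derived from the item's own series: median +/- `k` * MAD over a rolling
#' window of `window` months centred on the observation's month. Flagged
#' observations get `status = "corrected"` and are excluded from downstream
#' monthly statistics; nothing is deleted.
#'
#' @param obs observation data frame (`item, year, month, price`, ...).
#' @param ranges optional data frame `item, low, high`.
#' @param k robust-range width in MAD units (default 5).
#' @param window rolling window length in months for the self-range
#'   (default 12).
#' @param fallback use the robust self-range for items without an explicit
#'   range (default TRUE). With `ranges = NULL` and `fallback = FALSE` the
#'   call errors.
#' @return `obs` with a `status` column (`"observed"`/`"corrected"`) and an
#'   `n_flagged` attribute.
#' @examples
#' obs <- data.frame(item = "a", year = 2020, month = c(1, 1, 1),
#'                   price = c(100, 102, 5000))
#' screen_outliers(obs, ranges = data.frame(item = "a", low = 50, high = 500))
#' @export
screen_outliers <- function(obs, ranges = NULL, k = 5, window = 12,
                            fallback = TRUE) {
  stopifnot(all(c("item", "year", "month", "price") %in% names(obs)))
  if (is.null(ranges) && !fallback) {
    stop("no admissible-range table and fallback disabled")
  }
  flag <- rep(FALSE, nrow(obs))
  ymx <- ym(obs$year, obs$month)
  has_range <- if (!is.null(ranges)) obs$item %in% ranges$item else rep(FALSE, nrow(obs))

  if (any(has_range)) {
    i <- match(obs$item, ranges$item)
    flag[has_range] <- obs$price[has_range] < ranges$low[i[has_range]] |
      obs$price[has_range] > ranges$high[i[has_range]]
  }
  todo <- which(!has_range)
  if (length(todo) && fallback) {
    half <- window %/% 2
    for (it in unique(obs$item[todo])) {
      sel <- which(obs$item == it & !has_range)
      p <- obs$price[sel]; m <- ymx[sel]
      for (mm in unique(m)) {
        win <- p[m >= mm - half & m <= mm + half]
        med <- stats::median(win)
        s <- stats::mad(win)
        cur <- sel[m == mm]
        flag[cur] <- abs(obs$price[cur] - med) > k * s
      }
    }
  }
  obs$status <- ifelse(flag, "corrected", "observed")
  attr(obs, "n_flagged") <- sum(flag)
  obs
}

#' Monthly mean and minimum prices per item
#'
#' Collapses screened observations to one row per item-month with the mean
#' price over retained observations, the lowest observed price (the costing
#' basis used for official basic-basket pricing), and the number of retained
#' observations. Observations flagged `corrected` by [screen_outliers()] are
#' excluded.
#'
#' @param obs observation data frame, optionally carrying a `status` column.
#' @return a `price_panel`: data frame
#'   `item, year, month, min_price, mean_price, n_obs, status` with
#'   `status = "observed"` throughout (imputation adds other statuses).
#' @export
monthly_stats <- function(obs) {
  stopifnot(all(c("item", "year", "month", "price") %in% names(obs)))
  if ("status" %in% names(obs)) obs <- obs[obs$status != "corrected", , drop = FALSE]
  if (nrow(obs) == 0L) stop("no retained observations")
  key <- list(item = obs$item, ym = ym(obs$year, obs$month))
  out <- stats::aggregate(obs$price, by = key, FUN = mean)
  names(out)[3] <- "mean_price"
  out$min_price <- stats::aggregate(obs$price, by = key, FUN = min)$x
  out$n_obs <- stats::aggregate(obs$price, by = key, FUN = length)$x
  out$year <- ym_year(out$ym); out$month <- ym_month(out$ym)
  out$status <- "observed"
  out <- out[order(out$item, out$ym),
             c("item", "year", "month", "min_price", "mean_price", "n_obs", "status")]
  rownames(out) <- NULL
  structure(out, class = c("price_panel", "data.frame"))
}

#' Fill missing item-months by nearest-neighbour imputation
#'
#' Completes the item x month grid over a closed analysis window. A missing
#' cell is filled, by default, with the value of the temporally nearest
#' observed month of the same item; an exact tie between the two sides is
#' resolved by averaging the two neighbours. Filled cells get
#' `status = "imputed"` and `n_obs = 0`; observed cells are never altered, so
#' imputing an already-complete panel is the identity.
#'
#' `method = "donor"` instead borrows the month's value from the donor item
#' whose min-price profile correlates best with the target item over their
#' common observed months, rescaled by the ratio of the two items' mean
#' levels over those months (falling back to temporal imputation when no
#' usable donor exists).
#'
#' @param panel a `price_panel` from [monthly_stats()].
#' @param start,end analysis window bounds, `"YYYY-MM"` strings or [ym()]
#'   indices (defaults: the panel's own range).
#' @param method `"temporal"` (default) or `"donor"`.
#' @return a `price_panel` covering every item-month of the window.
#' @examples
#' p <- monthly_stats(data.frame(item = "a", year = 2020, month = c(1, 3),
#'                               price = c(100, 120)))
#' impute_missing(p, "2020-01", "2020-03")  # Feb = 110 (tie -> mean)
#' @export
impute_missing <- function(panel, start = NULL, end = NULL,
                           method = c("temporal", "donor")) {
  method <- match.arg(method)
  stopifnot(inherits(panel, "data.frame"),
            all(c("item", "year", "month", "min_price", "mean_price") %in% names(panel)))
  pym <- ym(panel$year, panel$month)
  start <- if (is.null(start)) min(pym) else as_ym(start)
  end <- if (is.null(end)) max(pym) else as_ym(end)
  months <- ym_seq(start, end)
  items <- unique(panel$item)

  none <- items[!items %in% panel$item[!is.na(panel$min_price)]]
  if (length(none)) stop("item(s) with zero observations: ",
                         paste(none, collapse = ", "))

  fill_one <- function(it) {
    rows <- panel[panel$item == it, , drop = FALSE]
    oym <- ym(rows$year, rows$month)
    miss <- setdiff(months, oym)
    keep <- rows[oym >= start & oym <= end, , drop = FALSE]
    if (!length(miss)) return(keep)
    imp <- data.frame(item = it, year = ym_year(miss), month = ym_month(miss),
                      min_price = NA_real_, mean_price = NA_real_,
                      n_obs = 0L, status = "imputed")
    for (j in seq_along(miss)) {
      d <- abs(oym - miss[j])
      near <- which(d == min(d))
      if (method == "donor") {
        v <- donor_value(panel, it, miss[j])
        if (!is.null(v)) {
          imp$min_price[j] <- v["min_price"]; imp$mean_price[j] <- v["mean_price"]
          next
        }
      }
      imp$min_price[j] <- mean(rows$min_price[near])
      imp$mean_price[j] <- mean(rows$mean_price[near])
    }
    rbind(keep, imp)
  }
  out <- do.call(rbind, lapply(items, fill_one))
  out <- out[order(out$item, ym(out$year, out$month)), ]
  rownames(out) <- NULL
  structure(out, class = c("price_panel", "data.frame"))
}

# donor-item imputation: most-correlated item observed in the target month
donor_value <- function(panel, it, target_ym) {
  pym <- ym(panel$year, panel$month)
  self <- panel[panel$item == it, ]
  self_ym <- pym[panel$item == it]
  best <- NULL; best_cor <- -Inf
  for (other in setdiff(unique(panel$item), it)) {
    o <- panel[panel$item == other, ]
    o_ym <- pym[panel$item == other]
    if (!target_ym %in% o_ym) next
    common <- intersect(self_ym, o_ym)
    if (length(common) < 3L) next
    a <- self$min_price[match(common, self_ym)]
    b <- o$min_price[match(common, o_ym)]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    r <- stats::cor(a, b)
    if (!is.na(r) && r > best_cor) {
      scale <- mean(a) / mean(b)
      best_cor <- r
      best <- c(min_price = o$min_price[match(target_ym, o_ym)] * scale,
                mean_price = o$mean_price[match(target_ym, o_ym)] * scale)
    }
  }
  best
}

#' @export
print.price_panel <- function(x, ...) {
  n_imp <- sum(x$status == "imputed")
  cat(sprintf("Price panel: %d items x %d months (%d cells, %d imputed)\n",
              length(unique(x$item)),
              length(unique(ym(x$year, x$month))), nrow(x), n_imp))
  print(utils::head(as.data.frame(x), 10), row.names = FALSE, ...)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}
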