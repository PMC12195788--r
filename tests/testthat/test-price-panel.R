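mk_obs <- function(item, ym_month_pairs, price, segment) {
  data.frame(item = item, year = ym_month_pairs$year, month = ym_month_pairs$month,
             price = price, segment = segment)
}

test_that("ratio splicing links segments onto the latest level", {
  # identical prices in the overlap month: ratio 1, series unchanged
  obs <- data.frame(item = "a", year = 2013, month = c(1, 2, 2, 3),
                    price = c(90, 100, 100, 105),
                    segment = c("s1", "s1", "s2", "s2"), obs_id = 1:4)
  out <- standardize_and_splice(obs)
  expect_equal(sort(out$price), c(90, 100, 105))

  # overlap means 100 (earlier) vs 110 (later): earlier scaled by 1.10
  obs$price <- c(90, 100, 110, 112)
  out <- standardize_and_splice(obs)
  expect_equal(out$price[out$month == 1], 99)           # 90 * 1.1
  expect_equal(out$price[out$month == 2], 110)          # later authoritative
  expect_equal(nrow(out), 3)                            # earlier overlap row dropped

  # unmapped raw labels are rejected loudly, never silently
  obs2 <- data.frame(item = c("tomate", "zz"), year = 2013, month = 1,
                     price = c(10, 20), segment = "s1")
  nm <- data.frame(raw = "tomate", canonical = "Tomatoes")
  expect_warning(out2 <- standardize_and_splice(obs2, name_map = nm), "zz")
  expect_identical(attr(out2, "rejected"), "zz")
  expect_identical(out2$item, "Tomatoes")
})

test_that("three segments chain pairwise like sequential two-segment splices", {
  seg <- function(months, price, label) {
    data.frame(item = "a", year = 2013, month = months, price = price,
               segment = label)
  }
  s1 <- seg(1:4, c(100, 100, 100, 100), "s1")
  s2 <- seg(4:8, c(110, 112, 114, 116, 118), "s2")
  s3 <- seg(8:12, c(130, 131, 132, 133, 134), "s3")

  all3 <- standardize_and_splice(rbind(s1, s2, s3))
  # oracle: two sequential two-segment splices, latest pair first (the later
  # segment is authoritative, so chaining runs backwards from it)
  step1 <- standardize_and_splice(rbind(s2, s3))
  step1$obs_id <- NULL
  step2 <- standardize_and_splice(rbind(s1, step1))
  expect_equal(all3$price[order(all3$month)], step2$price[order(step2$month)],
               tolerance = 1e-12)
  # continuity: every month present exactly once, on the latest level
  expect_equal(sort(all3$month), 1:12)
  expect_equal(all3$price[all3$month == 8], 130)
})

test_that("admissible-range screening flags without deleting", {
  obs <- data.frame(item = "a", year = 2020, month = 1, price = c(100, 102, 5000))
  rng <- data.frame(item = "a", low = 50, high = 500)
  out <- screen_outliers(obs, ranges = rng)
  expect_equal(out$status, c("observed", "observed", "corrected"))
  expect_equal(nrow(out), 3)
  expect_equal(attr(out, "n_flagged"), 1)

  # all within range: identity
  out2 <- screen_outliers(obs[1:2, ], ranges = rng)
  expect_equal(attr(out2, "n_flagged"), 0)

  expect_error(screen_outliers(obs, ranges = NULL, fallback = FALSE),
               "fallback disabled")
})

test_that("reference-range screening separates injected 10x outliers exactly", {
  cfg <- sim_config(seed = 21, start = c(2019L, 1L), end = c(2021L, 12L),
                    segment_breaks = list())
  pp <- gen_price_panel(cfg)
  scr <- screen_outliers(pp$observations, ranges = reference_ranges(cfg))
  flagged <- pp$observations$obs_id[scr$status == "corrected"]
  truth <- pp$truth$outlier_obs_id
  expect_gte(mean(truth %in% flagged), 0.95)          # recall
  expect_length(setdiff(flagged, truth), 0)           # no false removals
})

test_that("the MAD fallback screen catches 10x outliers with a rare false-flag rate", {
  # without reference ranges the screen falls back to median +/- 5*MAD over a
  # rolling year; seasonal swing inside the window makes a handful of 5-MAD
  # noise exceedances unavoidable, so the false-flag rate is bounded, not zero
  cfg <- sim_config(seed = 21, start = c(2019L, 1L), end = c(2021L, 12L),
                    segment_breaks = list())
  pp <- gen_price_panel(cfg)
  scr <- screen_outliers(pp$observations)
  flagged <- pp$observations$obs_id[scr$status == "corrected"]
  truth <- pp$truth$outlier_obs_id
  expect_gte(mean(truth %in% flagged), 0.95)
  expect_lt(length(setdiff(flagged, truth)) / nrow(pp$observations), 1e-3)
})

test_that("monthly stats collapse to mean, min and count per item-month", {
  obs <- data.frame(item = "a", year = 2020, month = 1, price = c(100, 102, 98))
  p <- monthly_stats(obs)
  expect_equal(p$mean_price, 100)
  expect_equal(p$min_price, 98)
  expect_equal(p$n_obs, 3L)

  single <- monthly_stats(data.frame(item = "a", year = 2020, month = 2, price = 77))
  expect_equal(single$mean_price, single$min_price)

  # min <= mean on any panel, against direct recomputation
  set.seed(5)
  obs <- data.frame(item = sample(letters[1:4], 200, TRUE),
                    year = 2020, month = sample(1:12, 200, TRUE),
                    price = runif(200, 10, 100))
  p <- monthly_stats(obs)
  expect_true(all(p$min_price <= p$mean_price))
  one <- obs[obs$item == "b" & obs$month == 3, "price"]
  expect_equal(p$mean_price[p$item == "b" & p$month == 3], mean(one))
})

test_that("temporal imputation fills gaps with the nearest month, averaging ties", {
  p <- monthly_stats(data.frame(item = "a", year = 2020, month = c(1, 3),
                                price = c(100, 120)))
  out <- impute_missing(p, ym(2020, 1), ym(2020, 3))
  expect_equal(out$min_price[out$month == 2], 110)     # tie -> mean
  expect_equal(out$status, c("observed", "imputed", "observed"))

  p2 <- monthly_stats(data.frame(item = "a", year = 2020, month = c(1, 4),
                                 price = c(100, 130)))
  out2 <- impute_missing(p2, ym(2020, 1), ym(2020, 4))
  expect_equal(out2$min_price, c(100, 100, 130, 130))

  # complete panel: identity
  full <- monthly_stats(data.frame(item = "a", year = 2020, month = 1:3,
                                   price = c(1, 2, 3)))
  expect_equal(as.data.frame(impute_missing(full)), as.data.frame(full))

  # an item with no observations cannot be imputed
  bad <- full
  bad$min_price[bad$item == "a"] <- NA
  expect_error(impute_missing(bad), "a")
})

test_that("imputation matches the exhaustive nearest-neighbour oracle on small panels", {
  months <- ym_seq(ym(2020, 1), ym(2020, 12))
  for (seed in 1:12) {
    n_items <- (seed %% 5) + 1
    panel <- random_gappy_panel(n_items, 12, seed = 1000 + seed)
    got <- impute_missing(panel, months[1], months[12])
    want <- nn_oracle(panel, months)
    key <- paste(got$item, ym(got$year, got$month))
    expect_equal(got$min_price[order(key)],
                 want$min_price[order(paste(want$item, want$ym))],
                 tolerance = 1e-12)
    # provenance conservation: every cell observed xor imputed
    expect_equal(nrow(got), n_items * 12)
    expect_true(all(got$status %in% c("observed", "imputed")))
    expect_equal(sum(got$status == "observed") + sum(got$status == "imputed"),
                 n_items * 12)
  }
})

test_that("donor-based imputation tracks a correlated item's profile", {
  base <- c(100, 110, 120, 130, 140, 150)
  p <- rbind(
    data.frame(item = "a", year = 2020, month = c(1, 2, 3, 5, 6),
               min_price = 2 * base[c(1, 2, 3, 5, 6)],
               mean_price = 2 * base[c(1, 2, 3, 5, 6)], n_obs = 1L,
               status = "observed"),
    data.frame(item = "b", year = 2020, month = 1:6, min_price = base,
               mean_price = base, n_obs = 1L, status = "observed"))
  out <- impute_missing(structure(p, class = c("price_panel", "data.frame")),
                        ym(2020, 1), ym(2020, 6), method = "donor")
  filled <- out$min_price[out$item == "a" & out$month == 4]
  expect_equal(filled, 2 * base[4], tolerance = 0.01)
})

test_that("the decade analysis window spans 117 calendar months", {
  expect_length(ym_seq(ym_parse("2014-04"), ym_parse("2023-12")), 117)
  # closed-interval window arithmetic: 12*(years-1) + 9 for an April start
  expect_length(ym_seq(ym_parse("2020-04"), ym_parse("2021-12")), 21)
  expect_error(ym_seq(ym_parse("2022-01"), ym_parse("2021-12")), "after")
})
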