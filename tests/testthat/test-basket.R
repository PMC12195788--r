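test_that("shares are purchase-mass proportions with filtering and renormalization", {
  sh <- compute_group_shares(toy_records(c(A = 30, B = 70)), "Q1")
  expect_equal(sh$share[sh$item == "A"], 0.30)
  expect_equal(sh$share[sh$item == "B"], 0.70)

  expect_equal(compute_group_shares(toy_records(c(A = 100)), "Q1")$share, 1.0)

  # min_share drops and renormalizes
  sh <- compute_group_shares(toy_records(c(A = 90, B = 8, C = 2)), "Q1",
                             min_share = 0.05)
  expect_setequal(sh$item, c("A", "B"))
  expect_equal(sum(sh$share), 1)
  expect_equal(sh$share[sh$item == "A"], 90 / 98)

  # cumulative-coverage cutoff keeps the dominant items only
  sh <- compute_group_shares(toy_records(c(A = 60, B = 30, C = 10)), "Q1",
                             coverage = 0.9)
  expect_setequal(sh$item, c("A", "B"))
  expect_equal(sum(sh$share), 1)

  expect_error(compute_group_shares(toy_records(c(A = 1)), "Q9"),
               "stratum not found")

  # expenditure-weighted shares via the weight switch
  rec <- toy_records(c(A = 30, B = 70))
  rec$spend <- c(80, 20)
  she <- compute_group_shares(rec, "Q1", weight = "spend")
  expect_equal(she$share[she$item == "A"], 0.8)
})

test_that("unmapped items and marginal subgroups are excluded with a trace", {
  rec <- rbind(toy_records(c(A = 50, B = 50)),
               data.frame(item = "mystery", stratum = "Q1", subgroup = NA,
                          quantity_g = 10))
  expect_warning(sh <- compute_group_shares(rec, "Q1"), "mystery")
  expect_setequal(sh$item, c("A", "B"))

  # a subgroup with marginal total mass yields an empty share set
  rec <- rbind(toy_records(c(A = 5000, B = 5000), subgroup = "veg"),
               toy_records(c(N = 0.5), subgroup = "nuts"))
  sh <- compute_group_shares(rec, "Q1")
  expect_false("nuts" %in% sh$subgroup)
  expect_identical(attr(sh, "excluded_subgroups"), "nuts")

  # all-zero quantities behave the same way
  rec <- rbind(toy_records(c(A = 10), subgroup = "veg"),
               toy_records(c(N = 0), subgroup = "nuts"))
  sh <- compute_group_shares(rec, "Q1")
  expect_identical(attr(sh, "excluded_subgroups"), "nuts")
})

test_that("allocation distributes the gram target in proportion and conserves it", {
  tg <- data.frame(group = "g", subgroup = "veg", grams_per_day = 200)
  sh <- data.frame(subgroup = "veg", item = c("A", "B"), share = c(0.3, 0.7))
  al <- allocate_group_target(tg, sh)
  expect_equal(al$grams_consume, c(140, 60))  # ordered by share, descending
  expect_equal(sum(al$grams_consume), 200)

  one <- allocate_group_target(data.frame(subgroup = "s", grams_per_day = 100),
                               data.frame(subgroup = "s", item = "x", share = 1))
  expect_equal(one$grams_consume, 100)

  expect_error(allocate_group_target(
    data.frame(subgroup = "s", grams_per_day = -1),
    data.frame(subgroup = "s", item = "x", share = 1)), "negative")

  # conservation over random share vectors
  set.seed(42)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    s <- rgamma(k, 1); s <- s / sum(s)
    tgt <- runif(1, 1, 500)
    al <- allocate_group_target(
      data.frame(subgroup = "s", grams_per_day = tgt),
      data.frame(subgroup = "s", item = paste0("i", 1:k), share = s))
    expect_equal(sum(al$grams_consume), tgt, tolerance = 1e-12)
  }
})

test_that("FTI converts consumed to purchased grams with the right direction", {
  expect_equal(round(apply_fti(100, 1.04), 2), 96.15)
  expect_equal(round(apply_fti(28.14, 2.5), 2), 11.26)
  expect_equal(apply_fti(77.3, 1), 77.3)

  set.seed(7)
  g <- runif(50, 1, 300)
  f <- runif(50, 0.2, 3)
  out <- apply_fti(g, f)
  expect_true(all(sign(out - g) == sign(1 - f) | f == 1))

  expect_error(apply_fti(10, 0, item = "broken"), "broken")
  expect_error(apply_fti(10, -1), "> 0")
})

test_that("shares respond monotonically to quantities and ignore common scaling", {
  set.seed(11)
  for (i in 1:10) {
    q <- runif(5, 1, 100); names(q) <- paste0("i", 1:5)
    sh0 <- compute_group_shares(toy_records(q), "Q1")
    q2 <- q; q2["i3"] <- q2["i3"] * 1.5
    sh1 <- compute_group_shares(toy_records(q2), "Q1")
    m <- merge(sh0, sh1, by = "item")
    expect_gte(m$share.y[m$item == "i3"], m$share.x[m$item == "i3"])
    expect_true(all(m$share.y[m$item != "i3"] <= m$share.x[m$item != "i3"] + 1e-12))
    # scale invariance
    shk <- compute_group_shares(toy_records(q * 37.5), "Q1")
    expect_equal(shk$share, sh0$share, tolerance = 1e-12)
  }
})

test_that("build_basket reproduces the packaged composition table", {
  b <- fixture_basket()
  t2 <- hsbfb_table2()
  m <- merge(as.data.frame(b), t2, by = c("subgroup", "item"))
  expect_equal(nrow(m), nrow(t2))
  expect_lt(max(abs(m$grams_purchase - m$grams_purchase_printed)), 0.02)

  tot <- summary(b)
  total_of <- function(s) tot$grams_purchase[tot$subgroup == s]
  expect_equal(total_of("All Types of Vegetables"), 369.85, tolerance = 0.02 / 369.85)
  expect_equal(total_of("Rice, Wheat, Corn, and Others"), 223.02, tolerance = 0.02 / 223)
  expect_equal(total_of("All Types of Fruits"), 411.85, tolerance = 0.02 / 411.85)
  expect_equal(total_of("Legumes"), 68.54, tolerance = 0.02 / 68.54)
  # consumed totals conserve the targets exactly
  tg <- hsbfb_targets()
  m2 <- merge(tot, tg, by = "subgroup")
  expect_equal(m2$grams_consume, m2$grams_per_day, tolerance = 1e-9)
})

test_that("build_basket edge behavior: duplicates, missing FTI, identity factors, round-trip", {
  tg <- data.frame(group = "g", subgroup = "s", grams_per_day = 100)
  sh <- data.frame(subgroup = "s", item = c("a", "a"), share = c(0.5, 0.5))
  fti <- data.frame(item = "a", factor = 1)
  expect_error(build_basket(tg, sh, fti), "duplicate")

  sh <- data.frame(subgroup = "s", item = c("a", "b"), share = c(0.5, 0.5))
  expect_warning(b <- build_basket(tg, sh, fti), "b")
  expect_equal(b$fti[b$item == "b"], 1)

  # all factors 1: purchased totals equal the targets
  t2 <- hsbfb_table2()
  fti1 <- data.frame(item = t2$item, subgroup = t2$subgroup, factor = 1)
  b1 <- build_basket(hsbfb_targets(), hsbfb_shares(), fti1)
  tot <- summary(b1)
  tg <- hsbfb_targets()
  m <- merge(tot, tg, by = "subgroup")
  expect_equal(m$grams_purchase, m$grams_per_day, tolerance = 1e-9)

  # round-trip: rebuilding from the emitted table reproduces itself
  b <- fixture_basket()
  sh2 <- b[, c("subgroup", "item", "share")]
  fti2 <- b[, c("subgroup", "item", "fti")]
  names(fti2)[3] <- "factor"
  b2 <- build_basket(hsbfb_targets(), sh2, fti2)
  expect_equal(as.data.frame(b2), as.data.frame(b), tolerance = 1e-12,
               ignore_attr = TRUE)
})
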