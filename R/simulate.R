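#' Configuration for the synthetic input generators
#'
#' Bundles every knob of the synthetic household survey, price panel, exchange
#' rate and reference-cost generators. The defaults emulate the statistical
#' structure the analysis assumes: concentrated right-skewed item shares
#' within each food subgroup (one dominant item around 15-30%, a long tail),
#' monthly item prices with trend, item-specific sinusoidal seasonality
#' (stronger for fresh produce), multiplicative noise, base-year segment
#' breaks with level shifts, missing months and 10x outliers, a daily
#' geometric-random-walk exchange rate, and a reference/basket cost pair with
#' a configurable seasonal premium. Every generator is fully reproducible from
#' `seed`; RNG state is restored on exit.
#'
#' @param seed integer seed driving all generators.
#' @param n_households households in the synthetic survey.
#' @param catalogue item catalogue (see [default_catalogue()]): columns
#'   `item, group, subgroup, fresh, marginal, price_level, base_mass_g`.
#' @param share_concentration Dirichlet concentration of the subgroup truth
#'   shares around their decayed weights (> 0).
#' @param share_decay geometric decay of item weights within a subgroup,
#'   in (0, 1); smaller = more concentrated.
#' @param household_concentration Dirichlet concentration of each household's
#'   item split around the truth shares.
#' @param seasonal_amplitude,seasonal_amplitude_fresh fractional seasonal
#'   price amplitude for staple and fresh-produce items.
#' @param trend fractional price trend per year.
#' @param noise_sd,rep_noise_sd lognormal sd of the common monthly shock and
#'   of the per-observation (outlet) shock.
#' @param n_reps price observations per item-month.
#' @param missing_rate,outlier_rate fractions in `[0, 1)`: item-months dropped;
#'   observations multiplied by `outlier_factor`.
#' @param outlier_factor multiplicative size of injected outliers.
#' @param segment_breaks list of `c(year, month)` where a new base-year
#'   segment starts.
#' @param segment_overlap months the outgoing segment keeps reporting after a
#'   break (gives the splice its overlap).
#' @param segment_shift_sd lognormal sd of the level shift of non-final
#'   segments (the final segment defines the reference level).
#' @param fx_level,fx_volatility exchange-rate level (CLP/USD) and daily
#'   log-volatility.
#' @param start,end panel window, `c(year, month)`.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_households = 400L,
                       catalogue = default_catalogue(),
                       share_concentration = 150,
                       share_decay = 0.8,
                       household_concentration = 50,
                       seasonal_amplitude = 0.05,
                       seasonal_amplitude_fresh = 0.15,
                       trend = 0.04,
                       noise_sd = 0.03,
                       rep_noise_sd = 0.05,
                       n_reps = 4L,
                       missing_rate = 0.05,
                       outlier_rate = 0.02,
                       outlier_factor = 10,
                       segment_breaks = list(c(2014L, 1L), c(2019L, 1L)),
                       segment_overlap = 3L,
                       segment_shift_sd = 0.1,
                       fx_level = 800,
                       fx_volatility = 0.002,
                       start = c(2010L, 1L),
                       end = c(2023L, 12L)) {
  stopifnot(share_decay > 0, share_decay < 1,
            missing_rate >= 0, missing_rate < 1,
            outlier_rate >= 0, outlier_rate < 1,
            seasonal_amplitude >= 0, noise_sd >= 0, fx_volatility >= 0,
            n_reps >= 1L, nrow(catalogue) > 0L)
  if (share_concentration <= 0 || household_concentration <= 0) {
    stop("degenerate configuration: concentration parameters must be > 0")
  }
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' Default synthetic item catalogue
#'
#' The packaged basket's items plus a marginal nuts-and-seeds entry, with a
#' flag for fresh produce (higher price seasonality), an indicative price
#' level (currency/kg) and a typical monthly household purchase mass for the
#' item's subgroup.
#'
#' @return data frame `item, group, subgroup, fresh, marginal, price_level,
#'   base_mass_g`.
#' @export
default_catalogue <- function() {
  t2 <- hsbfb_table2()
  tg <- hsbfb_targets()
  base_price <- c("Rice, Wheat, Corn, and Others" = 1500,
                  "Potatoes and Cassava" = 900,
                  "All Types of Vegetables" = 1200,
                  "All Types of Fruits" = 1400,
                  "Whole Milk or Equivalents" = 1000,
                  "Beef, Lamb, and Pork" = 7000,
                  "Chicken and Other Poultry" = 3500,
                  "Eggs" = 2500,
                  "Fish" = 8000,
                  "Legumes" = 2800,
                  "Nuts and Seeds" = 12000,
                  "Unsaturated Oils" = 3000,
                  "Saturated Oils" = 9000,
                  "All Types of Sugars" = 1100)
  cat <- data.frame(item = t2$item, group = t2$group, subgroup = t2$subgroup,
                    stringsAsFactors = FALSE)
  cat <- rbind(cat, data.frame(item = "Nuts and Seeds", group = "Protein Sources",
                               subgroup = "Nuts and Seeds"))
  cat$fresh <- cat$subgroup %in% c("All Types of Vegetables", "All Types of Fruits")
  cat$marginal <- cat$subgroup == "Nuts and Seeds"
  # deterministic within-subgroup price spread around the subgroup level
  idx <- stats::ave(seq_len(nrow(cat)), cat$subgroup, FUN = seq_along)
  n_sub <- stats::ave(seq_len(nrow(cat)), cat$subgroup, FUN = length)
  spread <- exp(0.6 * ((idx - 1) / pmax(n_sub - 1, 1) - 0.5))
  cat$price_level <- base_price[cat$subgroup] * ifelse(n_sub > 1, spread, 1)
  # typical monthly purchased mass per household scales with the daily target
  g <- tg$grams_per_day[match(cat$subgroup, tg$subgroup)]
  g[is.na(g) | g == 0] <- 50              # nominal mass for unallocated subgroups
  cat$base_mass_g <- 30 * g
  cat$base_mass_g[cat$marginal] <- 30 * g[cat$marginal] * 1e-4
  rownames(cat) <- NULL
  cat
}

# evaluate code under a seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Synthetic household purchase survey
#'
#' Draws, per subgroup, a truth share vector from a concentrated Dirichlet
#' around geometrically decaying item weights (few dominant items, long tail),
#' then gives every household a lognormal subgroup purchase mass split across
#' items by a household-level Dirichlet centred on the truth shares. Subgroups
#' flagged `marginal` in the catalogue purchase ~4 orders of magnitude less
#' mass, emulating a subgroup whose recorded consumption is negligible.
#' Aggregated item shares converge to the returned truth shares as
#' `n_households` grows.
#'
#' @param cfg a [sim_config()].
#' @param stratum stratum label stamped on the records (default `"Q1"`).
#' @return list: `records` (data frame `household, item, stratum, subgroup,
#'   quantity_g`) and `truth_shares` (`subgroup, item, share`).
#' @export
gen_consumption_survey <- function(cfg, stratum = "Q1") {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 101L, {
    cat <- cfg$catalogue
    recs <- vector("list", length(unique(cat$subgroup)))
    truth <- vector("list", length(recs))
    for (si in seq_along(unique(cat$subgroup))) {
      s <- unique(cat$subgroup)[si]
      d <- cat[cat$subgroup == s, ]
      k <- nrow(d)
      w <- cfg$share_decay^(seq_len(k) - 1)
      w <- w / sum(w)
      sh <- if (k == 1L) 1 else rdirichlet1(cfg$share_concentration * w)
      truth[[si]] <- data.frame(subgroup = s, item = d$item, share = sh)
      mass <- d$base_mass_g[1] * stats::rlnorm(cfg$n_households, 0, 0.3)
      split <- if (k == 1L) matrix(1, cfg$n_households, 1) else {
        g <- matrix(stats::rgamma(cfg$n_households * k,
                                  shape = rep(cfg$household_concentration * sh,
                                              each = cfg$n_households)),
                    nrow = cfg$n_households)
        g / rowSums(g)
      }
      q <- split * mass
      recs[[si]] <- data.frame(household = rep(seq_len(cfg$n_households), k),
                               item = rep(d$item, each = cfg$n_households),
                               stratum = stratum,
                               subgroup = s,
                               quantity_g = as.vector(q))
    }
    list(records = do.call(rbind, recs), truth_shares = do.call(rbind, truth))
  })
}

#' Synthetic consumer-price observations across base-year segments
#'
#' Each item's clean monthly price is
#' `level * (1 + trend * t) * (1 + amplitude * sin(2*pi*(month - peak)/12))`
#' with an item-specific peak month; observed prices add a common monthly
#' lognormal shock and per-observation (outlet) shocks. The window is cut into
#' base-year segments at `segment_breaks`; every non-final segment's prices
#' carry a known multiplicative level shift and keep reporting for
#' `segment_overlap` months past the break (the splice's raw material).
#' Item-months are dropped at `missing_rate` and observations inflated by
#' `outlier_factor` at `outlier_rate`, with all truth labels returned.
#'
#' @param cfg a [sim_config()].
#' @return list: `observations` (`item, year, month, price, segment, obs_id`),
#'   and `truth` with `clean` (noise- and shift-free monthly prices),
#'   `outlier_obs_id`, `missing_cells` (`item, year, month`) and
#'   `segment_shifts`.
#' @export
gen_price_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  months <- ym_seq(ym(cfg$start[1], cfg$start[2]), ym(cfg$end[1], cfg$end[2]))
  if (length(months) < 2L) stop("panel window must span at least 2 months")
  cat <- cfg$catalogue[!cfg$catalogue$marginal, , drop = FALSE]
  cat <- cat[!duplicated(cat$item), , drop = FALSE]   # one price series per market item

  seg_starts <- c(months[1], vapply(cfg$segment_breaks, function(b) ym(b[1], b[2]), 1L))
  seg_starts <- sort(unique(seg_starts))
  n_seg <- length(seg_starts)
  seg_of <- function(m) findInterval(m, seg_starts)

  with_seed(cfg$seed + 202L, {
    shifts <- c(exp(stats::rnorm(n_seg - 1L, 0, cfg$segment_shift_sd)), 1)
    names(shifts) <- paste0("seg", seq_len(n_seg))
    peaks <- sample.int(12L, nrow(cat), replace = TRUE)
    amp <- ifelse(cat$fresh, cfg$seasonal_amplitude_fresh, cfg$seasonal_amplitude)

    t_years <- (months - months[1]) / 12
    cal <- ym_month(months)
    clean_list <- obs_list <- vector("list", nrow(cat))
    missing_cells <- NULL
    for (i in seq_len(nrow(cat))) {
      clean <- cat$price_level[i] * (1 + cfg$trend * t_years) *
        (1 + amp[i] * sin(2 * pi * (cal - peaks[i]) / 12))
      clean_list[[i]] <- data.frame(item = cat$item[i], year = ym_year(months),
                                    month = ym_month(months), price = clean)
      keep <- stats::runif(length(months)) >= cfg$missing_rate
      if (!any(keep)) keep[sample.int(length(months), 1L)] <- TRUE
      if (any(!keep)) {
        missing_cells <- rbind(missing_cells,
                               data.frame(item = cat$item[i],
                                          year = ym_year(months[!keep]),
                                          month = ym_month(months[!keep])))
      }
      month_shock <- exp(stats::rnorm(length(months), 0, cfg$noise_sd))
      base_seg <- seg_of(months)
      rows <- NULL
      for (s in seq_len(n_seg)) {
        in_seg <- base_seg == s
        # outgoing segment keeps reporting through the overlap
        if (s < n_seg) {
          nxt <- seg_starts[s + 1L]
          in_seg <- in_seg | (months >= nxt & months < nxt + cfg$segment_overlap)
        }
        sel <- which(in_seg & keep)
        if (!length(sel)) next
        m_rep <- rep(months[sel], each = cfg$n_reps)
        p <- rep(clean[sel] * month_shock[sel], each = cfg$n_reps) *
          exp(stats::rnorm(length(m_rep), 0, cfg$rep_noise_sd)) * shifts[s]
        rows <- rbind(rows, data.frame(item = cat$item[i],
                                       year = ym_year(m_rep),
                                       month = ym_month(m_rep),
                                       price = p,
                                       segment = paste0("seg", s)))
      }
      obs_list[[i]] <- rows
    }
    obs <- do.call(rbind, obs_list)
    obs$obs_id <- seq_len(nrow(obs))
    is_out <- stats::runif(nrow(obs)) < cfg$outlier_rate
    obs$price[is_out] <- obs$price[is_out] * cfg$outlier_factor
    rownames(obs) <- NULL
    list(observations = obs,
         truth = list(clean = do.call(rbind, clean_list),
                      outlier_obs_id = obs$obs_id[is_out],
                      missing_cells = missing_cells,
                      segment_shifts = shifts))
  })
}

#' Admissible price ranges implied by the synthetic catalogue
#'
#' The reference-guide counterpart of the synthetic world: an admissible range
#' per item derived from the catalogue's known price level, mirroring how
#' national reference databases bound plausible retail prices. The default
#' bounds (`level/4` to `4 * level`) comfortably contain trend, seasonality
#' and noise at the generator defaults while excluding 10x outliers.
#'
#' @param cfg a [sim_config()].
#' @param lower,upper multiples of the catalogue price level.
#' @return data frame `item, low, high, source`.
#' @export
reference_ranges <- function(cfg, lower = 0.25, upper = 4) {
  stopifnot(inherits(cfg, "sim_config"), lower > 0, upper > lower)
  cat <- cfg$catalogue[!duplicated(cfg$catalogue$item), ]
  data.frame(item = cat$item, low = lower * cat$price_level,
             high = upper * cat$price_level, source = "synthetic catalogue")
}

#' Synthetic daily exchange-rate series
#'
#' A geometric random walk starting at `fx_level` with daily log-volatility
#' `fx_volatility`, over the configured window's calendar days.
#'
#' @param cfg a [sim_config()].
#' @return data frame `date, clp_per_usd`.
#' @export
gen_fx_series <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  from <- as.Date(sprintf("%04d-%02d-01", cfg$start[1], cfg$start[2]))
  last <- ym(cfg$end[1], cfg$end[2])
  to <- as.Date(sprintf("%04d-%02d-%02d", cfg$end[1], cfg$end[2],
                        days_in_month(last)))
  dates <- seq(from, to, by = "day")
  with_seed(cfg$seed + 303L, {
    steps <- stats::rnorm(length(dates) - 1L, 0, cfg$fx_volatility)
    data.frame(date = format(dates, "%Y-%m-%d"),
               clp_per_usd = cfg$fx_level * exp(cumsum(c(0, steps))))
  })
}

#' Synthetic reference/basket monthly cost pair with a seasonal premium
#'
#' Builds a reference cost series (level, trend, lognormal noise) and a target
#' series costing `(1 + premium(month))` times the reference, where the
#' premium is a sinusoid over the calendar year:
#' `premium(m) = premium_mean + premium_amplitude * cos(2*pi*(m - peak_month)/12)`.
#' Used for closed-loop gap-recovery tests: the generator's premium profile is
#' the truth that [compare_costs()] should recover.
#'
#' @param cfg a [sim_config()].
#' @param premium_mean,premium_amplitude,peak_month premium profile (defaults:
#'   mean 13.9%, peak 21.1% in October).
#' @param noise_sd lognormal sd applied independently to both series.
#' @param ref_level reference cost level, currency/month.
#' @param start,end window as `c(year, month)`. The default covers whole
#'   calendar years (January 2014 - December of the config's end year) so the
#'   seasonal term averages out and the configured `premium_mean` equals the
#'   true window-mean gap, which closed-loop recovery tests rely on.
#' @return list: `reference` and `basket` (cost-series data frames
#'   `year, month, days, cost_local`) and `truth` (premium profile by calendar
#'   month, mean premium, peak month).
#' @export
gen_reference_costs <- function(cfg, premium_mean = 0.139,
                                premium_amplitude = 0.072, peak_month = 10L,
                                noise_sd = 0.005, ref_level = 35000,
                                start = c(2014L, 1L),
                                end = c(cfg$end[1], 12L)) {
  stopifnot(inherits(cfg, "sim_config"))
  months <- ym_seq(ym(start[1], start[2]), ym(end[1], end[2]))
  cal <- ym_month(months)
  premium <- premium_mean + premium_amplitude * cos(2 * pi * (cal - peak_month) / 12)
  with_seed(cfg$seed + 404L, {
    t_years <- (months - months[1]) / 12
    ref <- ref_level * (1 + cfg$trend * t_years) *
      exp(stats::rnorm(length(months), 0, noise_sd))
    bas <- ref * (1 + premium) * exp(stats::rnorm(length(months), 0, noise_sd))
    mk <- function(cost) {
      structure(data.frame(year = ym_year(months), month = ym_month(months),
                           days = days_in_month(months), cost_local = cost),
                class = c("cost_series", "data.frame"),
                basis = "min", days_policy = "calendar")
    }
    profile <- premium_mean + premium_amplitude * cos(2 * pi * (1:12 - peak_month) / 12)
    list(reference = mk(ref), basket = mk(bas),
         truth = list(premium_by_calendar_month = profile,
                      mean_premium = premium_mean,
                      amplitude = premium_amplitude,
                      peak_month = peak_month))
  })
}
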