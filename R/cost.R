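#' Monthly cost of a basket from an item price panel
#'
#' Prices the daily purchase quantities of a basket at each month's per-kg
#' item prices and scales to a monthly cost:
#' `cost(month) = sum_items grams_purchase / 1000 * price_per_kg * days(month)`.
#' The minimum observed price is the default basis, matching the convention
#' used to cost official basic food baskets; the monthly mean is available as
#' an alternative.
#'
#' @param basket a [build_basket()] result (needs `item, subgroup,
#'   grams_purchase`).
#' @param panel a complete `price_panel` (after [impute_missing()]), prices in
#'   currency per kg.
#' @param basis `"min"` (default) or `"mean"`.
#' @param days_policy `"calendar"` (default) or `"fixed30"`; see
#'   [days_in_month()].
#' @param start,end analysis window (`"YYYY-MM"` or [ym()] indices; defaults:
#'   the panel's range). Every basket item must have a panel cell in every
#'   month of the window.
#' @return a `cost_series`: data frame `year, month, days, cost_local` with
#'   attributes `basis` and `days_policy`.
#' @examples
#' b <- data.frame(subgroup = "s", item = "a", grams_purchase = 1000)
#' p <- monthly_stats(data.frame(item = "a", year = 2020, month = 4, price = 1))
#' basket_cost_monthly(b, p)  # 1 kg/day at 1/kg over 30 days = 30
#' @export
basket_cost_monthly <- function(basket, panel, basis = c("min", "mean"),
                                days_policy = c("calendar", "fixed30"),
                                start = NULL, end = NULL) {
  basis <- match.arg(basis)
  days_policy <- match.arg(days_policy)
  stopifnot(all(c("item", "grams_purchase") %in% names(basket)))
  pym <- ym(panel$year, panel$month)
  start <- if (is.null(start)) min(pym) else as_ym(start)
  end <- if (is.null(end)) max(pym) else as_ym(end)
  months <- ym_seq(start, end)
  pcol <- if (basis == "min") "min_price" else "mean_price"

  # basket items may be subgroup-scoped (same name in two subgroups maps to
  # one market price series), so price lookup is by item name
  items <- unique(basket$item)
  miss <- setdiff(items, panel$item)
  if (length(miss)) stop("basket item(s) missing from the price panel: ",
                         paste(miss, collapse = ", "))
  grams <- tapply(basket$grams_purchase, basket$item, sum)[items]

  key <- paste(panel$item, pym, sep = "\r")
  cost <- numeric(length(months))
  for (j in seq_along(months)) {
    idx <- match(paste(items, months[j], sep = "\r"), key)
    if (anyNA(idx)) {
      stop("missing item-month after imputation: ",
           paste(items[is.na(idx)], ym_format(months[j]), collapse = ", "))
    }
    cost[j] <- sum(grams / 1000 * panel[[pcol]][idx])
  }
  days <- days_in_month(months, days_policy)
  out <- data.frame(year = ym_year(months), month = ym_month(months),
                    days = days, cost_local = cost * days)
  structure(out, class = c("cost_series", "data.frame"),
            basis = basis, days_policy = days_policy)
}

#' Convert a monthly cost series to US dollars
#'
#' Divides each monthly local-currency cost by the month's mean daily exchange
#' rate and derives a per-day cost:
#' `cost_usd_month = cost_local / mean(daily rate)`,
#' `cost_usd_day = cost_usd_month / days(month)`.
#'
#' @param series a `cost_series` from [basket_cost_monthly()] (or any data
#'   frame with `year, month, cost_local`).
#' @param fx data frame `date, clp_per_usd` of daily local-currency-per-USD
#'   rates (`date` as `"YYYY-MM-DD"`); must cover every month of the series.
#' @param days_policy day-count convention; default inherits the series
#'   attribute (calendar days otherwise).
#' @return the series with added `fx_rate, cost_usd_month, cost_usd_day`.
#' @export
to_usd <- function(series, fx, days_policy = NULL) {
  stopifnot(all(c("year", "month", "cost_local") %in% names(series)),
            all(c("date", "clp_per_usd") %in% names(fx)))
  if (is.null(days_policy)) {
    days_policy <- attr(series, "days_policy")
    if (is.null(days_policy)) days_policy <- "calendar"
  }
  d <- as.Date(fx$date)
  fym <- ym(as.integer(format(d, "%Y")), as.integer(format(d, "%m")))
  monthly <- tapply(fx$clp_per_usd, fym, mean)
  sym <- ym(series$year, series$month)
  rate <- monthly[as.character(sym)]
  if (anyNA(rate)) {
    stop("exchange rate missing for month(s): ",
         paste(ym_format(sym[is.na(rate)]), collapse = ", "))
  }
  series$fx_rate <- as.numeric(rate)
  series$cost_usd_month <- series$cost_local / series$fx_rate
  series$cost_usd_day <- series$cost_usd_month /
    days_in_month(sym, days_policy)
  series
}

#' Month-by-month percentage gap between two cost series
#'
#' Computes `gap(month) = 100 * (cost_a - cost_b) / cost_b` for every month of
#' the common window, the mean gap over the window, and the months where the
#' gap peaks and bottoms out (the seasonal extremes).
#'
#' @param series_a,series_b `cost_series` over the identical set of months
#'   (`series_b` is the reference the gap is expressed against).
#' @param value column to compare (default `"cost_local"`).
#' @return a `gap_summary` list: `by_month` (data frame `year, month,
#'   cost_a, cost_b, gap_percent`), `mean_gap`, `max_month`/`max_gap`,
#'   `min_month`/`min_gap` (months as `"YYYY-MM"`), `seasonal` (mean gap by
#'   calendar month) and `peak_calendar_month`/`trough_calendar_month`.
#' @examples
#' a <- data.frame(year = 2014, month = 4, cost_local = 39193)
#' b <- data.frame(year = 2014, month = 4, cost_local = 35019)
#' compare_costs(a, b)$mean_gap  # 11.9% (1 dp)
#' @export
compare_costs <- function(series_a, series_b, value = "cost_local") {
  ka <- ym(series_a$year, series_a$month)
  kb <- ym(series_b$year, series_b$month)
  if (length(ka) != length(kb) || !all(sort(ka) == sort(kb))) {
    stop("the two series do not cover the same months")
  }
  a <- series_a[[value]][order(ka)]
  b <- series_b[[value]][order(kb)]
  months <- sort(ka)
  gap <- 100 * (a - b) / b
  i_max <- which.max(gap); i_min <- which.min(gap)
  cal <- ym_month(months)
  seasonal <- data.frame(month = sort(unique(cal)),
                         mean_gap = as.numeric(tapply(gap, cal, mean)))
  structure(list(
    by_month = data.frame(year = ym_year(months), month = ym_month(months),
                          cost_a = a, cost_b = b, gap_percent = gap),
    mean_gap = mean(gap),
    max_month = ym_format(months[i_max]), max_gap = gap[i_max],
    min_month = ym_format(months[i_min]), min_gap = gap[i_min],
    seasonal = seasonal,
    peak_calendar_month = seasonal$month[which.max(seasonal$mean_gap)],
    trough_calendar_month = seasonal$month[which.min(seasonal$mean_gap)]),
    class = "gap_summary")
}

#' @export
print.gap_summary <- function(x, ...) {
  cat(sprintf("Cost gap over %d months: mean %.1f%%\n", nrow(x$by_month), x$mean_gap))
  cat(sprintf("  widest  %s: %+.1f%%\n", x$max_month, x$max_gap))
  cat(sprintf("  narrowest %s: %+.1f%%\n", x$min_month, x$min_gap))
  invisible(x)
}

#' Poverty lines from a basket cost (Orshansky method)
#'
#' Scales a monthly food-basket cost to a total poverty line with an Orshansky
#' multiplier (food share of total spending), and sets the extreme-poverty
#' line as a fraction of the poverty line:
#' `poverty_line = orshansky * basket_cost`;
#' `extreme_line = extreme_fraction * poverty_line`. Chile's current
#' methodology uses 2.68 and two-thirds.
#'
#' @param basket_cost monthly basket cost (> 0, any currency).
#' @param orshansky multiplier (> 0), default 2.68.
#' @param extreme_fraction fraction of the poverty line defining extreme
#'   poverty, default 2/3.
#' @return list `basket_cost, orshansky, poverty_line, extreme_line`.
#' @examples
#' poverty_thresholds(100)  # 268 and 178.67
#' @export
poverty_thresholds <- function(basket_cost, orshansky = 2.68,
                               extreme_fraction = 2 / 3) {
  if (any(basket_cost <= 0) || orshansky <= 0 || extreme_fraction <= 0) {
    stop("basket cost, multiplier and fraction must all be positive")
  }
  pl <- orshansky * basket_cost
  list(basket_cost = basket_cost, orshansky = orshansky,
       poverty_line = pl, extreme_line = extreme_fraction * pl)
}

#' Period means of a cost series
#'
#' Arithmetic mean of a cost column over one or more closed sub-windows of the
#' series (e.g. the full decade, or a late high-inflation stretch).
#'
#' @param series a `cost_series` (after [to_usd()] when averaging USD/day).
#' @param windows list of `c(start, end)` pairs (`"YYYY-MM"` strings or [ym()]
#'   indices); names are carried to the result.
#' @param value column to average, default `"cost_usd_day"`.
#' @return named numeric vector of window means.
#' @export
summarize_period <- function(series, windows, value = "cost_usd_day") {
  if (!value %in% names(series)) stop("series lacks column ", value)
  sym <- ym(series$year, series$month)
  vapply(windows, function(w) {
    from <- as_ym(w[[1]]); to <- as_ym(w[[2]])
    sel <- sym >= from & sym <= to
    if (!any(sel)) stop("empty window: ", ym_format(from), "..", ym_format(to))
    mean(series[[value]][sel])
  }, numeric(1))
}

#' @export
print.cost_series <- function(x, ...) {
  cat(sprintf("Monthly cost series: %s to %s (%d months, basis: %s)\n",
              sprintf("%04d-%02d", x$year[1], x$month[1]),
              sprintf("%04d-%02d", x$year[nrow(x)], x$month[nrow(x)]),
              nrow(x), attr(x, "basis") %||% "?"))
  print(utils::head(as.data.frame(x), 6), row.names = FALSE, ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Plot a monthly cost series
#'
#' @param x a `cost_series`.
#' @param value column to plot (default `"cost_local"`).
#' @param ... passed to [graphics::plot()].
#' @return the series, invisibly.
#' @export
plot.cost_series <- function(x, value = "cost_local", ...) {
  t <- x$year + (x$month - 0.5) / 12
  graphics::plot(t, x[[value]], type = "l", xlab = "year", ylab = value, ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
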