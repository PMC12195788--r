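#' Calendar-month index helpers
#'
#' Months are handled internally as a single integer index,
#' `year * 12 + (month - 1)`, so that windows are closed integer intervals and
#' month arithmetic never touches Date objects.
#'
#' @param year,month integer vectors.
#' @param x a month index (integer) or, for `ym_parse()`, a `"YYYY-MM"` string.
#' @param from,to month indices.
#' @return `ym()` and `ym_parse()` return integer month indices; `ym_year()`,
#'   `ym_month()` their calendar components; `ym_format()` `"YYYY-MM"` strings;
#'   `ym_seq()` an integer sequence of consecutive months.
#' @examples
#' ym(2014, 4)
#' ym_format(ym_seq(ym_parse("2023-11"), ym_parse("2024-02")))
#' @export
ym <- function(year, month) {
  stopifnot(all(month >= 1L & month <= 12L))
  as.integer(year) * 12L + as.integer(month) - 1L
}

#' @rdname ym
#' @export
ym_year <- function(x) as.integer(x) %/% 12L

#' @rdname ym
#' @export
ym_month <- function(x) as.integer(x) %% 12L + 1L

#' @rdname ym
#' @export
ym_parse <- function(x) {
  m <- regmatches(x, regexec("^(\\d{4})-(\\d{1,2})$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("cannot parse year-month: ", paste(x[bad], collapse = ", "))
  ym(vapply(m, function(p) as.integer(p[2]), 1L),
     vapply(m, function(p) as.integer(p[3]), 1L))
}

#' @rdname ym
#' @export
ym_format <- function(x) sprintf("%04d-%02d", ym_year(x), ym_month(x))

#' @rdname ym
#' @export
ym_seq <- function(from, to) {
  if (from > to) stop("window start is after window end")
  seq.int(as.integer(from), as.integer(to))
}

#' Days in a calendar month
#'
#' @param x month index as from [ym()].
#' @param policy `"calendar"` (true calendar days, leap-year aware) or
#'   `"fixed30"` (every month counts 30 days).
#' @return integer vector of day counts.
#' @examples
#' days_in_month(ym(2014, 4))        # 30
#' days_in_month(ym(2020, 2))        # 29
#' @export
days_in_month <- function(x, policy = c("calendar", "fixed30")) {
  policy <- match.arg(policy)
  if (policy == "fixed30") return(rep.int(30L, length(x)))
  y <- ym_year(x)
  m <- ym_month(x)
  base <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  d <- base[m]
  leap <- (y %% 4L == 0L & y %% 100L != 0L) | y %% 400L == 0L
  d[m == 2L & leap] <- 29L
  d
}

# internal: coerce a window spec ("YYYY-MM" strings or integer ym) to ym
as_ym <- function(x) {
  if (is.character(x)) ym_parse(x) else as.integer(x)
}
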