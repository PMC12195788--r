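#' Read the delimited input files
#'
#' Thin readers over [utils::read.csv()] that validate the column contract of
#' each input and return plain data frames. All files are comma-separated,
#' UTF-8, with a header row.
#'
#' * consumption survey: `item,stratum,subgroup,quantity_g` (optional `group`)
#' * food-group targets: `group,subgroup,grams_per_day`
#' * transformation factors: `item,factor,source` (optional `subgroup` to scope
#'   an item that appears in more than one subgroup)
#' * nutrient table: `item,basis,energy_kcal_100g,protein_g_100g,carb_g_100g,
#'   lipid_g_100g` (optional `subgroup`)
#' * price observations: `item,year,month,price,segment,obs_id` (optional
#'   `item_raw` when a name map is applied downstream)
#' * admissible price ranges: `item,low,high,source`
#' * reference basket costs: `year,month,cost_clp`
#' * exchange rates: `date,clp_per_usd` with ISO dates
#'
#' @param path file path.
#' @return a data frame with the validated columns.
#' @name readers
NULL

read_delim_checked <- function(path, required) {
  x <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                       fileEncoding = "UTF-8")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s",
                 basename(path), paste(missing, collapse = ", ")))
  }
  x
}

#' @rdname readers
#' @export
read_survey <- function(path) {
  x <- read_delim_checked(path, c("item", "stratum", "subgroup", "quantity_g"))
  if (any(x$quantity_g < 0, na.rm = TRUE)) stop("negative quantity_g in ", path)
  x
}

#' @rdname readers
#' @export
read_targets <- function(path) {
  x <- read_delim_checked(path, c("group", "subgroup", "grams_per_day"))
  if (anyDuplicated(x$subgroup)) stop("duplicate subgroup in targets: ", path)
  if (any(x$grams_per_day < 0)) stop("negative grams_per_day in ", path)
  x
}

#' @rdname readers
#' @export
read_fti <- function(path) {
  x <- read_delim_checked(path, c("item", "factor"))
  if (!"source" %in% names(x)) x$source <- NA_character_
  x
}

#' @rdname readers
#' @export
read_nutrients <- function(path) {
  read_delim_checked(path, c("item", "basis", "energy_kcal_100g",
                             "protein_g_100g", "carb_g_100g", "lipid_g_100g"))
}

#' @rdname readers
#' @export
read_price_obs <- function(path) {
  x <- read_delim_checked(path, c("item", "year", "month", "price", "segment"))
  if (!"obs_id" %in% names(x)) x$obs_id <- seq_len(nrow(x))
  if (any(x$price <= 0)) stop("non-positive price in ", path)
  x
}

#' @rdname readers
#' @export
read_ranges <- function(path) {
  x <- read_delim_checked(path, c("item", "low", "high"))
  if (any(x$low <= 0) || any(x$high < x$low)) {
    stop("admissible ranges must satisfy 0 < low <= high: ", path)
  }
  x
}

#' @rdname readers
#' @export
read_reference_costs <- function(path) {
  read_delim_checked(path, c("year", "month", "cost_clp"))
}

#' @rdname readers
#' @export
read_fx <- function(path) {
  x <- read_delim_checked(path, c("date", "clp_per_usd"))
  if (any(x$clp_per_usd <= 0)) stop("non-positive exchange rate in ", path)
  x
}

#' Packaged basket fixtures
#'
#' Accessors for the plain-text tables shipped with the package: the food-group
#' gram targets, the published basket composition (grams to consume, adjustment
#' factor, purchased grams), the published subgroup nutrient totals, and a
#' synthetic per-item nutrient table back-solved from those subgroup totals
#' (uniform per-100 g values within each subgroup; see the package vignette).
#'
#' @return data frames; see [readers] for columns. `hsbfb_table2()` rows carry
#'   `group, subgroup, item, grams_consume, fti, grams_purchase_printed`.
#' @examples
#' head(hsbfb_table2())
#' @export
hsbfb_targets <- function() {
  read_targets(system.file("extdata", "eat_lancet_targets.csv",
                           package = "basketcost", mustWork = TRUE))
}

#' @rdname hsbfb_targets
#' @export
hsbfb_table2 <- function() {
  read_delim_checked(
    system.file("extdata", "table2_basket.csv",
                package = "basketcost", mustWork = TRUE),
    c("group", "subgroup", "item", "grams_consume", "fti",
      "grams_purchase_printed"))
}

#' @rdname hsbfb_targets
#' @export
hsbfb_table3 <- function() {
  read_delim_checked(
    system.file("extdata", "table3_totals.csv",
                package = "basketcost", mustWork = TRUE),
    c("group", "subgroup", "energy_kcal", "protein_g", "carb_g", "lipid_g"))
}

#' @rdname hsbfb_targets
#' @export
hsbfb_nutrients_synthetic <- function() {
  read_nutrients(system.file("extdata", "synthetic_item_nutrients.csv",
                             package = "basketcost", mustWork = TRUE))
}

#' Consumption shares implied by the packaged basket table
#'
#' Derives the within-subgroup consumption share of every packaged basket item
#' as its printed grams-to-consume divided by the subgroup total, renormalized
#' so shares sum to one within each subgroup (the printed gram columns carry
#' 2-dp rounding, so raw ratios can miss 1 by a few 1e-4).
#'
#' @return a `share_table` as returned by [compute_group_shares()].
#' @export
hsbfb_shares <- function() {
  t2 <- hsbfb_table2()
  tot <- stats::ave(t2$grams_consume, t2$subgroup, FUN = sum)
  out <- data.frame(subgroup = t2$subgroup, item = t2$item,
                    share = t2$grams_consume / tot,
                    stringsAsFactors = FALSE)
  structure(out, class = c("share_table", "data.frame"),
            excluded_subgroups = character())
}
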