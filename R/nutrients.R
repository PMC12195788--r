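#' Per-item daily nutrient contributions
#'
#' Multiplies each basket item's daily grams by its per-100 g nutrient values:
#' `contribution = grams / 100 * value_per_100g`, for energy (kcal), protein,
#' carbohydrate and lipid (g).
#'
#' The nutrient table's `basis` declares which gram column it applies to:
#' values per 100 g of prepared/consumed food multiply `grams_consume`, values
#' per 100 g as purchased multiply `grams_purchase`. The basis is a property of
#' the table, not of a row.
#'
#' @param basket a [build_basket()] result, or any data frame with columns
#'   `group, subgroup, item` and the gram column the basis requires.
#' @param nutrients data frame `item, energy_kcal_100g, protein_g_100g,
#'   carb_g_100g, lipid_g_100g`, optional `subgroup` (scoped lookup) and
#'   optional `basis` column (checked against `basis` if both given).
#' @param basis `"consumed"` (default) or `"purchased"`.
#' @return data frame with the basket keys plus `grams, energy_kcal, protein_g,
#'   carb_g, lipid_g` per day.
#' @examples
#' b <- data.frame(group = "g", subgroup = "s", item = "x", grams_consume = 50)
#' n <- data.frame(item = "x", energy_kcal_100g = 200, protein_g_100g = 10,
#'                 carb_g_100g = 20, lipid_g_100g = 5)
#' attach_profiles(b, n)  # 100 kcal/day
#' @export
attach_profiles <- function(basket, nutrients, basis = c("consumed", "purchased")) {
  basis <- match.arg(basis)
  cols <- c("energy_kcal_100g", "protein_g_100g", "carb_g_100g", "lipid_g_100g")
  stopifnot(all(c("item", cols) %in% names(nutrients)))
  if ("basis" %in% names(nutrients)) {
    declared <- unique(nutrients$basis)
    if (length(declared) != 1L) stop("nutrient table declares mixed bases")
    if (declared != basis) {
      stop(sprintf("nutrient table basis is '%s' but basis = '%s' requested",
                   declared, basis))
    }
  }
  gram_col <- if (basis == "consumed") "grams_consume" else "grams_purchase"
  if (!gram_col %in% names(basket)) stop("basket lacks column ", gram_col)

  idx <- if ("subgroup" %in% names(nutrients) && "subgroup" %in% names(basket)) {
    match(paste(basket$subgroup, basket$item, sep = "\r"),
          paste(nutrients$subgroup, nutrients$item, sep = "\r"))
  } else {
    match(basket$item, nutrients$item)
  }
  if (anyNA(idx)) {
    stop("no nutrient entry for item(s): ",
         paste(unique(basket$item[is.na(idx)]), collapse = ", "))
  }
  g <- basket[[gram_col]]
  keys <- intersect(c("group", "subgroup", "item"), names(basket))
  out <- basket[, keys, drop = FALSE]
  out$grams <- g
  out$energy_kcal <- g / 100 * nutrients$energy_kcal_100g[idx]
  out$protein_g <- g / 100 * nutrients$protein_g_100g[idx]
  out$carb_g <- g / 100 * nutrients$carb_g_100g[idx]
  out$lipid_g <- g / 100 * nutrients$lipid_g_100g[idx]
  rownames(out) <- NULL
  out
}

#' Aggregate nutrient contributions by subgroup with a grand total
#'
#' Sums per-item daily contributions to one row per subgroup plus a `TOTAL`
#' row that equals the column sums of the subgroup rows exactly.
#'
#' @param contributions data frame from [attach_profiles()] (any data frame
#'   with `subgroup` and the four nutrient columns works; `group` optional).
#' @return a `nutrient_totals` data frame: per-subgroup rows, then a final row
#'   with `subgroup == "TOTAL"`.
#' @export
aggregate_totals <- function(contributions) {
  cols <- c("energy_kcal", "protein_g", "carb_g", "lipid_g")
  stopifnot(nrow(contributions) > 0L,
            all(c("subgroup", cols) %in% names(contributions)))
  x <- contributions
  if (!"group" %in% names(x)) x$group <- x$subgroup
  sub <- stats::aggregate(x[cols], by = x[c("group", "subgroup")], FUN = sum)
  sub <- sub[order(match(sub$subgroup, unique(x$subgroup))), ]
  total <- data.frame(group = "TOTAL", subgroup = "TOTAL",
                      as.list(colSums(sub[cols])))
  out <- rbind(sub, total)
  rownames(out) <- NULL
  structure(out, class = c("nutrient_totals", "data.frame"))
}

#' Macronutrient shares of total energy
#'
#' Converts the grand-total macronutrient grams to percentages of total energy
#' using energy conversion (Atwater) factors:
#' `percent = 100 * grams * factor / energy_total`. The three percentages need
#' not sum to 100: energy from unaccounted components (fibre, alcohol) and
#' database rounding leave a remainder.
#'
#' @param totals a `nutrient_totals` from [aggregate_totals()], or a list/row
#'   with `energy_kcal, protein_g, carb_g, lipid_g`.
#' @param factors named kcal/g conversion factors; default the Atwater general
#'   factors `c(protein = 4, carbohydrate = 4, lipid = 9)`.
#' @return named numeric: `protein`, `carbohydrate`, `lipid` in percent.
#' @examples
#' macro_percentages(list(energy_kcal = 2000, protein_g = 75,
#'                        carb_g = 260, lipid_g = 72))
#' @export
macro_percentages <- function(totals,
                              factors = c(protein = 4, carbohydrate = 4, lipid = 9)) {
  stopifnot(all(c("protein", "carbohydrate", "lipid") %in% names(factors)))
  row <- if (inherits(totals, "nutrient_totals")) {
    totals[totals$subgroup == "TOTAL", , drop = FALSE]
  } else {
    totals
  }
  e <- row$energy_kcal
  if (length(e) != 1L || is.na(e) || e <= 0) stop("total energy must be > 0")
  c(protein = 100 * row$protein_g * factors[["protein"]] / e,
    carbohydrate = 100 * row$carb_g * factors[["carbohydrate"]] / e,
    lipid = 100 * row$lipid_g * factors[["lipid"]] / e)
}

#' @export
print.nutrient_totals <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], round, digits)
  print(y, row.names = FALSE, ...)
  pct <- macro_percentages(x)
  cat(sprintf("Energy from macronutrients: protein %.2f%%, carbohydrate %.2f%%, lipid %.2f%%\n",
              pct[["protein"]], pct[["carbohydrate"]], pct[["lipid"]]))
  invisible(x)
}
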