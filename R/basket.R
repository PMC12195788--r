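#' Within-subgroup consumption shares from survey purchase records
#'
#' Computes, for one income stratum, each item's share of the total quantity
#' purchased within its food subgroup. Shares are the allocation weights used
#' to distribute a food-group gram target across the items the stratum
#' actually buys.
#'
#' Items whose share falls below `min_share` are dropped and the remaining
#' shares renormalized. `coverage < 1` keeps only the most-purchased items
#' until their cumulative share reaches `coverage` (then renormalizes), a
#' "most representative items" selection. A whole subgroup is excluded (empty
#' share set, zero downstream allocation) when its recorded mass is marginal:
#' below `marginal_share` of the stratum's total recorded mass, or below the
#' absolute `min_subgroup_g`, or zero.
#'
#' @param records data frame of purchase records with columns
#'   `item, stratum, subgroup, quantity_g` (see [read_survey()]). Quantities
#'   must share one declared mass unit.
#' @param stratum the stratum label to keep (e.g. `"Q1"`, the lowest income
#'   quintile).
#' @param min_share drop items below this share of their subgroup (default 0:
#'   keep every recorded item).
#' @param coverage cumulative-share cutoff in (0, 1]; default 1.
#' @param marginal_share exclude a subgroup whose total mass is below this
#'   fraction of the stratum's total recorded mass (default 0.001).
#' @param min_subgroup_g absolute alternative to `marginal_share`, in grams
#'   (default 0 = disabled).
#' @param weight column of `records` that defines the share basis. The default
#'   is purchased mass (`"quantity_g"`); pass an expenditure column for
#'   expenditure-weighted shares.
#' @return a `share_table`: data frame `subgroup, item, share` where shares sum
#'   to 1 within each retained subgroup, with attribute `excluded_subgroups`.
#' @examples
#' rec <- data.frame(item = c("A", "B"), stratum = "Q1",
#'                   subgroup = "veg", quantity_g = c(30, 70))
#' compute_group_shares(rec, "Q1")
#' @seealso [allocate_group_target()], [build_basket()]
#' @export
compute_group_shares <- function(records, stratum, min_share = 0, coverage = 1,
                                 marginal_share = 0.001, min_subgroup_g = 0,
                                 weight = "quantity_g") {
  stopifnot(is.data.frame(records),
            all(c("item", "stratum", "subgroup", weight) %in% names(records)))
  if (min_share < 0 || min_share >= 1) stop("min_share must be in [0, 1)")
  if (coverage <= 0 || coverage > 1) stop("coverage must be in (0, 1]")
  x <- records[records$stratum == stratum, , drop = FALSE]
  x$quantity_g <- x[[weight]]
  if (nrow(x) == 0L) stop("stratum not found: ", stratum)
  if (any(x$quantity_g < 0)) stop("negative purchase quantities")

  unmapped <- is.na(x$subgroup) | x$subgroup == ""
  if (any(unmapped)) {
    warning("excluding ", sum(unmapped), " record(s) with no subgroup mapping: ",
            paste(unique(x$item[unmapped]), collapse = ", "))
    x <- x[!unmapped, , drop = FALSE]
  }
  if (nrow(x) == 0L) stop("no mapped records for stratum ", stratum)

  agg <- stats::aggregate(quantity_g ~ subgroup + item, data = x, FUN = sum)
  sub_tot <- tapply(agg$quantity_g, agg$subgroup, sum)
  grand <- sum(agg$quantity_g)

  marginal <- sub_tot <= 0 | sub_tot < marginal_share * grand | sub_tot < min_subgroup_g
  excluded <- names(sub_tot)[marginal]

  keep <- !(agg$subgroup %in% excluded)
  agg <- agg[keep, , drop = FALSE]
  agg$share <- agg$quantity_g / sub_tot[agg$subgroup]

  # per-subgroup share filtering and renormalization
  pieces <- lapply(split(agg, agg$subgroup), function(d) {
    d <- d[d$share >= min_share & d$share > 0, , drop = FALSE]
    if (nrow(d) == 0L) return(d)
    d <- d[order(-d$share, d$item), , drop = FALSE]
    if (coverage < 1) {
      cum <- cumsum(d$share) / sum(d$share)
      d <- d[seq_len(which(cum >= coverage - 1e-12)[1]), , drop = FALSE]
    }
    d$share <- d$share / sum(d$share)
    d
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out <- out[, c("subgroup", "item", "share")]
  structure(out, class = c("share_table", "data.frame"),
            excluded_subgroups = excluded)
}

#' Distribute a food-group gram target over item shares
#'
#' Applies the reference-diet daily gram target of each subgroup to its item
#' share vector: `grams_consume = share * grams_per_day`. Allocation conserves
#' mass (item grams sum to the target); a subgroup with an empty share set
#' receives zero allocation.
#'
#' @param targets data frame `group, subgroup, grams_per_day` (one or more
#'   rows; see [read_targets()]).
#' @param shares a `share_table` from [compute_group_shares()] (or any data
#'   frame `subgroup, item, share`).
#' @return data frame `group, subgroup, item, share, grams_consume`.
#' @examples
#' sh <- data.frame(subgroup = "veg", item = c("A", "B"), share = c(0.3, 0.7))
#' tg <- data.frame(group = "Vegetables", subgroup = "veg", grams_per_day = 200)
#' allocate_group_target(tg, sh)
#' @export
allocate_group_target <- function(targets, shares) {
  stopifnot(all(c("subgroup", "grams_per_day") %in% names(targets)),
            all(c("subgroup", "item", "share") %in% names(shares)))
  if (any(targets$grams_per_day < 0)) stop("negative gram target rejected")
  if (!"group" %in% names(targets)) targets$group <- targets$subgroup
  bad <- abs(tapply(shares$share, shares$subgroup, sum) - 1) > 1e-9
  if (any(bad)) {
    stop("shares do not sum to 1 in subgroup(s): ",
         paste(names(bad)[bad], collapse = ", "))
  }
  out <- merge(targets[, c("group", "subgroup", "grams_per_day")], shares,
               by = "subgroup")
  out$grams_consume <- out$share * out$grams_per_day
  out <- out[order(match(out$subgroup, targets$subgroup), -out$share, out$item), ]
  rownames(out) <- NULL
  out[, c("group", "subgroup", "item", "share", "grams_consume")]
}

#' Purchased grams from consumed grams via the food transformation index
#'
#' The food transformation index (FTI) is the ratio of prepared/edible mass to
#' purchased mass, so `grams_purchase = grams_consume / factor`. A factor
#' below 1 (preparation loss, e.g. peel) inflates the purchase requirement; a
#' factor above 1 (water uptake during cooking, e.g. rice) deflates it.
#'
#' @param grams_consume numeric vector of daily consumed grams.
#' @param factor FTI values, recycled against `grams_consume`; must be > 0.
#' @param item optional item labels used in error messages.
#' @return numeric vector of daily purchased grams.
#' @examples
#' apply_fti(100, 1.04)  # potato: 96.15 g to purchase
#' apply_fti(28.14, 2.5) # rice swells when cooked: 11.26 g
#' @export
apply_fti <- function(grams_consume, factor, item = NULL) {
  if (any(factor <= 0)) {
    who <- if (is.null(item)) which(factor <= 0) else item[factor <= 0]
    stop("FTI factor must be > 0; offending item(s): ",
         paste(who, collapse = ", "))
  }
  if (any(grams_consume < 0)) stop("negative consumed grams")
  grams_consume / factor
}

#' Build the basket item table
#'
#' Runs the full allocation: item shares are applied to the subgroup gram
#' targets and the resulting consumed grams converted to purchased grams with
#' each item's transformation factor. One row per retained item.
#'
#' @param targets data frame `group, subgroup, grams_per_day`.
#' @param shares a `share_table` (see [compute_group_shares()]).
#' @param fti data frame `item, factor` with optional `subgroup` (an item
#'   listed under two subgroups, e.g. cucumber as vegetable and as fruit, can
#'   carry a different factor in each) and optional `source`. An allocated
#'   item with no entry gets factor 1 with a warning.
#' @return a `basket`: data frame
#'   `group, subgroup, item, share, grams_consume, fti, grams_purchase`.
#' @examples
#' tg <- data.frame(group = "Vegetables", subgroup = "veg", grams_per_day = 300)
#' sh <- data.frame(subgroup = "veg", item = c("tomato", "onion"),
#'                  share = c(0.6, 0.4))
#' fti <- data.frame(item = c("tomato", "onion"), factor = c(0.83, 0.78))
#' build_basket(tg, sh, fti)
#' @export
build_basket <- function(targets, shares, fti) {
  stopifnot(all(c("item", "factor") %in% names(fti)))
  dup <- duplicated(shares[, c("subgroup", "item")])
  if (any(dup)) {
    stop("duplicate item within a subgroup: ",
         paste(unique(paste(shares$subgroup[dup], shares$item[dup], sep = "/")),
               collapse = ", "))
  }
  alloc <- allocate_group_target(targets, shares)
  alloc$fti <- match_fti(alloc$subgroup, alloc$item, fti)
  missing <- is.na(alloc$fti)
  if (any(missing)) {
    warning("no FTI entry for: ",
            paste(alloc$item[missing], collapse = ", "),
            "; defaulting to factor 1")
    alloc$fti[missing] <- 1
  }
  alloc$grams_purchase <- apply_fti(alloc$grams_consume, alloc$fti, alloc$item)
  structure(alloc, class = c("basket", "data.frame"),
            excluded_subgroups = attr(shares, "excluded_subgroups"))
}

# subgroup-scoped FTI lookup with item-level fallback
match_fti <- function(subgroup, item, fti) {
  if ("subgroup" %in% names(fti)) {
    key <- paste(subgroup, item, sep = "\r")
    fkey <- paste(fti$subgroup, fti$item, sep = "\r")
    f <- fti$factor[match(key, fkey)]
    f[is.na(f)] <- fti$factor[match(item[is.na(f)], fti$item)]
  } else {
    f <- fti$factor[match(item, fti$item)]
  }
  f
}

#' @export
print.basket <- function(x, digits = 2, ...) {
  cat(sprintf("Food basket: %d items in %d subgroups\n",
              nrow(x), length(unique(x$subgroup))))
  y <- as.data.frame(x)
  y$share <- round(100 * y$share, digits)
  y$grams_consume <- round(y$grams_consume, digits)
  y$grams_purchase <- round(y$grams_purchase, digits)
  names(y)[names(y) == "share"] <- "share_pct"
  print(y, row.names = FALSE, ...)
  ex <- attr(x, "excluded_subgroups")
  if (length(ex)) cat("Excluded (marginal) subgroups:", paste(ex, collapse = ", "), "\n")
  invisible(x)
}

#' Subgroup totals of a basket
#'
#' @param object a `basket` from [build_basket()].
#' @param ... unused.
#' @return data frame of per-subgroup consumed and purchased gram totals.
#' @export
summary.basket <- function(object, ...) {
  out <- stats::aggregate(cbind(grams_consume, grams_purchase) ~ group + subgroup,
                          data = object, FUN = sum)
  out <- out[order(match(out$subgroup, unique(object$subgroup))), ]
  rownames(out) <- NULL
  out
}
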