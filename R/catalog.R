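#' Food-group catalog
#'
#' A catalog names the food groups used as recommender "items", flags the
#' subset eligible to appear in recommendation lists (groups aligned with
#' dietary guidelines), and optionally maps individual FFQ item columns to
#' groups for [collapse_items()].
#'
#' @param groups Character vector of unique group identifiers, in display
#'   order. This order is also the tie-break order for recommendations.
#' @param eligible Character vector, a subset of `groups`, of groups that may
#'   be emitted as recommendations.
#' @param item_mapping Optional named character vector or list mapping each
#'   FFQ item name to exactly one group identifier.
#' @return An object of class `food_group_catalog` with elements `groups`,
#'   `eligible` and `item_mapping`.
#' @seealso [default_catalog()], [read_catalog()]
#' @export
food_group_catalog <- function(groups, eligible, item_mapping = NULL) {
  groups <- as.character(groups)
  eligible <- as.character(eligible)
  if (anyDuplicated(groups)) {
    stop("duplicate group identifiers: ",
         paste(unique(groups[duplicated(groups)]), collapse = ", "))
  }
  if (!all(eligible %in% groups)) {
    stop("eligible groups not in catalog: ",
         paste(setdiff(eligible, groups), collapse = ", "))
  }
  if (anyDuplicated(eligible)) stop("duplicate eligible group identifiers")
  if (!is.null(item_mapping)) {
    item_mapping <- unlist(item_mapping)
    if (is.null(names(item_mapping)) || any(!nzchar(names(item_mapping)))) {
      stop("item_mapping must be named by FFQ item")
    }
    if (anyDuplicated(names(item_mapping))) {
      stop("each FFQ item must map to exactly one group")
    }
    bad <- setdiff(unique(item_mapping), groups)
    if (length(bad)) {
      stop("item_mapping targets unknown groups: ", paste(bad, collapse = ", "))
    }
  }
  structure(list(groups = groups, eligible = eligible,
                 item_mapping = item_mapping),
            class = "food_group_catalog")
}

#' Default food-group catalog (21 groups, 8 eligible)
#'
#' The default catalog used throughout the package: 21 food groups formed by
#' collapsing FFQ items by preparation or nutritional characteristics, of
#' which 8 are eligible as recommendations (whole cereals; tubers and roots;
#' beans and other legumes; oilseeds; fruits; vegetables; white meats and
#' fish; low-fat dairy products and milk), following Brazilian dietary
#' guidelines for groups with a recognized role in chronic-disease
#' prevention.
#'
#' @return A `food_group_catalog` with 21 groups and 8 eligible groups.
#' @export
default_catalog <- function() {
  groups <- c(
    "refined_cereals", "whole_cereals", "tubers_and_roots", "breads",
    "confectionery", "beans_and_other_legumes", "oilseeds", "fruits",
    "vegetables", "red_meats", "white_meats_and_fish", "processed_meats",
    "eggs", "high_fat_dairy_products_and_milk",
    "low_fat_dairy_products_and_milk", "oils_and_fats", "pasta",
    "salted_snacks", "juices_and_other_beverages", "soft_drinks",
    "alcoholic_beverages"
  )
  eligible <- c(
    "whole_cereals", "tubers_and_roots", "beans_and_other_legumes",
    "oilseeds", "fruits", "vegetables", "white_meats_and_fish",
    "low_fat_dairy_products_and_milk"
  )
  food_group_catalog(groups, eligible)
}

#' Read a catalog from a JSON or YAML config file
#'
#' The file must contain `groups` (ordered list) and `eligible` (list), and
#' may contain `item_mapping` (map from FFQ item to group).
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A `food_group_catalog`.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported catalog format: .", ext, " (use JSON or YAML)")
  )
  if (is.null(cfg$groups) || is.null(cfg$eligible)) {
    stop("catalog config must define 'groups' and 'eligible'")
  }
  food_group_catalog(cfg$groups, cfg$eligible, cfg$item_mapping)
}

#' @export
print.food_group_catalog <- function(x, ...) {
  cat("Food-group catalog:", length(x$groups), "groups,",
      length(x$eligible), "eligible as recommendations\n")
  cat("  groups:  ", paste(x$groups, collapse = ", "), "\n")
  cat("  eligible:", paste(x$eligible, collapse = ", "), "\n")
  if (!is.null(x$item_mapping)) {
    cat("  item_mapping:", length(x$item_mapping), "FFQ items\n")
  }
  invisible(x)
}

#' Collapse per-item FFQ intake into food-group intake
#'
#' Sums the daily intake of individual FFQ items into the catalog's food
#' groups using `catalog$item_mapping`. Groups with no mapped items get zero
#' intake. Identifier and energy columns (`participant_id`, `energy_kcal`)
#' are carried through unchanged.
#'
#' @param ffq_items Data frame with `participant_id`, optionally
#'   `energy_kcal`, and one numeric column per FFQ item.
#' @param catalog A `food_group_catalog` whose `item_mapping` covers every
#'   item column.
#' @return An intake table: `participant_id`, `energy_kcal` (if present), and
#'   one column per catalog group, in catalog order. Total grams per
#'   participant are conserved.
#' @export
collapse_items <- function(ffq_items, catalog) {
  stopifnot(inherits(catalog, "food_group_catalog"))
  if (is.null(catalog$item_mapping)) {
    stop("catalog has no item_mapping; cannot collapse FFQ items")
  }
  carried <- intersect(c("participant_id", "energy_kcal"), names(ffq_items))
  item_cols <- setdiff(names(ffq_items), carried)
  unmapped <- setdiff(item_cols, names(catalog$item_mapping))
  if (length(unmapped)) {
    stop("unmapped FFQ items: ", paste(unmapped, collapse = ", "))
  }
  out <- ffq_items[, carried, drop = FALSE]
  item_mat <- as.matrix(ffq_items[, item_cols, drop = FALSE])
  grp_of <- unname(catalog$item_mapping[item_cols])
  for (g in catalog$groups) {
    cols <- item_cols[grp_of == g]
    out[[g]] <- if (length(cols)) {
      rowSums(item_mat[, cols, drop = FALSE])
    } else {
      rep(0, nrow(ffq_items))
    }
  }
  out
}
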