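#' Validate a participant-by-food-group intake table
#'
#' An intake table holds one row per participant with a unique
#' `participant_id`, a positive `energy_kcal` column (total daily energy),
#' and one non-negative, finite grams/day column per catalog group. Zero
#' intake means the group was not consumed; missing values are not allowed.
#'
#' @param table Data frame to validate.
#' @param catalog A `food_group_catalog`; the table must contain exactly its
#'   group columns (extra non-group covariate columns are permitted).
#' @param require_energy Require the `energy_kcal` column (default `TRUE`).
#' @return The table, invisibly, if valid; otherwise an error.
#' @export
validate_intake_table <- function(table, catalog, require_energy = TRUE) {
  stopifnot(is.data.frame(table), inherits(catalog, "food_group_catalog"))
  if (!"participant_id" %in% names(table)) {
    stop("intake table must have a participant_id column")
  }
  if (anyDuplicated(table$participant_id)) {
    stop("duplicate participant_id: ",
         paste(unique(table$participant_id[duplicated(table$participant_id)]),
               collapse = ", "))
  }
  missing_groups <- setdiff(catalog$groups, names(table))
  if (length(missing_groups)) {
    stop("intake table is missing catalog group columns: ",
         paste(missing_groups, collapse = ", "))
  }
  if (require_energy && !"energy_kcal" %in% names(table)) {
    stop("intake table must have an energy_kcal column")
  }
  for (g in catalog$groups) {
    x <- table[[g]]
    if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)) || any(x < 0)) {
      bad <- table$participant_id[is.na(x) | !is.finite(x) | x < 0][1]
      stop("invalid intake in group '", g, "' (participant ", bad,
           "): values must be finite and non-negative")
    }
  }
  invisible(table)
}

#' Exclude participants with implausible daily energy intake
#'
#' Keeps rows whose total daily energy intake lies within `[lo, hi]`
#' kcal/day; exclusion is strict (energy below `lo` or above `hi`), so the
#' boundary values themselves are kept. The defaults drop intakes below 500
#' or above 4000 kcal/day, the usual plausibility window for FFQ-derived
#' energy.
#'
#' @param table Intake table with an `energy_kcal` column.
#' @param lo,hi Plausibility bounds in kcal/day (`lo < hi`).
#' @param quiet Suppress the exclusion-count message.
#' @return The kept rows in their original order, with attribute
#'   `n_excluded` giving the number of rows removed.
#' @export
filter_by_energy <- function(table, lo = 500, hi = 4000, quiet = FALSE) {
  stopifnot(is.data.frame(table), lo < hi)
  if (!"energy_kcal" %in% names(table)) {
    stop("intake table must have an energy_kcal column")
  }
  e <- table$energy_kcal
  if (anyNA(e) || any(!is.finite(e)) || any(e < 0)) {
    bad <- table$participant_id[is.na(e) | !is.finite(e) | e < 0][1]
    stop("missing or negative energy_kcal for participant ", bad)
  }
  keep <- e >= lo & e <= hi
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!keep)
  if (!quiet) {
    message("filter_by_energy: excluded ", sum(!keep), " of ", nrow(table),
            " participants outside [", lo, ", ", hi, "] kcal/day")
  }
  out
}

#' Read an intake CSV
#'
#' Expects the header `participant_id,energy_kcal,<group_1>,...,<group_k>`
#' with zeros explicit (no missing values). Columns are checked against the
#' catalog.
#'
#' @param path CSV path.
#' @param catalog A `food_group_catalog`.
#' @return A validated intake table.
#' @export
read_intake_csv <- function(path, catalog = default_catalog()) {
  if (!file.exists(path)) stop("intake file not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  tab$participant_id <- as.character(tab$participant_id)
  validate_intake_table(tab, catalog)
  tab
}

#' Write an intake CSV
#'
#' @param table Intake table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intake_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
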