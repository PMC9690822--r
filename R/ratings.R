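#' Rating matrix constructor
#'
#' A rating matrix is a users-by-items numeric matrix with observed entries
#' in \{1,...,5\} and `NA` for missing cells. A cell is missing exactly when
#' the participant did not consume the group (zero intake); missing cells
#' are the recommendation candidates.
#'
#' @param m Numeric matrix with dimnames (users in rows, items in columns);
#'   observed values must be integers in 1..5.
#' @return An object of class `rating_matrix`.
#' @export
rating_matrix <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("rating matrix must have user rownames and item colnames")
  }
  obs <- m[!is.na(m)]
  if (length(obs) && (any(obs < 1 | obs > 5) || any(obs != round(obs)))) {
    stop("observed ratings must be integers in {1,...,5}")
  }
  structure(m, class = c("rating_matrix", "matrix", "array"))
}

#' @export
print.rating_matrix <- function(x, ...) {
  cat("Rating matrix:", nrow(x), "users x", ncol(x), "items; ",
      sum(!is.na(x)), "observed cells (",
      round(100 * mean(!is.na(x)), 1), "% dense)\n", sep = " ")
  invisible(x)
}

# Rank-based quintile rating for one item's positive intakes.
# Average ranks so tied values always share a rating; a lone consumer sits
# at quantile position 0.5 and gets the middle rating 3.
.quintile_of_ranks <- function(x) {
  n <- length(x)
  r <- rank(x, ties.method = "average")
  q <- ceiling(5 * (r - 0.5) / n)
  pmin(pmax(q, 1L), 5L)
}

#' Discretize intake into 1-5 quintile ratings
#'
#' For each food group independently, participants who consumed the group
#' (intake > 0) are ranked and assigned a rating 1-5 by quintile of that
#' group's consumer distribution; zero intake becomes a missing cell
#' (a recommendation candidate), not a low rating. Ties share average ranks
#' and therefore always share a rating.
#'
#' Per-group intake cutpoints (the 20/40/60/80% consumer quantiles) are
#' attached as attribute `cutpoints` so the discretization learned on one
#' partition can be frozen and applied to new participants with
#' [quintile_transform()].
#'
#' @param table Intake table (validated against `catalog`).
#' @param catalog A `food_group_catalog`; its groups become the items.
#' @param warn Warn on degenerate groups (no consumers, or fewer than 5
#'   distinct positive values).
#' @return A `rating_matrix` with attribute `cutpoints` (named list of
#'   length-4 numeric vectors, `NULL` for groups with no consumers).
#' @export
quintile_ratings <- function(table, catalog = default_catalog(), warn = TRUE) {
  validate_intake_table(table, catalog, require_energy = FALSE)
  if (nrow(table) == 0) stop("intake table is empty")
  users <- as.character(table$participant_id)
  m <- matrix(NA_real_, nrow(table), length(catalog$groups),
              dimnames = list(users, catalog$groups))
  cutpoints <- stats::setNames(vector("list", length(catalog$groups)),
                               catalog$groups)
  for (g in catalog$groups) {
    x <- table[[g]]
    consumed <- x > 0
    if (!any(consumed)) {
      if (warn) warning("group '", g, "' has no consumers; all cells missing")
      next
    }
    xv <- x[consumed]
    if (warn && length(unique(xv)) < 5) {
      warning("group '", g, "' has fewer than 5 distinct positive intakes; ",
              "quintile ratings assigned by the tie rule")
    }
    m[consumed, g] <- .quintile_of_ranks(xv)
    cutpoints[[g]] <- unname(stats::quantile(xv, c(0.2, 0.4, 0.6, 0.8)))
  }
  out <- rating_matrix(m)
  attr(out, "cutpoints") <- cutpoints
  out
}

#' Apply frozen quintile cutpoints to new participants
#'
#' Transforms an intake table into ratings using per-group cutpoints learned
#' elsewhere (e.g. on a training partition, via the `cutpoints` attribute of
#' [quintile_ratings()]). Intakes outside the learned range clamp to rating
#' 1 or 5; zero intake is missing, as always.
#'
#' @param table Intake table.
#' @param cutpoints Named list of length-4 ascending numeric vectors per
#'   group (20/40/60/80% consumer quantiles); `NULL` entries give all-missing
#'   columns.
#' @param catalog A `food_group_catalog`.
#' @return A `rating_matrix` for the new participants.
#' @export
quintile_transform <- function(table, cutpoints, catalog = default_catalog()) {
  validate_intake_table(table, catalog, require_energy = FALSE)
  stopifnot(all(catalog$groups %in% names(cutpoints)))
  users <- as.character(table$participant_id)
  m <- matrix(NA_real_, nrow(table), length(catalog$groups),
              dimnames = list(users, catalog$groups))
  for (g in catalog$groups) {
    cp <- cutpoints[[g]]
    if (is.null(cp)) next
    x <- table[[g]]
    consumed <- x > 0
    m[consumed, g] <- 1L + findInterval(x[consumed], cp)
  }
  rating_matrix(m)
}

#' Serialize a rating matrix to long-format CSV
#'
#' Writes observed cells only, as `user,item,rating`.
#'
#' @param R A `rating_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rating_matrix <- function(R, path) {
  idx <- which(!is.na(R), arr.ind = TRUE)
  long <- data.frame(user = rownames(R)[idx[, 1]],
                     item = colnames(R)[idx[, 2]],
                     rating = R[idx])
  long <- long[order(match(long$user, rownames(R)),
                     match(long$item, colnames(R))), ]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a rating matrix from long-format CSV
#'
#' @param path CSV with columns `user,item,rating` (observed cells only).
#' @param users,items Optional full user/item sets (and order); defaults to
#'   order of first appearance in the file. Supply these to retain users or
#'   items with no observed cells.
#' @return A `rating_matrix`.
#' @export
read_rating_matrix <- function(path, users = NULL, items = NULL) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("user", "item", "rating") %in% names(long)))
  long$user <- as.character(long$user)
  if (is.null(users)) users <- unique(long$user)
  if (is.null(items)) items <- unique(long$item)
  m <- matrix(NA_real_, length(users), length(items),
              dimnames = list(users, items))
  m[cbind(match(long$user, users), match(long$item, items))] <-
    as.numeric(long$rating)
  rating_matrix(m)
}
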