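#' Top-N dietary recommendation lists
#'
#' Orders each user's recommendation candidates — cells that were missing in
#' the source rating matrix and received a predicted rating — by predicted
#' rating (highest first, ties broken by catalog order) and keeps at most
#' `n_max` of them. With `eligible_only = TRUE` (production mode) candidates
#' are first restricted to the catalog's eligible groups, so a highly rated
#' but discouraged group (say, soft drinks) is never recommended; evaluation
#' protocols that score all groups should set `eligible_only = FALSE`.
#'
#' Observed (consumed) items are never recommended; unpredictable cells have
#' no score and are excluded. Users with no candidates get an empty list.
#'
#' @param P A `predicted_ratings` object.
#' @param catalog A `food_group_catalog`; its group order breaks ties.
#' @param n_max Maximum list length (default 5, the production cap).
#' @param eligible_only Restrict candidates to `catalog$eligible`.
#' @return A data frame `user, rank, item, predicted_rating`, class
#'   `recommendation_list`, with users in input order and ranks 1..n per
#'   user. Attribute `n_max` records the cap.
#' @export
top_n_recommend <- function(P, catalog = default_catalog(), n_max = 5,
                            eligible_only = TRUE) {
  stopifnot(inherits(P, "predicted_ratings"))
  if (n_max < 1) stop("n_max must be >= 1")
  m <- P$ratings
  stopifnot(identical(colnames(m), catalog$groups))
  item_ok <- if (eligible_only) colnames(m) %in% catalog$eligible
             else rep(TRUE, ncol(m))
  rows <- vector("list", nrow(m))
  for (u in seq_len(nrow(m))) {
    cand <- which(P$provenance[u, ] == "predicted" & item_ok)
    if (!length(cand)) next
    # sort by predicted rating desc; ties by catalog (column) order
    ord <- cand[order(-m[u, cand], cand)]
    keep <- ord[seq_len(min(n_max, length(ord)))]
    rows[[u]] <- data.frame(user = rownames(m)[u],
                            rank = seq_along(keep),
                            item = colnames(m)[keep],
                            predicted_rating = unname(m[u, keep]))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(user = character(), rank = integer(),
                      item = character(), predicted_rating = numeric())
  }
  rownames(out) <- NULL
  attr(out, "n_max") <- n_max
  attr(out, "users") <- rownames(m)
  class(out) <- c("recommendation_list", "data.frame")
  out
}

#' Write recommendations to CSV
#'
#' @param recs A `recommendation_list` (from [top_n_recommend()]).
#' @param path Output CSV path (`user,rank,item,predicted_rating`).
#' @return `path`, invisibly.
#' @export
write_recommendations <- function(recs, path) {
  utils::write.csv(as.data.frame(recs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
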