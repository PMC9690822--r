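#' Predicted-ratings container
#'
#' Dense user-by-item values on the 1-5 scale with a per-cell provenance
#' flag: `"observed"` cells pass through from the input rating matrix,
#' `"predicted"` cells were filled by collaborative filtering, and
#' `"unpredictable"` cells were missing but had no usable neighbors (their
#' value stays `NA`; they are never silently filled).
#'
#' @param ratings Numeric user x item matrix.
#' @param provenance Character matrix of the same shape with entries
#'   `observed`, `predicted` or `unpredictable`.
#' @param method Label of the producing method.
#' @return An object of class `predicted_ratings`.
#' @keywords internal
predicted_ratings <- function(ratings, provenance, method) {
  stopifnot(identical(dim(ratings), dim(provenance)),
            all(provenance %in% c("observed", "predicted", "unpredictable")))
  pred <- ratings[provenance == "predicted"]
  stopifnot(!anyNA(pred), all(pred >= 1), all(pred <= 5))
  structure(list(ratings = ratings, provenance = provenance, method = method),
            class = "predicted_ratings")
}

#' @export
print.predicted_ratings <- function(x, ...) {
  tab <- table(factor(x$provenance,
                      c("observed", "predicted", "unpredictable")))
  cat("Predicted ratings (", x$method, "): ", nrow(x$ratings), " users x ",
      ncol(x$ratings), " items; ", tab[["observed"]], " observed, ",
      tab[["predicted"]], " predicted, ", tab[["unpredictable"]],
      " unpredictable\n", sep = "")
  invisible(x)
}

# Order candidate neighbors by similarity (descending), ties broken by
# original index for reproducibility, and keep the top k.
.top_k <- function(sim_values, candidate_idx, k) {
  ord <- order(-sim_values, candidate_idx)
  candidate_idx[ord][seq_len(min(k, length(candidate_idx)))]
}

#' User-based collaborative-filtering prediction
#'
#' Fills each missing cell (user u, item i) from the `k_neighbors` most
#' similar users who rated i, with the mean-centered weighted aggregate
#' \deqn{\hat r_{ui} = \bar r_u + \frac{\sum_v s_{uv} (r_{vi} - \bar r_v)}
#' {\sum_v |s_{uv}|}}{r_ui = rbar_u + sum_v s_uv (r_vi - rbar_v) / sum_v |s_uv|}
#' clamped to [1, 5]. Centering on each user's mean rating corrects
#' between-user differences in how the rating scale is used. Cells with no
#' usable neighbor (no defined — and, with `positive_only`, positive —
#' similarity to any rater of i, or a zero weight sum) are flagged
#' unpredictable.
#'
#' @param R A `rating_matrix`.
#' @param S A user-axis `similarity_matrix` computed on the same users.
#' @param cfg A `neighborhood_config` (method `"UBCF"`).
#' @param neighbors Optional character or integer vector restricting which
#'   users may serve as neighbors (e.g. training users only in a train/test
#'   evaluation). Defaults to all users.
#' @param users Optional subset of users to predict for (default all).
#' @return A `predicted_ratings` object.
#' @export
predict_ubcf <- function(R, S, cfg = neighborhood_config("UBCF"),
                         neighbors = NULL, users = NULL) {
  stopifnot(inherits(R, "rating_matrix"), inherits(S, "similarity_matrix"),
            S$axis == "user",
            identical(rownames(S$sim), rownames(R)))
  M <- unclass(R)
  n_users <- nrow(M)
  neigh_idx <- if (is.null(neighbors)) seq_len(n_users) else {
    if (is.character(neighbors)) match(neighbors, rownames(M)) else neighbors
  }
  stopifnot(!anyNA(neigh_idx))
  target_idx <- if (is.null(users)) seq_len(n_users) else {
    if (is.character(users)) match(users, rownames(M)) else users
  }
  user_means <- rowMeans(M, na.rm = TRUE)   # NaN for users with no ratings

  out <- M
  prov <- matrix("observed", nrow(M), ncol(M), dimnames = dimnames(M))
  prov[is.na(M)] <- "unpredictable"
  for (u in target_idx) {
    missing_items <- which(is.na(M[u, ]))
    if (!length(missing_items)) next
    if (all(is.na(M[u, ]))) {
      warning("user '", rownames(M)[u],
              "' has no observed ratings; all cells unpredictable")
      next
    }
    s_u <- S$sim[u, ]
    usable <- !is.na(s_u)
    usable[u] <- FALSE
    usable[-neigh_idx] <- FALSE
    if (cfg$positive_only) usable <- usable & s_u > 0
    if (!any(usable)) next
    for (i in missing_items) {
      raters <- which(usable & !is.na(M[, i]))
      if (!length(raters)) next
      top <- .top_k(s_u[raters], raters, cfg$k_neighbors)
      w <- s_u[top]
      denom <- sum(abs(w))
      if (denom <= 0) next
      est <- user_means[u] + sum(w * (M[top, i] - user_means[top])) / denom
      out[u, i] <- min(max(est, 1), 5)
      prov[u, i] <- "predicted"
    }
  }
  predicted_ratings(out, prov, "UBCF")
}

#' Item-based collaborative-filtering prediction
#'
#' Fills each missing cell (user u, item i) from the `k_neighbors` items
#' most similar to i that u has rated, with the weighted average
#' \deqn{\hat r_{ui} = \frac{\sum_j s_{ij} r_{uj}}{\sum_j |s_{ij}|}}{
#' r_ui = sum_j s_ij r_uj / sum_j |s_ij|}
#' clamped to [1, 5]. Cells with no usable similar item are flagged
#' unpredictable.
#'
#' @param R A `rating_matrix` (the users to predict for; may differ from the
#'   matrix the item similarities were learned on).
#' @param S An item-axis `similarity_matrix` over the same items as `R`.
#' @param cfg A `neighborhood_config` (method `"IBCF"`).
#' @return A `predicted_ratings` object.
#' @export
predict_ibcf <- function(R, S, cfg = neighborhood_config("IBCF")) {
  stopifnot(inherits(R, "rating_matrix"), inherits(S, "similarity_matrix"),
            S$axis == "item",
            identical(rownames(S$sim), colnames(R)))
  M <- unclass(R)
  out <- M
  prov <- matrix("observed", nrow(M), ncol(M), dimnames = dimnames(M))
  prov[is.na(M)] <- "unpredictable"
  for (u in seq_len(nrow(M))) {
    rated <- which(!is.na(M[u, ]))
    missing_items <- which(is.na(M[u, ]))
    if (!length(missing_items)) next
    if (!length(rated)) {
      warning("user '", rownames(M)[u],
              "' has no observed ratings; all cells unpredictable")
      next
    }
    for (i in missing_items) {
      s_i <- S$sim[i, rated]
      usable <- !is.na(s_i)
      if (cfg$positive_only) usable <- usable & s_i > 0
      if (!any(usable)) next
      cand <- rated[usable]
      top <- .top_k(S$sim[i, cand], cand, cfg$k_neighbors)
      w <- S$sim[i, top]
      denom <- sum(abs(w))
      if (denom <= 0) next
      est <- sum(w * M[u, top]) / denom
      out[u, i] <- min(max(est, 1), 5)
      prov[u, i] <- "predicted"
    }
  }
  predicted_ratings(out, prov, "IBCF")
}

#' Export predictions as long-format CSV
#'
#' Writes `user,item,predicted_rating,provenance` for every cell.
#'
#' @param P A `predicted_ratings` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(P, path) {
  stopifnot(inherits(P, "predicted_ratings"))
  m <- P$ratings
  long <- data.frame(
    user = rep(rownames(m), times = ncol(m)),
    item = rep(colnames(m), each = nrow(m)),
    predicted_rating = as.vector(m),
    provenance = as.vector(P$provenance)
  )
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
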