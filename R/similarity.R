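#' Pairwise Pearson similarity over co-rated cells
#'
#' Computes the Pearson correlation between every pair of users (rows) or
#' items (columns) of a rating matrix, using only the cells observed by both
#' members of the pair. A pair is undefined (`NA`) when fewer than
#' `min_overlap` cells are co-observed or when either side has zero variance
#' on the overlap. The diagonal is 1 for any entity with at least one
#' observed rating.
#'
#' The computation is vectorized with masked cross-products; it matches a
#' per-pair `cor()` loop to numerical precision.
#'
#' @param R A `rating_matrix`.
#' @param axis `"user"` for user-user similarity, `"item"` for item-item.
#' @param min_overlap Minimum number of co-observed cells for a defined
#'   similarity (default 3).
#' @return An object of class `similarity_matrix`: list with `sim`
#'   (symmetric matrix, `NA` where undefined), `overlap` (co-observation
#'   counts) and `axis`.
#' @export
pearson_similarity <- function(R, axis = c("user", "item"), min_overlap = 3) {
  axis <- match.arg(axis)
  stopifnot(inherits(R, "rating_matrix"), min_overlap >= 1)
  M <- unclass(R)
  if (axis == "item") M <- t(M)
  if (nrow(M) < 2) stop("need at least 2 ", axis, "s to compute similarity")

  W <- !is.na(M)           # observation mask
  X <- ifelse(W, M, 0)
  Wn <- W * 1
  n   <- tcrossprod(Wn)              # overlap counts
  Sx  <- tcrossprod(X, Wn)           # sum of a's ratings over co-observed cells
  Sxx <- tcrossprod(X^2, Wn)
  Sxy <- tcrossprod(X)
  # pairwise-complete moments: cov and variances on the overlap
  with_n <- n > 0
  cov  <- Sxy - Sx * t(Sx) / ifelse(with_n, n, 1)
  varx <- Sxx - Sx^2 / ifelse(with_n, n, 1)
  vary <- t(varx)
  eps <- 1e-12
  denom <- sqrt(pmax(varx, 0) * pmax(vary, 0))
  sim <- ifelse(denom > eps, cov / denom, NA_real_)
  sim[n < min_overlap] <- NA_real_
  sim[!with_n] <- NA_real_
  sim <- pmin(pmax(sim, -1), 1)
  # self-similarity is 1 whenever the entity has any rating at all
  rated <- rowSums(W) > 0
  diag(sim) <- ifelse(rated, 1, NA_real_)
  dimnames(sim) <- list(rownames(M), rownames(M))
  dimnames(n) <- dimnames(sim)
  structure(list(sim = sim, overlap = n, axis = axis,
                 min_overlap = min_overlap),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  p <- nrow(x$sim)
  off <- x$sim[upper.tri(x$sim)]
  cat("Pearson similarity (", x$axis, "-", x$axis, "): ", p, " x ", p,
      "; ", round(100 * mean(!is.na(off)), 1), "% of pairs defined",
      " (min_overlap = ", x$min_overlap, ")\n", sep = "")
  invisible(x)
}

#' Neighborhood configuration for k-NN collaborative filtering
#'
#' @param method `"UBCF"` (user-based) or `"IBCF"` (item-based).
#' @param k_neighbors Number of most-similar neighbors aggregated per
#'   prediction. Defaults: 25 for UBCF, 30 for IBCF.
#' @param min_overlap Minimum co-rated cells for a defined similarity.
#' @param positive_only Drop non-positive similarities from neighborhoods
#'   (default `TRUE`): aggregating ratings with negative weights is
#'   ill-behaved on a 1-5 scale.
#' @return An object of class `neighborhood_config`.
#' @export
neighborhood_config <- function(method = c("UBCF", "IBCF"),
                                k_neighbors = NULL,
                                min_overlap = 3,
                                positive_only = TRUE) {
  method <- match.arg(method)
  if (is.null(k_neighbors)) k_neighbors <- if (method == "UBCF") 25L else 30L
  stopifnot(k_neighbors >= 1, min_overlap >= 2)
  structure(list(method = method, k_neighbors = as.integer(k_neighbors),
                 min_overlap = as.integer(min_overlap),
                 positive_only = isTRUE(positive_only)),
            class = "neighborhood_config")
}
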