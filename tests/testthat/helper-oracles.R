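# Independent, deliberately naive reference implementations used to check
# the vectorized code, plus small fixture builders. Everything here is
# loop-based and leans on base R (cor, sort) rather than the package's own
# internals.

# random partially observed rating matrix
random_rating_matrix <- function(n_users, n_items, density = 0.7, seed = 1) {
  set.seed(seed)
  m <- matrix(as.numeric(sample(1:5, n_users * n_items, replace = TRUE)),
              n_users, n_items,
              dimnames = list(paste0("u", seq_len(n_users)),
                              paste0("i", seq_len(n_items))))
  m[matrix(runif(n_users * n_items) > density, n_users, n_items)] <- NA
  rating_matrix(m)
}

# pairwise Pearson over co-observed cells, one cor() call per pair
oracle_pearson <- function(R, axis = "user", min_overlap = 3) {
  M <- unclass(R)
  if (axis == "item") M <- t(M)
  p <- nrow(M)
  sim <- matrix(NA_real_, p, p, dimnames = list(rownames(M), rownames(M)))
  for (a in seq_len(p)) {
    for (b in seq_len(p)) {
      both <- !is.na(M[a, ]) & !is.na(M[b, ])
      if (a == b) {
        if (any(!is.na(M[a, ]))) sim[a, b] <- 1
        next
      }
      if (sum(both) < min_overlap) next
      x <- M[a, both]; y <- M[b, both]
      if (sd(x) == 0 || sd(y) == 0) next
      sim[a, b] <- cor(x, y)
    }
  }
  sim
}

# naive UBCF: per missing cell, rank candidate neighbors by similarity
# (ties by index), take k, apply the mean-centered weighted aggregate
oracle_ubcf <- function(R, sim, k, positive_only = TRUE, neighbors = NULL) {
  M <- unclass(R)
  if (is.null(neighbors)) neighbors <- seq_len(nrow(M))
  means <- rowMeans(M, na.rm = TRUE)
  out <- M
  for (u in seq_len(nrow(M))) {
    if (all(is.na(M[u, ]))) next
    for (i in seq_len(ncol(M))) {
      if (!is.na(M[u, i])) next
      cand <- setdiff(neighbors, u)
      cand <- cand[!is.na(sim[u, cand]) & !is.na(M[cand, i])]
      if (positive_only) cand <- cand[sim[u, cand] > 0]
      if (!length(cand)) next
      cand <- cand[order(-sim[u, cand], cand)]
      top <- cand[seq_len(min(k, length(cand)))]
      w <- sim[u, top]
      if (sum(abs(w)) <= 0) next
      est <- means[u] + sum(w * (M[top, i] - means[top])) / sum(abs(w))
      out[u, i] <- min(max(est, 1), 5)
    }
  }
  out
}

# naive IBCF: weighted average of the user's rated items most similar to i
oracle_ibcf <- function(R, sim, k, positive_only = TRUE) {
  M <- unclass(R)
  out <- M
  for (u in seq_len(nrow(M))) {
    rated <- which(!is.na(M[u, ]))
    if (!length(rated)) next
    for (i in seq_len(ncol(M))) {
      if (!is.na(M[u, i])) next
      cand <- rated[!is.na(sim[i, rated])]
      if (positive_only) cand <- cand[sim[i, cand] > 0]
      if (!length(cand)) next
      cand <- cand[order(-sim[i, cand], cand)]
      top <- cand[seq_len(min(k, length(cand)))]
      w <- sim[i, top]
      if (sum(abs(w)) <= 0) next
      out[u, i] <- min(max(sum(w * M[u, top]) / sum(abs(w)), 1), 5)
    }
  }
  out
}

# small intake table over a tiny catalog
tiny_catalog <- function(n_groups = 4, n_eligible = min(2, n_groups)) {
  groups <- paste0("g", seq_len(n_groups))
  food_group_catalog(groups, groups[seq_len(min(n_eligible, n_groups))])
}

tiny_intake <- function(m, energy = NULL) {
  tab <- data.frame(participant_id = paste0("p", seq_len(nrow(m))))
  if (!is.null(energy)) tab$energy_kcal <- energy
  for (j in seq_len(ncol(m))) tab[[paste0("g", j)]] <- m[, j]
  tab
}

# a predicted_ratings object built directly from matrices (test fixture)
make_predictions <- function(ratings, provenance, method = "UBCF") {
  ffqrec:::predicted_ratings(ratings, provenance, method)
}
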