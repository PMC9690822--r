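make_R <- function(m) {
  dimnames(m) <- list(paste0("u", seq_len(nrow(m))),
                      paste0("i", seq_len(ncol(m))))
  rating_matrix(m)
}

test_that("UBCF with one perfect neighbor and equal means passes ratings through", {
  # u1 and u2 identical on i1..i4 (sim = 1, equal means); u2 also rated i5
  m <- rbind(c(2, 3, 4, 3, NA),
             c(2, 3, 4, 3, 5),
             c(1, 1, NA, NA, 1))
  R <- make_R(m)
  S <- pearson_similarity(R, "user", min_overlap = 3)
  cfg <- neighborhood_config("UBCF", k_neighbors = 1)
  P <- predict_ubcf(R, S, cfg)
  # r_u1 bar = 3, r_u2 bar (on its ratings) = 3.4; with sim 1 and k = 1:
  # 3 + (5 - 3.4) = 4.6
  expect_equal(P$ratings["u1", "i5"], 4.6)
  expect_equal(P$provenance["u1", "i5"], "predicted")
})

test_that("UBCF with two equally similar neighbors of equal mean averages them", {
  m <- rbind(c(1, 2, 3, 4, NA),
             c(1, 2, 3, 4, 2),
             c(1, 2, 3, 4, 4))
  R <- make_R(m)
  S <- pearson_similarity(R, "user", min_overlap = 3)
  cfg <- neighborhood_config("UBCF", k_neighbors = 2)
  P <- predict_ubcf(R, S, cfg)
  # both neighbors sim = 1; centered contributions average: 2.5 +
  # ((2 - 2.4) + (4 - 2.8)) / 2 = 2.9
  mu <- mean(c(1, 2, 3, 4))
  expected <- mu + ((2 - mean(c(1, 2, 3, 4, 2))) +
                      (4 - mean(c(1, 2, 3, 4, 4)))) / 2
  expect_equal(P$ratings["u1", "i5"], expected)
})

test_that("IBCF pass-through and symmetry anchors hold", {
  # i1 and i2 perfectly correlated (shifted copies) across u2..u4;
  # u1 rated i1 only, so the single similar item passes its rating through
  m <- rbind(c(3, NA, NA),
             c(1, 2, 5),
             c(2, 3, 1),
             c(4, 5, 2))
  R <- make_R(m)
  S <- pearson_similarity(R, "item", min_overlap = 3)
  expect_equal(S$sim["i1", "i2"], 1)
  cfg <- neighborhood_config("IBCF", k_neighbors = 1)
  P <- predict_ibcf(R, S, cfg)
  expect_equal(P$provenance["u1", "i2"], "predicted")
  expect_equal(P$ratings["u1", "i2"], 3)
  # two similar items with equal positive similarity -> mean of ratings
  sim <- matrix(NA_real_, 3, 3, dimnames = list(colnames(R), colnames(R)))
  diag(sim) <- 1
  sim["i3", "i1"] <- sim["i1", "i3"] <- 0.5
  sim["i3", "i2"] <- sim["i2", "i3"] <- 0.5
  S_fixed <- structure(list(sim = sim, overlap = sim, axis = "item",
                            min_overlap = 2), class = "similarity_matrix")
  m2 <- rbind(c(2, 4, NA))
  R2 <- make_R(m2)
  P2 <- predict_ibcf(R2, S_fixed, neighborhood_config("IBCF"))
  expect_equal(P2$ratings["u1", "i3"], 3)
})

test_that("vectorized predictors match the naive loop oracles", {
  for (seed in 1:8) {
    R <- random_rating_matrix(8, 6, density = 0.65, seed = seed)
    S_u <- pearson_similarity(R, "user", min_overlap = 3)
    S_i <- pearson_similarity(R, "item", min_overlap = 3)
    for (k in c(1, 3, 25)) {
      cfg_u <- neighborhood_config("UBCF", k)
      cfg_i <- neighborhood_config("IBCF", k)
      got_u <- suppressWarnings(predict_ubcf(R, S_u, cfg_u))
      got_i <- suppressWarnings(predict_ibcf(R, S_i, cfg_i))
      expect_equal(got_u$ratings, oracle_ubcf(R, S_u$sim, k),
                   tolerance = 1e-9)
      expect_equal(got_i$ratings, oracle_ibcf(R, S_i$sim, k),
                   tolerance = 1e-9)
    }
  }
})

test_that("predictions are deterministic and permutation-equivariant", {
  R <- random_rating_matrix(10, 7, density = 0.6, seed = 5)
  S <- pearson_similarity(R, "user", min_overlap = 3)
  cfg <- neighborhood_config("UBCF", 3)
  P1 <- suppressWarnings(predict_ubcf(R, S, cfg))
  P2 <- suppressWarnings(predict_ubcf(R, S, cfg))
  expect_identical(P1$ratings, P2$ratings)

  # permute users; predictions permute identically (neighbor ties are
  # broken by similarity then index, and this fixture has no exact ties)
  perm <- c(3, 1, 4, 2, 5, 10, 8, 6, 9, 7)
  Rp <- rating_matrix(unclass(R)[perm, ])
  Sp <- pearson_similarity(Rp, "user", min_overlap = 3)
  Pp <- suppressWarnings(predict_ubcf(Rp, Sp, cfg))
  expect_equal(Pp$ratings, P1$ratings[perm, ], tolerance = 1e-12)
})

test_that("predicted values stay on the rating scale and flags are honest", {
  for (seed in 1:5) {
    R <- random_rating_matrix(9, 6, density = 0.5, seed = seed + 50)
    S <- pearson_similarity(R, "user", min_overlap = 2)
    P <- suppressWarnings(predict_ubcf(R, S, neighborhood_config("UBCF", 5)))
    pred <- P$ratings[P$provenance == "predicted"]
    expect_true(all(pred >= 1 & pred <= 5))
    # observed cells pass through unchanged
    obs <- P$provenance == "observed"
    expect_identical(P$ratings[obs], unclass(R)[obs])
    # unpredictable cells stay NA
    expect_true(all(is.na(P$ratings[P$provenance == "unpredictable"])))
  }
})

test_that("a user with no observed ratings is warned about and unpredictable", {
  m <- rbind(c(NA, NA, NA),
             c(1, 2, 3),
             c(2, 3, 4),
             c(3, 4, 5))
  R <- make_R(m)
  S <- pearson_similarity(R, "user", min_overlap = 3)
  expect_warning(P <- predict_ubcf(R, S, neighborhood_config("UBCF")),
                 "no observed ratings")
  expect_true(all(P$provenance["u1", ] == "unpredictable"))
})
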