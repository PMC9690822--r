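test_that("user split is reproducible and has the expected sizes", {
  R <- random_rating_matrix(100, 21, density = 0.95, seed = 2)
  sch <- evaluation_scheme(train_fraction = 0.7, given = 10, seed = 77)
  sp1 <- split_scheme(R, sch)
  sp2 <- split_scheme(R, sch)
  expect_length(sp1$train_users, 70)
  expect_length(sp1$test_users, 30)
  expect_identical(sp1$train_users, sp2$train_users)
  expect_identical(unclass(sp1$test_given), unclass(sp2$test_given))
})

test_that("per-user given/withheld cells partition the observed cells", {
  R <- random_rating_matrix(60, 21, density = 0.9, seed = 6)
  sch <- evaluation_scheme(given = 10, seed = 5)
  sp <- suppressWarnings(split_scheme(R, sch))
  for (u in sp$test_users) {
    obs <- which(!is.na(unclass(R)[u, ]))
    kept <- which(!is.na(unclass(sp$test_given)[u, ]))
    withheld <- which(!is.na(unclass(sp$test_withheld)[u, ]))
    # independent set-difference scan
    expect_length(kept, 10)
    expect_length(intersect(kept, withheld), 0)
    expect_setequal(union(kept, withheld), obs)
    expect_equal(unclass(sp$test_given)[u, kept], unclass(R)[u, kept])
    expect_equal(unclass(sp$test_withheld)[u, withheld],
                 unclass(R)[u, withheld])
  }
})

test_that("test users without enough observed ratings are dropped loudly", {
  set.seed(8)
  m <- matrix(sample(1:5, 40 * 21, TRUE), 40, 21,
              dimnames = list(paste0("u", 1:40), paste0("i", 1:21)))
  m[1:20, 12:21] <- NA  # these users have only 11 observed cells
  R <- rating_matrix(m)
  sch <- evaluation_scheme(given = 15, seed = 3)
  expect_warning(sp <- split_scheme(R, sch), "dropped")
  n_obs <- rowSums(!is.na(m))
  expect_true(all(n_obs[sp$test_users] > 15))
})

test_that("scheme validation rejects bad fractions", {
  expect_error(evaluation_scheme(train_fraction = 0), "train_fraction")
  expect_error(evaluation_scheme(train_fraction = 1), "train_fraction")
})

test_that("error metrics match hand values and a naive loop oracle", {
  mk_truth <- function(v) {
    rating_matrix(matrix(v, 1, length(v),
                         dimnames = list("u1", paste0("i", seq_along(v)))))
  }
  mk_pred <- function(v) {
    m <- matrix(v, 1, length(v), dimnames = list("u1", paste0("i", seq_along(v))))
    prov <- matrix("predicted", 1, length(v), dimnames = dimnames(m))
    make_predictions(m, prov)
  }
  # perfect predictions
  em <- rating_error_metrics(mk_pred(c(1, 3, 5)), mk_truth(c(1, 3, 5)))
  expect_equal(c(em$rmse, em$mse, em$mae), c(0, 0, 0))
  # unit errors
  em <- rating_error_metrics(mk_pred(c(2, 4)), mk_truth(c(1, 5)))
  expect_equal(c(em$rmse, em$mse, em$mae), c(1, 1, 1))
  # 50 random pairs against an explicit loop
  set.seed(12)
  truth <- sample(1:5, 50, TRUE)
  pred <- pmin(pmax(truth + rnorm(50), 1), 5)
  em <- rating_error_metrics(mk_pred(pred), mk_truth(truth))
  sq <- ab <- 0
  for (j in 1:50) {
    sq <- sq + (pred[j] - truth[j])^2
    ab <- ab + abs(pred[j] - truth[j])
  }
  expect_equal(em$mse, sq / 50, tolerance = 1e-12)
  expect_equal(em$rmse, sqrt(sq / 50), tolerance = 1e-12)
  expect_equal(em$mae, ab / 50, tolerance = 1e-12)
  expect_equal(em$n, 50)
})

test_that("unpredictable cells are excluded from error metrics and counted", {
  m <- matrix(c(2, NA, 4), 1, 3,
              dimnames = list("u1", c("i1", "i2", "i3")))
  prov <- matrix(c("predicted", "unpredictable", "predicted"), 1, 3,
                 dimnames = dimnames(m))
  P <- make_predictions(m, prov)
  truth <- rating_matrix(matrix(c(1, 5, 5), 1, 3, dimnames = dimnames(m)))
  em <- rating_error_metrics(P, truth)
  expect_equal(em$n, 2)
  expect_equal(em$n_unpredictable, 1)
  expect_equal(em$mae, 1)

  all_unpred <- make_predictions(
    matrix(NA_real_, 1, 3, dimnames = dimnames(m)),
    matrix("unpredictable", 1, 3, dimnames = dimnames(m)))
  expect_error(rating_error_metrics(all_unpred, truth), "no evaluable")
})

test_that("top-N confusion reproduces hand-computed set algebra", {
  items <- paste0("i", 1:11)
  users <- c("u1", "u2")
  wh <- matrix(NA_real_, 2, 11, dimnames = list(users, items))
  wh["u1", c("i1", "i2", "i3")] <- c(5, 4, 1)
  wh["u2", c("i4", "i5")] <- c(2, 3)
  withheld <- rating_matrix(wh)
  universe <- list(u1 = items, u2 = items)
  recs <- data.frame(user = c("u1", "u1", "u2", "u2"),
                     rank = c(1L, 2L, 1L, 2L),
                     item = c("i1", "i9", "i4", "i5"),
                     predicted_rating = c(5, 4, 3, 2))
  attr(recs, "n_max") <- 2
  class(recs) <- c("recommendation_list", "data.frame")
  conf <- topn_confusion(recs, withheld, universe)
  # u1: relevant {i1,i2,i3}; recommended {i1,i9} -> tp 1 fp 1 fn 2 tn 7
  # u2: relevant {i4,i5}; recommended {i4,i5} -> tp 2 fp 0 fn 0 tn 9
  expect_equal(conf$tp, 1.5)
  expect_equal(conf$fp, 0.5)
  expect_equal(conf$fn, 1)
  expect_equal(conf$tn, 8)
  expect_equal(conf$precision, 1.5 / 2)
  expect_equal(conf$recall, 1.5 / 2.5)
  expect_equal(conf$tp + conf$fp + conf$fn + conf$tn, 11)

  # per-user counts expose the raw set algebra
  pu <- topn_confusion(recs, withheld, universe, per_user = TRUE)
  expect_equal(pu$tp, c(1, 2))
  expect_equal(pu$tn, c(7, 9))
})

test_that("recommending a kept item is a protocol violation", {
  items <- paste0("i", 1:5)
  withheld <- rating_matrix(matrix(c(3, rep(NA, 4)), 1, 5,
                                   dimnames = list("u1", items)))
  universe <- list(u1 = items[1:3])  # i4, i5 were kept visible
  recs <- data.frame(user = "u1", rank = 1L, item = "i4",
                     predicted_rating = 4)
  attr(recs, "n_max") <- 1
  class(recs) <- c("recommendation_list", "data.frame")
  expect_error(topn_confusion(recs, withheld, universe),
               "protocol violation")
})

test_that("good_rating thresholds relevance", {
  items <- paste0("i", 1:6)
  withheld <- rating_matrix(matrix(c(5, 1, 2, NA, NA, NA), 1, 6,
                                   dimnames = list("u1", items)))
  universe <- list(u1 = items)
  recs <- data.frame(user = "u1", rank = 1L, item = "i1",
                     predicted_rating = 5)
  attr(recs, "n_max") <- 1
  class(recs) <- c("recommendation_list", "data.frame")
  conf_any <- topn_confusion(recs, withheld, universe, good_rating = 1)
  conf_high <- topn_confusion(recs, withheld, universe, good_rating = 4)
  expect_equal(conf_any$fn, 2)  # i2, i3 relevant at threshold 1
  expect_equal(conf_high$fn, 0) # only i1 relevant at threshold 4
})

test_that("evaluation sweep satisfies the protocol identities", {
  co <- generate_cohort(synthetic_config(n_participants = 400, seed = 21))
  intake <- filter_by_energy(co$intake, quiet = TRUE)
  R <- quintile_ratings(intake, warn = FALSE)
  ev <- evaluate_sweep(R, evaluation_scheme(seed = 13))
  for (m in names(ev$error_metrics)) {
    em <- ev$error_metrics[[m]]
    expect_equal(em$mse, em$rmse^2, tolerance = 1e-12)
    expect_lte(em$mae, em$rmse)
  }
  conf <- ev$confusion
  expect_equal(conf$precision, conf$tp / (conf$tp + conf$fp),
               tolerance = 1e-12)
  expect_equal(conf$recall, conf$tp / (conf$tp + conf$fn),
               tolerance = 1e-12)
  expect_equal(conf$tpr, conf$recall, tolerance = 1e-12)
  expect_equal(conf$fpr, conf$fp / (conf$fp + conf$tn), tolerance = 1e-12)
  for (m in unique(conf$method)) {
    cm <- conf[conf$method == m, ]
    # conservation: the averaged counts fill the candidate universe
    expect_equal(cm$tp + cm$fp + cm$fn + cm$tn,
                 rep((cm$tp + cm$fp + cm$fn + cm$tn)[1], nrow(cm)),
                 tolerance = 1e-9)
    # monotonicity in list size
    expect_true(all(diff(cm$tp) >= -1e-12))
    expect_true(all(diff(cm$fp) >= -1e-12))
    expect_true(all(diff(cm$fn) <= 1e-12))
    expect_true(all(diff(cm$tn) <= 1e-12))
    expect_true(all(diff(cm$recall) >= -1e-12))
  }
  # curve points ordered by list size trace non-decreasing TPR and FPR
  for (m in names(ev$curves)) {
    expect_true(all(diff(ev$curves[[m]]$roc[, "tpr"]) >= -1e-12))
    expect_true(all(diff(ev$curves[[m]]$roc[, "fpr"]) >= -1e-12))
  }
})

test_that("identical scheme and seed give identical reports", {
  co <- generate_cohort(synthetic_config(n_participants = 300, seed = 4))
  intake <- filter_by_energy(co$intake, quiet = TRUE)
  R <- quintile_ratings(intake, warn = FALSE)
  ev1 <- evaluate_sweep(R, evaluation_scheme(seed = 9))
  ev2 <- evaluate_sweep(R, evaluation_scheme(seed = 9))
  expect_identical(ev1$confusion, ev2$confusion)
  expect_identical(ev1$error_metrics, ev2$error_metrics)
})
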