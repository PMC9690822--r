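# Run expr with a temporary RNG state seeded by `seed`, restoring the
# caller's .Random.seed afterwards.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Withheld-item evaluation scheme
#'
#' Describes the given-x evaluation protocol: users are split at random into
#' a training and a testing partition; each test user keeps `given` observed
#' ratings visible to the recommender and the remainder are withheld as
#' prediction and relevance targets. A withheld item is relevant when its
#' true rating is at least `good_rating`; the default 1 counts any consumed
#' item as relevant ("recommended items with intake").
#'
#' @param train_fraction Proportion of users assigned to training
#'   (default 0.70).
#' @param given Number of observed ratings kept per test user (default 10).
#' @param good_rating Relevance threshold on withheld ratings (default 1).
#' @param seed Integer seed driving the random split and withholding.
#' @param list_sizes Recommendation-list sizes to sweep, ascending
#'   (default 1, 3, 5, 10).
#' @return An object of class `evaluation_scheme`.
#' @export
evaluation_scheme <- function(train_fraction = 0.70, given = 10,
                              good_rating = 1, seed = NULL,
                              list_sizes = c(1, 3, 5, 10)) {
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("train_fraction must be in (0, 1)")
  }
  stopifnot(given >= 1, good_rating >= 1, !is.unsorted(list_sizes))
  structure(list(train_fraction = train_fraction, given = as.integer(given),
                 good_rating = good_rating, seed = seed,
                 list_sizes = as.integer(list_sizes)),
            class = "evaluation_scheme")
}

#' Split a rating matrix into train / test-given / test-withheld
#'
#' Users are divided at random by `scheme$train_fraction`; for each test
#' user, exactly `scheme$given` observed cells (chosen uniformly at random)
#' stay visible in `test_given` and the rest move to `test_withheld`. Test
#' users with no more than `given` observed ratings cannot contribute a
#' withheld item and are dropped with a warning. The three parts are
#' disjoint and their union is the observed cells of the retained users.
#'
#' @param R A `rating_matrix`.
#' @param scheme An `evaluation_scheme`.
#' @return A list of class `cf_split` with `rating_matrix` elements `train`
#'   (training users, all their cells), `test_given` and `test_withheld`
#'   (test users by all items), plus `train_users` and `test_users`.
#' @export
split_scheme <- function(R, scheme) {
  stopifnot(inherits(R, "rating_matrix"), inherits(scheme, "evaluation_scheme"))
  n <- nrow(R)
  .with_seed(scheme$seed, {
    perm <- sample.int(n)
    n_train <- round(n * scheme$train_fraction)
    train_idx <- sort(perm[seq_len(n_train)])
    test_idx <- sort(perm[-seq_len(n_train)])

    n_obs <- rowSums(!is.na(R))
    droppable <- test_idx[n_obs[test_idx] <= scheme$given]
    if (length(droppable)) {
      warning(length(droppable), " test user(s) with <= given = ",
              scheme$given, " observed ratings dropped: ",
              paste(utils::head(rownames(R)[droppable], 5), collapse = ", "),
              if (length(droppable) > 5) ", ...")
      test_idx <- setdiff(test_idx, droppable)
    }

    given_m <- matrix(NA_real_, length(test_idx), ncol(R),
                      dimnames = list(rownames(R)[test_idx], colnames(R)))
    withheld_m <- given_m
    for (j in seq_along(test_idx)) {
      u <- test_idx[j]
      obs <- which(!is.na(R[u, ]))
      keep <- sort(sample(obs, scheme$given))
      given_m[j, keep] <- R[u, keep]
      wh <- setdiff(obs, keep)
      withheld_m[j, wh] <- R[u, wh]
    }
    structure(list(
      train = rating_matrix(unclass(R)[train_idx, , drop = FALSE]),
      test_given = rating_matrix(given_m),
      test_withheld = rating_matrix(withheld_m),
      train_users = rownames(R)[train_idx],
      test_users = rownames(R)[test_idx],
      scheme = scheme
    ), class = "cf_split")
  })
}

#' Rating-prediction error metrics over withheld cells
#'
#' Computes RMSE, MSE and MAE between predicted ratings and withheld true
#' ratings. Withheld cells the recommender could not predict (flagged
#' unpredictable) are excluded from the averages and their count reported.
#'
#' @param P A `predicted_ratings` covering the truth's users and items.
#' @param truth A `rating_matrix` of withheld true ratings.
#' @return A list of class `error_metrics`: `rmse`, `mse`, `mae`, `n`
#'   (evaluable pairs) and `n_unpredictable`.
#' @export
rating_error_metrics <- function(P, truth) {
  stopifnot(inherits(P, "predicted_ratings"), inherits(truth, "rating_matrix"))
  ui <- match(rownames(truth), rownames(P$ratings))
  ii <- match(colnames(truth), colnames(P$ratings))
  stopifnot(!anyNA(ui), !anyNA(ii))
  pred <- P$ratings[ui, ii, drop = FALSE]
  prov <- P$provenance[ui, ii, drop = FALSE]
  cells <- !is.na(truth)
  if (any(prov[cells] == "observed")) {
    stop("withheld cells were visible to the predictor (protocol violation)")
  }
  evaluable <- cells & prov == "predicted"
  n_unpred <- sum(cells & prov == "unpredictable")
  if (!any(evaluable)) stop("no evaluable (predicted, withheld) pairs")
  e <- pred[evaluable] - unclass(truth)[evaluable]
  structure(list(rmse = sqrt(mean(e^2)), mse = mean(e^2), mae = mean(abs(e)),
                 n = sum(evaluable), n_unpredictable = n_unpred),
            class = "error_metrics")
}

#' @export
print.error_metrics <- function(x, ...) {
  cat(sprintf("RMSE %.4f  MSE %.4f  MAE %.4f  (n = %d pairs, %d unpredictable)\n",
              x$rmse, x$mse, x$mae, x$n, x$n_unpredictable))
  invisible(x)
}

#' Top-N confusion matrix against withheld items
#'
#' Scores one recommendation run against the withheld truth, per the
#' standard top-N protocol. For each test user, with candidate universe
#' `universe[[user]]` (every item not kept visible for that user):
#' relevant = withheld items rated at least `good_rating`; TP = recommended
#' and relevant; FP = recommended, not relevant; FN = relevant, not
#' recommended; TN = the rest of the universe. Items the recommender could
#' not score count as not recommended (an abstaining recommender still loses
#' recall). Reported counts are per-user means; rates derive from the means,
#' matching how averaged contingency tables are conventionally printed.
#'
#' @param recs A `recommendation_list` built from the test users' given
#'   ratings only.
#' @param withheld A `rating_matrix` of withheld cells for the test users.
#' @param universe Named list mapping each test user to their candidate item
#'   set. Recommending an item outside its user's universe (i.e. a kept,
#'   visible item) is a protocol violation and an error.
#' @param good_rating Relevance threshold (default 1).
#' @param per_user Return the raw per-user counts instead of their means
#'   (used e.g. to attach Monte-Carlo standard errors to precision).
#' @return One-row data frame: `list_size`, per-user mean `tp`, `fp`, `fn`,
#'   `tn`, derived `precision`, `recall`, `tpr`, `fpr`, and `n_users`; or,
#'   with `per_user = TRUE`, one row per user with the raw counts and
#'   per-user rates.
#' @export
topn_confusion <- function(recs, withheld, universe, good_rating = 1,
                           per_user = FALSE) {
  stopifnot(inherits(recs, "recommendation_list"),
            inherits(withheld, "rating_matrix"))
  users <- rownames(withheld)
  stopifnot(all(users %in% names(universe)))
  rec_split <- split(recs$item, factor(recs$user, levels = users))
  tp <- fp <- fn <- tn <- numeric(length(users))
  for (j in seq_along(users)) {
    u <- users[j]
    uni <- universe[[u]]
    recd <- rec_split[[u]]
    if (length(setdiff(recd, uni))) {
      stop("protocol violation: recommendation of a kept (given) item for ",
           "user ", u, ": ", paste(setdiff(recd, uni), collapse = ", "))
    }
    wh <- unclass(withheld)[j, ]
    relevant <- names(wh)[!is.na(wh) & wh >= good_rating]
    tp[j] <- length(intersect(recd, relevant))
    fp[j] <- length(setdiff(recd, relevant))
    fn[j] <- length(setdiff(relevant, recd))
    tn[j] <- length(uni) - tp[j] - fp[j] - fn[j]
  }
  if (per_user) {
    return(confusion_rates(data.frame(
      user = users, list_size = attr(recs, "n_max"),
      tp = tp, fp = fp, fn = fn, tn = tn
    )))
  }
  confusion_rates(data.frame(
    list_size = attr(recs, "n_max"),
    tp = mean(tp), fp = mean(fp), fn = mean(fn), tn = mean(tn),
    n_users = length(users)
  ))
}

#' Derive precision/recall/TPR/FPR from confusion counts
#'
#' Adds (or recomputes) `precision = tp/(tp+fp)`, `recall = tpr =
#' tp/(tp+fn)` and `fpr = fp/(fp+tn)` on a data frame of (possibly
#' averaged) confusion counts.
#'
#' @param counts Data frame with columns `tp`, `fp`, `fn`, `tn`.
#' @return The data frame with `precision`, `recall`, `tpr`, `fpr` columns.
#' @export
confusion_rates <- function(counts) {
  stopifnot(all(c("tp", "fp", "fn", "tn") %in% names(counts)))
  counts$precision <- counts$tp / (counts$tp + counts$fp)
  counts$recall <- counts$tp / (counts$tp + counts$fn)
  counts$tpr <- counts$recall
  counts$fpr <- counts$fp / (counts$fp + counts$tn)
  counts
}

#' Expected precision of a random ranking
#'
#' Under uniformly random ranking of each user's candidate universe, the
#' expected precision at any list size is the relevant fraction of the
#' universe, `|relevant_u| / |universe_u|`, averaged over users. Used as the
#' analytic null against which collaborative filtering must show lift.
#'
#' @param withheld A `rating_matrix` of withheld cells for the test users.
#' @param universe Named list of candidate item sets per user.
#' @param good_rating Relevance threshold.
#' @return The base-rate precision (scalar).
#' @export
random_ranking_base_rate <- function(withheld, universe, good_rating = 1) {
  users <- rownames(withheld)
  rates <- vapply(seq_along(users), function(j) {
    wh <- unclass(withheld)[j, ]
    n_rel <- sum(!is.na(wh) & wh >= good_rating)
    n_rel / length(universe[[users[j]]])
  }, numeric(1))
  mean(rates)
}

# Candidate universe per test user: every item not kept visible.
.candidate_universe <- function(test_given) {
  items <- colnames(test_given)
  stats::setNames(
    lapply(seq_len(nrow(test_given)),
           function(j) items[is.na(unclass(test_given)[j, ])]),
    rownames(test_given)
  )
}

# Predicted-ratings restricted to a row subset (used to score test users).
.subset_predictions <- function(P, users) {
  idx <- match(users, rownames(P$ratings))
  predicted_ratings(P$ratings[idx, , drop = FALSE],
                    P$provenance[idx, , drop = FALSE], P$method)
}

#' Train, predict and evaluate UBCF and IBCF under the withheld-item protocol
#'
#' Runs the full evaluation: splits users by `scheme`, fits each method on
#' the training users plus the test users' given ratings, predicts the
#' missing cells of the test users, and reports rating-error metrics over
#' the withheld cells, averaged top-N confusion matrices at each list size,
#' and the ROC (FPR, TPR) and precision-recall curve points traced by the
#' list-size sweep. The confusion step scores all items (`eligible_only =
#' FALSE`): the protocol measures whether consumed items are recovered, not
#' whether they are advisable.
#'
#' A global-mean baseline (predict the overall mean training rating
#' everywhere) is evaluated on the same withheld cells for reference.
#'
#' For UBCF, user similarities are computed on the combined matrix and
#' neighborhoods are restricted to training users; for IBCF, item
#' similarities are learned on the training matrix and applied to the test
#' users' given ratings.
#'
#' @param R A `rating_matrix`.
#' @param scheme An `evaluation_scheme`.
#' @param methods Methods to evaluate (subset of `"UBCF"`, `"IBCF"`).
#' @param cfgs Optional named list of `neighborhood_config`s per method.
#' @return An object of class `cf_evaluation`: list with `error_metrics`
#'   (per method), `confusion` (data frame over method x list size),
#'   `curves` (per method: `roc` and `pr` point matrices), `baseline_rmse`,
#'   `base_rate`, `split_sizes` and the `scheme`.
#' @export
evaluate_sweep <- function(R, scheme, methods = c("UBCF", "IBCF"),
                           cfgs = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(cfgs)) {
    cfgs <- lapply(stats::setNames(methods, methods), neighborhood_config)
  }
  sp <- split_scheme(R, scheme)
  combined <- rating_matrix(rbind(unclass(sp$train), unclass(sp$test_given)))
  universe <- .candidate_universe(sp$test_given)

  error_metrics <- list()
  confusion <- list()
  curves <- list()
  for (method in methods) {
    cfg <- cfgs[[method]]
    P_test <- if (method == "UBCF") {
      S <- pearson_similarity(combined, "user", cfg$min_overlap)
      P <- predict_ubcf(combined, S, cfg, neighbors = sp$train_users,
                        users = sp$test_users)
      .subset_predictions(P, sp$test_users)
    } else {
      S <- pearson_similarity(sp$train, "item", cfg$min_overlap)
      predict_ibcf(sp$test_given, S, cfg)
    }
    error_metrics[[method]] <- rating_error_metrics(P_test, sp$test_withheld)
    conf <- do.call(rbind, lapply(scheme$list_sizes, function(n) {
      recs <- top_n_recommend(P_test, default_list_catalog(colnames(R)),
                              n_max = n, eligible_only = FALSE)
      topn_confusion(recs, sp$test_withheld, universe, scheme$good_rating)
    }))
    conf <- cbind(method = method, conf)
    confusion[[method]] <- conf
    curves[[method]] <- list(
      roc = cbind(fpr = conf$fpr, tpr = conf$tpr),
      pr = cbind(recall = conf$recall, precision = conf$precision)
    )
  }

  train_mean <- mean(unclass(combined), na.rm = TRUE)
  truth_vals <- unclass(sp$test_withheld)
  e <- train_mean - truth_vals[!is.na(truth_vals)]
  baseline_rmse <- sqrt(mean(e^2))

  structure(list(
    error_metrics = error_metrics,
    confusion = do.call(rbind, c(confusion, make.row.names = FALSE)),
    curves = curves,
    baseline_rmse = baseline_rmse,
    base_rate = random_ranking_base_rate(sp$test_withheld, universe,
                                         scheme$good_rating),
    split_sizes = c(train = length(sp$train_users),
                    test = length(sp$test_users)),
    scheme = scheme
  ), class = "cf_evaluation")
}

# Minimal catalog over the rating matrix's own items, used when the
# evaluation sweep ranks all items (no eligibility filter, catalog order =
# item order).
default_list_catalog <- function(items) {
  food_group_catalog(items, character(0))
}

#' @export
print.cf_evaluation <- function(x, ...) {
  cat("Withheld-item evaluation (train ", x$split_sizes[["train"]],
      " / test ", x$split_sizes[["test"]], " users)\n", sep = "")
  for (m in names(x$error_metrics)) {
    em <- x$error_metrics[[m]]
    cat(sprintf("  %s: RMSE %.3f  MSE %.3f  MAE %.3f\n",
                m, em$rmse, em$mse, em$mae))
  }
  cat(sprintf("  global-mean baseline RMSE %.3f; random-ranking base-rate precision %.3f\n",
              x$baseline_rmse, x$base_rate))
  print(x$confusion, digits = 3)
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param ev A `cf_evaluation`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_evaluation_json <- function(ev, path) {
  stopifnot(inherits(ev, "cf_evaluation"))
  out <- list(
    error_metrics = lapply(ev$error_metrics, function(em) {
      list(rmse = em$rmse, mse = em$mse, mae = em$mae, n = em$n,
           n_unpredictable = em$n_unpredictable)
    }),
    confusion = split(ev$confusion[setdiff(names(ev$confusion), "method")],
                      ev$confusion$method),
    curves = lapply(ev$curves, function(cv) {
      list(roc = apply(cv$roc, 1, as.list),
           pr = apply(cv$pr, 1, as.list))
    }),
    baseline_rmse = ev$baseline_rmse,
    base_rate = ev$base_rate,
    split_sizes = as.list(ev$split_sizes),
    scheme = unclass(ev$scheme)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, null = "null")
  invisible(path)
}
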