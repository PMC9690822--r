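#' Published reference confusion counts (ELSA-Brasil dietary recommender)
#'
#' The per-user mean confusion counts (TP, FP, FN, TN) published for the
#' ELSA-Brasil dietary recommender evaluation, for user-based and
#' item-based collaborative filtering at recommendation-list sizes 1, 3, 5
#' and 10 under the given-10 withheld-item protocol (candidate universe of
#' 11 of the 21 food groups per test user). The underlying participant
#' data are not publicly available, so these averaged counts are the only
#' reproducible quantities: [confusion_rates()] applied to them recovers
#' the published precision and recall to two decimals.
#'
#' Note the arithmetic signature identifying the list-size sweep: TP + FP
#' equals the list size in every row.
#'
#' @return Data frame with columns `method`, `list_size`, `tp`, `fp`,
#'   `fn`, `tn`, and the published `precision` and `recall` for
#'   comparison.
#' @export
reference_confusion_counts <- function() {
  data.frame(
    method = rep(c("UBCF", "IBCF"), each = 4),
    list_size = rep(c(1L, 3L, 5L, 10L), 2),
    tp = c(0.88, 2.70, 4.54, 9.11, 0.88, 2.66, 4.45, 9.03),
    fp = c(0.12, 0.30, 0.46, 0.89, 0.12, 0.34, 0.55, 0.97),
    fn = c(9.08, 7.25, 5.41, 0.85, 9.08, 7.30, 5.51, 0.93),
    tn = c(0.92, 0.75, 0.59, 0.15, 0.92, 0.70, 0.49, 0.07),
    precision = c(0.88, 0.90, 0.91, 0.91, 0.88, 0.89, 0.89, 0.90),
    recall = c(0.09, 0.27, 0.46, 0.91, 0.09, 0.27, 0.45, 0.91)
  )
}

#' Published reference error metrics (ELSA-Brasil dietary recommender)
#'
#' The published withheld-rating error metrics for the ELSA-Brasil dietary
#' recommender: RMSE, MSE and MAE per method. Kept for context and for the
#' MSE = RMSE^2 / MAE <= RMSE identity checks; they are not reproducible as
#' pipeline outputs because the participant data are unavailable.
#'
#' @return Data frame with columns `method`, `rmse`, `mse`, `mae`.
#' @export
reference_error_metrics <- function() {
  data.frame(method = c("UBCF", "IBCF"),
             rmse = c(1.49, 1.67),
             mse = c(2.21, 2.78),
             mae = c(1.26, 1.40))
}
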