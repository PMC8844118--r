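#' Root mean squared error between predicted suitability and 0/1 records
#'
#' @param pred predicted suitabilities.
#' @param obs observed 0/1 labels (same length).
#' @return `sqrt(mean((pred - obs)^2))`.
#' @export
rmse <- function(pred, obs) {
  if (length(pred) == 0 || length(pred) != length(obs))
    stop("pred and obs must have equal positive length")
  sqrt(mean((pred - obs)^2))
}

#' Rank-based AUC
#'
#' Probability that a random presence scores above a random absence, with
#' ties counted 0.5 — computed from midranks (Mann-Whitney form), which is
#' exactly the pair-counting definition.
#'
#' @param pred scores.
#' @param obs 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(pred, obs) {
  n1 <- sum(obs == 1); n0 <- sum(obs == 0)
  if (n1 == 0 || n0 == 0) stop("need at least one presence and one absence")
  r <- rank(pred)
  (sum(r[obs == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Best True Skill Statistic over a threshold grid
#'
#' Scans binarization thresholds (prediction >= threshold means predicted
#' presence) and returns the maximum of sensitivity + specificity - 1; ties
#' resolve to the lowest threshold.
#'
#' @param pred scores in `[0, 1]`.
#' @param obs 0/1 labels; both classes must be present.
#' @param step threshold-grid step (default 0.01).
#' @return list with `tss`, `threshold`, `sensitivity`, `specificity`.
#' @export
tss_best <- function(pred, obs, step = 0.01) {
  n1 <- sum(obs == 1); n0 <- sum(obs == 0)
  if (n1 == 0 || n0 == 0) stop("need at least one presence and one absence")
  thresholds <- seq(0, 1, by = step)
  best <- list(tss = -Inf, threshold = NA_real_, sensitivity = NA_real_,
               specificity = NA_real_)
  for (t in thresholds) {
    pp <- pred >= t
    sens <- sum(pp & obs == 1) / n1
    spec <- sum(!pp & obs == 0) / n0
    tss <- sens + spec - 1
    if (tss > best$tss + 1e-12) {
      best <- list(tss = tss, threshold = t, sensitivity = sens, specificity = spec)
    }
  }
  best
}

#' Gate models on discrimination thresholds
#'
#' A model is retained when its test AUC and TSS both meet the (inclusive)
#' minimums. An empty retained set is a legal outcome, recorded per sample.
#'
#' @param metrics data.frame with at least columns `auc` and `tss` (one row
#'   per model).
#' @param auc_min,tss_min inclusive thresholds (defaults 0.7 and 0.4).
#' @return logical vector: retained per row.
#' @export
select_models <- function(metrics, auc_min = 0.7, tss_min = 0.4) {
  metrics$auc >= auc_min & metrics$tss >= tss_min
}
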