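#' Assemble an outcome table for the factor-importance analysis
#'
#' Builds the long-format table relating a modeling outcome (standardized
#' variable importance, predicted-simulated r, or future between-version
#' difference samples) to the experimental factors. Factors with a single
#' observed level are uninformative and excluded with a warning; the
#' remaining factor columns are kept as factors and one-hot encoded at fit
#' time.
#'
#' @param df data.frame with a numeric `response` column and candidate
#'   factor columns.
#' @param factor_cols candidate factor column names (default: the standard
#'   experiment factors present in `df`).
#' @return an `outcome_table`: data.frame with `response` plus the retained
#'   factor columns (as factors), with attribute `factors`.
#' @export
assemble_outcomes <- function(df, factor_cols = NULL) {
  if (is.null(factor_cols))
    factor_cols <- intersect(c("species_tag", "version_tag", "resolution_tag",
                               "gcm_tag", "scenario_tag", "timeframe_tag"),
                             names(df))
  stopifnot("response" %in% names(df))
  if (any(!is.finite(df$response))) stop("missing/non-finite responses")
  keep <- character(0)
  for (f in factor_cols) {
    lv <- unique(df[[f]][!is.na(df[[f]])])
    if (length(lv) >= 2) keep <- c(keep, f)
    else warning("factor '", f, "' has a single level; excluded")
  }
  out <- df[, c("response", keep), drop = FALSE]
  for (f in keep) out[[f]] <- factor(out[[f]])
  structure(out, factors = keep, class = c("outcome_table", "data.frame"))
}

one_hot <- function(df, factors) {
  mats <- lapply(factors, function(f) {
    m <- stats::model.matrix(~ 0 + df[[f]])
    colnames(m) <- paste0(f, "_", levels(df[[f]]))
    m
  })
  x <- do.call(cbind, mats)
  groups <- rep(factors, vapply(mats, ncol, integer(1)))
  list(x = as.data.frame(x), groups = groups)
}

#' Random-forest factor importance with block permutation
#'
#' Fits a regression random forest of the response on the one-hot-encoded
#' factors (1000 trees, `mtry = floor(p/3)` with a minimum of 1, `p` the
#' number of encoded columns), then scores each factor by permuting all its
#' one-hot columns jointly (level coherence preserved): raw importance is
#' the mean over `n_perm` permutations of
#' `1 - cor(pred_original, pred_permuted)`, negatives clipped, standardized
#' to percent of the total. A constant response gives an all-zero, flagged
#' result.
#'
#' @param table an [assemble_outcomes()] table (>= 50 rows).
#' @param n_trees forest size (default 1000).
#' @param mtry variables tried per split; default `max(1, floor(p/3))`.
#' @param n_perm permutations per factor (default 5).
#' @param seed integer seed.
#' @return data.frame `factor`, `mean_importance` (percent), `sd_importance`
#'   (sd over the permutation repeats, on the same percent scale), plus
#'   attribute `flagged` (TRUE when the response was constant).
#' @export
rf_factor_importance <- function(table, n_trees = 1000, mtry = NULL,
                                 n_perm = 5, seed = 1L) {
  stopifnot(inherits(table, "outcome_table"))
  if (nrow(table) < 50) stop("need >= 50 rows")
  factors <- attr(table, "factors")
  if (length(factors) < 1) stop("no informative factor")
  if (stats::sd(table$response) == 0) {
    out <- data.frame(factor = factors, mean_importance = 0, sd_importance = 0)
    attr(out, "flagged") <- TRUE
    return(out)
  }
  enc <- one_hot(table, factors)
  if (is.null(mtry)) mtry <- max(1L, floor(ncol(enc$x) / 3))
  set.seed(derive_seed(seed, "rf_factor"))
  rf <- randomForest::randomForest(x = enc$x, y = table$response,
                                   ntree = n_trees, mtry = mtry)
  p0 <- stats::predict(rf, enc$x)
  raw <- matrix(NA_real_, length(factors), n_perm,
                dimnames = list(factors, NULL))
  for (f in factors) {
    cols <- which(enc$groups == f)
    for (k in seq_len(n_perm)) {
      set.seed(derive_seed(seed, "rf_factor_perm", f, k))
      xp <- enc$x
      xp[, cols] <- xp[sample.int(nrow(xp)), cols]
      p1 <- stats::predict(rf, xp)
      raw[f, k] <- if (stats::sd(p1) == 0 || stats::sd(p0) == 0)
        mean(abs(p1 - p0)) else 1 - stats::cor(p0, p1)
    }
  }
  raw[raw < 0] <- 0
  means <- rowMeans(raw)
  tot <- sum(means)
  scale_f <- if (tot > 0) 100 / tot else 0
  out <- data.frame(factor = factors,
                    mean_importance = unname(means * scale_f),
                    sd_importance = unname(apply(raw, 1, stats::sd) * scale_f))
  attr(out, "flagged") <- FALSE
  out
}
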