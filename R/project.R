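#' Project per-sample models over a climate stack
#'
#' Predicts suitability on every unmasked cell for each sample's retained
#' model or ensemble; masked cells stay masked (0 under the mask, which is
#' never read downstream).
#'
#' @param models named list of `hsm_model` / `hsm_ensemble` objects (one per
#'   sample with >= 1 retained model).
#' @param stack a [climate_stack()] containing every model variable.
#' @return a `projection_set`: list with `grids` (named list of suitability
#'   matrices), `spec`, and `context` (the stack's tags).
#' @export
project_models <- function(models, stack) {
  if (length(models) == 0) stop("no models to project")
  vars <- if (inherits(models[[1]], "hsm_ensemble")) models[[1]]$members[[1]]$variables
          else models[[1]]$variables
  miss <- setdiff(vars, names(stack$values))
  if (length(miss)) stop("stack lacks variable(s): ", paste(miss, collapse = ", "))
  sp <- stack$spec
  cc <- cell_centers(sp)
  ok <- !sp$mask[cbind(cc$row, cc$col)]
  newdata <- as.data.frame(lapply(stack$values, function(v) v[cbind(cc$row, cc$col)]))
  grids <- lapply(models, function(m) {
    p <- numeric(nrow(cc))
    p[ok] <- predict(m, newdata[ok, , drop = FALSE])
    matrix(p, sp$n_rows, sp$n_cols)
  })
  structure(list(grids = grids, spec = sp,
                 context = list(version_tag = stack$version_tag,
                                resolution_tag = stack$resolution_tag,
                                scenario_tag = stack$scenario_tag,
                                gcm_tag = stack$gcm_tag,
                                timeframe_tag = stack$timeframe_tag)),
            class = "projection_set")
}

#' Per-cell median across projected samples
#'
#' Even sample counts take the mean of the two central order statistics.
#'
#' @param ps a `projection_set` (>= 1 grid).
#' @return matrix of per-cell medians.
#' @export
median_projection <- function(ps) {
  if (length(ps$grids) == 0) stop("empty projection set")
  arr <- simplify2array(ps$grids)
  if (length(ps$grids) == 1L) return(ps$grids[[1]])
  apply(arr, c(1, 2), stats::median)
}

#' Between-version difference of median predictions
#'
#' @param median_b,median_a matrices on the same geometry (version B and A).
#' @return `median_b - median_a`, in `[-1, 1]`.
#' @export
version_difference <- function(median_b, median_a) {
  if (!all(dim(median_b) == dim(median_a))) stop("mismatched grids")
  median_b - median_a
}

#' Predicted-simulated correlation over random pixel samples
#'
#' For each of `n_sets` seeded uniform samples of unmasked pixels (without
#' replacement within a set), Pearson's r between the median predicted
#' suitability and the simulated occurrence probability.
#'
#' @param median_grid matrix of median predictions.
#' @param sim_prob matrix of simulated occurrence probabilities (same
#'   geometry).
#' @param spec the shared [grid_spec()].
#' @param n_pixels pixels per sample (default 10000); if fewer unmasked
#'   pixels exist, all are used with a warning.
#' @param n_sets number of samples (default 50).
#' @param seed integer seed.
#' @return numeric vector of length `n_sets`.
#' @export
predicted_simulated_r <- function(median_grid, sim_prob, spec, n_pixels = 10000L,
                                  n_sets = 50L, seed = 1L) {
  stopifnot(all(dim(median_grid) == dim(sim_prob)))
  ok <- which(!spec$mask)
  if (length(ok) < n_pixels) {
    warning("fewer unmasked pixels (", length(ok), ") than n_pixels; using all")
    n_pixels <- length(ok)
  }
  vapply(seq_len(n_sets), function(s) {
    set.seed(derive_seed(seed, "pred_sim_r", s))
    idx <- if (n_pixels == length(ok)) ok else sample(ok, n_pixels)
    a <- median_grid[idx]; b <- sim_prob[idx]
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
      stop("zero variance in sampled vector")
    stats::cor(a, b)
  }, numeric(1))
}

#' Sample between-version difference values at random pixels
#'
#' @param diff_grid difference matrix (e.g. from [version_difference()]).
#' @param spec the [grid_spec()].
#' @param n_pixels pixels to draw (default 10000; capped at the unmasked
#'   count with a warning).
#' @param seed integer seed.
#' @return numeric vector of sampled difference values.
#' @export
sample_future_differences <- function(diff_grid, spec, n_pixels = 10000L, seed = 1L) {
  ok <- which(!spec$mask)
  if (length(ok) == 0) stop("empty unmasked extent")
  if (length(ok) < n_pixels) {
    warning("fewer unmasked pixels (", length(ok), ") than n_pixels; using all")
    n_pixels <- length(ok)
  }
  set.seed(derive_seed(seed, "future_diff"))
  idx <- if (n_pixels == length(ok)) ok else sample(ok, n_pixels)
  diff_grid[idx]
}

# Flat-top hexagonal binning on the (simulated, predicted) unit plane.
# cell width = horizontal distance between adjacent hex centers; axial
# coordinates (q, r) with origin hex centered at (0, 0). Cube-rounding gives
# the containing hexagon of each point.
hex_axial <- function(x, y, width) {
  size <- width / 1.5  # flat-top: horizontal center spacing = 1.5 * size
  q <- (2 / 3) * x / size
  r <- (-1 / 3) * x / size + (sqrt(3) / 3) * y / size
  rq <- round(q); rr <- round(r); rs <- round(-q - r)
  dq <- abs(rq - q); dr <- abs(rr - r); ds <- abs(rs - (-q - r))
  fix_q <- dq > dr & dq > ds
  fix_r <- !fix_q & dr > ds
  rq[fix_q] <- -rr[fix_q] - rs[fix_q]
  rr[fix_r] <- -rq[fix_r] - rs[fix_r]
  data.frame(hex_q = as.integer(rq), hex_r = as.integer(rr))
}

#' Hexagonal-bin summary of predicted vs simulated suitability
#'
#' Bins the (simulated occurrence probability, median predicted suitability)
#' pairs of all unmasked pixels into flat-top hexagons of the given width
#' (origin hex centered at (0, 0) of the unit square) and reports per-cell
#' counts and `log10(count)`, plus the least-squares slope/intercept of
#' predicted ~ simulated.
#'
#' @param pred_grid,sim_grid matrices on the same geometry.
#' @param spec the [grid_spec()].
#' @param cell_width hexagon width in plane units (default 0.04).
#' @return list with `bins` (data.frame `hex_q`, `hex_r`, `center_x`,
#'   `center_y`, `count`, `log10_count`), `slope`, `intercept`, `n_pixels`.
#' @export
hexbin_summary <- function(pred_grid, sim_grid, spec, cell_width = 0.04) {
  stopifnot(all(dim(pred_grid) == dim(sim_grid)))
  ok <- which(!spec$mask)
  if (length(ok) == 0) stop("empty unmasked extent")
  sim <- sim_grid[ok]; pred <- pred_grid[ok]
  ax <- hex_axial(sim, pred, cell_width)
  key <- paste(ax$hex_q, ax$hex_r)
  tab <- table(key)
  qr_ <- do.call(rbind, strsplit(names(tab), " "))
  size <- cell_width / 1.5
  q <- as.integer(qr_[, 1]); r <- as.integer(qr_[, 2])
  bins <- data.frame(hex_q = q, hex_r = r,
                     center_x = size * 1.5 * q,
                     center_y = size * sqrt(3) * (r + q / 2),
                     count = as.integer(tab))
  bins$log10_count <- log10(bins$count)
  fit <- stats::lm(pred ~ sim)
  list(bins = bins[order(bins$hex_q, bins$hex_r), ],
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n_pixels = length(ok))
}
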