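#' Moran's I for one distance class
#'
#' `I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' with indicator weights `w_ij = 1` iff the inter-point distance falls in
#' `(d_min, d_max]` (`w_ii = 0`) and `S0 = sum_ij w_ij`. The first class is
#' closed at 0 so zero-distance pairs of distinct points are included.
#'
#' @param values numeric vector (n >= 3, nonzero variance).
#' @param coords two-column matrix / data.frame of planar km coordinates.
#' @param d_min,d_max distance-class bounds (km).
#' @return Moran's I (scalar).
#' @export
morans_i <- function(values, coords, d_min = 0, d_max = Inf) {
  n <- length(values)
  if (n < 3) stop("need at least 3 points")
  x <- values - mean(values)
  ss <- sum(x^2)
  if (ss == 0) stop("zero variance in values")
  coords <- as.matrix(coords)
  d <- as.matrix(stats::dist(coords))
  w <- (d > d_min & d <= d_max)
  if (d_min <= 0) w <- w | (d == 0)
  diag(w) <- FALSE
  s0 <- sum(w)
  if (s0 == 0) stop("no weighted pairs in distance class")
  cross <- as.numeric(t(x) %*% w %*% x)
  (n / s0) * cross / ss
}

#' Residual correlogram: Moran's I per contiguous distance class
#'
#' Classes are `(0, w], (w, 2w], ...` up to `max_distance` (the first class
#' includes distance 0 between distinct points); classes with fewer than one
#' weighted pair are masked (`NA`).
#'
#' @param residuals numeric residual vector (>= 10 points).
#' @param coords two-column coordinates (km).
#' @param class_width distance-class width, km (default 100).
#' @param max_distance largest class edge, km; default half the extent
#'   diagonal of the points.
#' @return a `correlogram`: data.frame with `class_low`, `class_high`,
#'   `class_center`, `morans_i`, `pair_count`.
#' @export
build_correlogram <- function(residuals, coords, class_width = 100,
                              max_distance = NULL) {
  if (class_width <= 0) stop("class_width must be > 0")
  if (length(residuals) < 10) stop("need >= 10 points")
  coords <- as.matrix(coords)
  if (is.null(max_distance)) {
    rng_x <- diff(range(coords[, 1])); rng_y <- diff(range(coords[, 2]))
    max_distance <- sqrt(rng_x^2 + rng_y^2) / 2
  }
  edges <- seq(0, max_distance + class_width - 1e-9, by = class_width)
  if (length(edges) < 2) edges <- c(0, class_width)
  d <- as.matrix(stats::dist(coords))
  diag(d) <- NA
  out <- data.frame(class_low = edges[-length(edges)], class_high = edges[-1])
  out$class_center <- (out$class_low + out$class_high) / 2
  out$morans_i <- NA_real_
  out$pair_count <- 0L
  for (k in seq_len(nrow(out))) {
    inclass <- d > out$class_low[k] & d <= out$class_high[k]
    if (k == 1L) inclass <- inclass | d == 0
    np <- sum(inclass, na.rm = TRUE) / 2
    out$pair_count[k] <- np
    if (np >= 1 && stats::sd(residuals) > 0)
      out$morans_i[k] <- morans_i(residuals, coords,
                                  d_min = out$class_low[k], d_max = out$class_high[k])
  }
  class(out) <- c("correlogram", "data.frame")
  out
}

#' Estimate the spatial-autocorrelation range from a correlogram
#'
#' The range is formalized as the center of the first distance class whose
#' Moran's I falls to `eps` or below (the distance after which residual
#' autocorrelation has effectively vanished). If no class crosses, the
#' largest class edge is returned with a warning.
#'
#' @param cg a [build_correlogram()] result.
#' @param eps crossing threshold (default 0.05).
#' @return SAC range in km.
#' @export
estimate_sac_range <- function(cg, eps = 0.05) {
  ok <- !is.na(cg$morans_i)
  if (!any(ok)) stop("all correlogram classes are masked")
  idx <- which(ok & cg$morans_i <= eps)
  if (length(idx) == 0) {
    warning("Moran's I never falls to eps; returning max distance")
    return(max(cg$class_high[ok]))
  }
  cg$class_center[idx[1]]
}

#' Choose the spatial block size from per-algorithm SAC ranges
#'
#' Conservative rule: the maximum SAC range over algorithms, plus 100 km, so
#' blocks exceed every estimated autocorrelation range.
#'
#' @param sac_ranges numeric vector of SAC ranges (km), one per algorithm.
#' @param pad additive safety margin (km, default 100).
#' @return block size in km.
#' @export
choose_block_size <- function(sac_ranges, pad = 100) {
  sac_ranges <- sac_ranges[is.finite(sac_ranges)]
  if (length(sac_ranges) == 0) stop("no finite SAC range supplied")
  max(sac_ranges) + pad
}

#' Checkerboard block-to-fold designs over a grid extent
#'
#' Tiles square blocks of side `block_size` from the extent origin (top-left)
#' and assigns folds by parity: `fold = ((block_row + block_col) %% 2) + 1`.
#' The complement design swaps the two folds; both are returned, giving the
#' two blocks-to-folds assignments evaluated per sample.
#'
#' @param spec a [grid_spec()].
#' @param block_size block side in km (> 0); the extent must span at least
#'   two blocks on one axis.
#' @return list of two `block_design`s (`primary`, `complement`); each has
#'   `block_size`, `blocks` (data.frame `block_row`, `block_col`, `fold`),
#'   `assignment_id`, and the originating `spec`.
#' @export
checkerboard_folds <- function(spec, block_size) {
  if (block_size <= 0) stop("block_size must be > 0")
  ext_x <- spec$n_cols * spec$cell_size
  ext_y <- spec$n_rows * spec$cell_size
  n_bx <- ceiling(ext_x / block_size)
  n_by <- ceiling(ext_y / block_size)
  if (n_bx < 2 && n_by < 2) stop("extent smaller than one block on both axes")
  blocks <- expand.grid(block_row = seq_len(n_by) - 1L, block_col = seq_len(n_bx) - 1L)
  blocks$fold <- ((blocks$block_row + blocks$block_col) %% 2L) + 1L
  primary <- structure(list(block_size = block_size, blocks = blocks,
                            assignment_id = "primary", spec = spec),
                       class = "block_design")
  comp <- primary
  comp$blocks$fold <- 3L - comp$blocks$fold
  comp$assignment_id <- "complement"
  list(primary = primary, complement = comp)
}

#' Assign points to checkerboard folds
#'
#' A point inherits the fold of its containing block; blocks are half-open
#' (`[start, start + size)`) from the top-left extent origin, so a point on a
#' shared edge belongs to the lower-index block.
#'
#' @param points data.frame with `x`, `y` (km) inside the extent.
#' @param design a `block_design` from [checkerboard_folds()].
#' @return integer fold label (1 or 2) per point.
#' @export
assign_points_to_folds <- function(points, design) {
  sp <- design$spec
  bx <- floor((points$x - sp$origin_x) / design$block_size)
  by <- floor((sp$origin_y - points$y) / design$block_size)
  max_bx <- max(design$blocks$block_col); max_by <- max(design$blocks$block_row)
  if (any(bx < 0 | by < 0 | bx > max_bx | by > max_by))
    stop("point(s) outside the blocked extent")
  fold <- ((by + bx) %% 2L) + 1L
  if (design$assignment_id == "complement") fold <- 3L - fold
  as.integer(fold)
}

#' Residuals of full-data habitat-suitability models
#'
#' Fits each requested learner on all points of a sample (no fold split) and
#' returns per-point residuals `label - predicted suitability`, the input to
#' the residual correlograms that set the spatial block size.
#'
#' @param sample a `pres_abs_sample`.
#' @param stack the [climate_stack()] supplying predictor values.
#' @param algorithms learner tags (default the two smoother/boosting
#'   families used for the correlograms: `"gam"`, `"gbm"`).
#' @param seed integer seed (forwarded to the learners).
#' @return named list (per algorithm) of data.frames `x`, `y`, `residual`.
#' @export
full_data_residuals <- function(sample, stack, algorithms = c("gam", "gbm"),
                                seed = 1L) {
  pts <- sample$points
  if (length(unique(pts$label)) < 2) stop("degenerate single-class sample")
  xv <- extract_values(stack, pts$x, pts$y)
  out <- list()
  for (alg in algorithms) {
    fit <- fit_hsm(alg, xv, pts$label, seed = derive_seed(seed, "fulldata", alg))
    pred <- predict(fit, xv)
    out[[alg]] <- data.frame(x = pts$x, y = pts$y, residual = pts$label - pred)
  }
  out
}
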