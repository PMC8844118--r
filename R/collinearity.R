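#' Stepwise variance-inflation-factor filtering
#'
#' Computes, for each variable, `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes
#' from regressing variable `j` on all remaining variables, then repeatedly
#' drops the variable with the largest VIF while that maximum exceeds
#' `threshold`. Exactly collinear variables yield infinite VIF and are
#' dropped first.
#'
#' @param data data.frame or matrix of point-level variable values (rows =
#'   points, columns = variables); needs more points than variables and no
#'   constant column.
#' @param threshold VIF threshold (default 10).
#' @return a `vif_report`: list with `vif` (named final VIFs of retained
#'   variables), `retained` (character), `dropped` (character, in drop order).
#' @export
vif_stepwise <- function(data, threshold = 10) {
  x <- as.data.frame(data)
  if (ncol(x) < 2) stop("need at least 2 variables")
  if (nrow(x) <= ncol(x)) stop("need more points than variables")
  sds <- vapply(x, stats::sd, numeric(1))
  if (any(sds == 0)) stop("constant column(s): ",
                          paste(names(x)[sds == 0], collapse = ", "))
  vif_one <- function(j, cols) {
    fit <- stats::lm(x[[j]] ~ ., data = x[setdiff(cols, j)])
    r2 <- min(summary(fit)$r.squared, 1)
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }
  cols <- names(x); dropped <- character(0)
  repeat {
    if (length(cols) == 1L) { vifs <- stats::setNames(1, cols); break }
    vifs <- vapply(cols, vif_one, numeric(1), cols = cols)
    if (max(vifs) <= threshold) break
    worst <- cols[which.max(vifs)]
    dropped <- c(dropped, worst)
    cols <- setdiff(cols, worst)
  }
  structure(list(vif = vifs, retained = cols, dropped = dropped,
                 threshold = threshold), class = "vif_report")
}

#' Consensus variable selection across version x resolution combinations
#'
#' A variable is retained when it survives stepwise VIF filtering in strictly
#' more than half of the dataset-version x grid-resolution combinations.
#'
#' @param reports list of [vif_stepwise()] reports (one per combination), or
#'   a list of character vectors of retained names.
#' @return character vector of consensus-retained variable names.
#' @export
consensus_variable_selection <- function(reports) {
  if (length(reports) == 0) stop("empty report list")
  retained_sets <- lapply(reports, function(r)
    if (inherits(r, "vif_report")) r$retained else as.character(r))
  all_vars <- unique(unlist(retained_sets))
  counts <- vapply(all_vars, function(v)
    sum(vapply(retained_sets, function(s) v %in% s, logical(1))), numeric(1))
  all_vars[counts > length(reports) / 2]
}

#' Between-version pairwise correlation on stratified random point sets
#'
#' Draws `n_sets` point sets by stratified random sampling — the extent is
#' partitioned into a regular `k x k` stratum grid (`k = round(sqrt(n_points))`)
#' and one unmasked cell is drawn uniformly within each stratum — and
#' computes, per variable and set, Pearson's r between the version-A and
#' version-B values at those cells.
#'
#' @param stack_a,stack_b two [climate_stack()]s on the same [grid_spec()].
#' @param n_points target points per set (>= 9).
#' @param n_sets number of replicate point sets.
#' @param seed integer seed.
#' @return data.frame with columns `set`, `variable`, `r`, `n_points`.
#' @export
pairwise_between_version_r <- function(stack_a, stack_b, n_points = 100,
                                       n_sets = 10, seed = 1L) {
  if (!same_spec(stack_a$spec, stack_b$spec)) stop("stacks must share one grid_spec")
  sp <- stack_a$spec
  k <- max(2L, round(sqrt(n_points)))
  cc <- cell_centers(sp)
  ok <- !sp$mask[cbind(cc$row, cc$col)]
  if (sum(ok) < 3) stop("fewer than 3 unmasked cells")
  sx <- pmin(floor((cc$col - 1) / sp$n_cols * k) + 1L, k)
  sy <- pmin(floor((cc$row - 1) / sp$n_rows * k) + 1L, k)
  stratum <- (sy - 1L) * k + sx
  vars <- names(stack_a$values)
  out <- list()
  for (s in seq_len(n_sets)) {
    set.seed(derive_seed(seed, "pairwise_r", s))
    idx <- unlist(lapply(split(which(ok), stratum[ok]), function(cells)
      if (length(cells) == 1L) cells else sample(cells, 1L)), use.names = FALSE)
    rows <- cc$row[idx]; cols <- cc$col[idx]
    for (v in vars) {
      va <- stack_a$values[[v]][cbind(rows, cols)]
      vb <- stack_b$values[[v]][cbind(rows, cols)]
      out[[length(out) + 1L]] <- data.frame(
        set = s, variable = v,
        r = if (stats::sd(va) == 0 || stats::sd(vb) == 0) NA_real_
            else stats::cor(va, vb),
        n_points = length(idx))
    }
  }
  do.call(rbind, out)
}

#' Local (focal-window) Pearson correlation between two grids
#'
#' Computes, for every unmasked cell, Pearson's r between the two grids over
#' the `window x window` neighborhood centered on the cell; edge cells use
#' the truncated neighborhood. Cells whose neighborhood has zero variance in
#' either grid (or fewer than 3 unmasked neighbors) are masked in the output.
#'
#' @param grid_a,grid_b numeric matrices of equal dimension.
#' @param spec the shared [grid_spec()].
#' @param window odd window side length (>= 3; default 5).
#' @return list with `values` (matrix of local r, `NA` where undefined) and
#'   `spec` (a [grid_spec()] whose mask marks undefined cells).
#' @export
local_focal_r <- function(grid_a, grid_b, spec, window = 5) {
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3")
  stopifnot(all(dim(grid_a) == dim(grid_b)))
  h <- (window - 1L) / 2L
  nr <- nrow(grid_a); nc <- ncol(grid_a)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    ri <- max(1L, i - h):min(nr, i + h)
    for (j in seq_len(nc)) {
      if (spec$mask[i, j]) next
      cj <- max(1L, j - h):min(nc, j + h)
      keep <- !spec$mask[ri, cj, drop = FALSE]
      if (sum(keep) < 3) next
      a <- grid_a[ri, cj, drop = FALSE][keep]
      b <- grid_b[ri, cj, drop = FALSE][keep]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next
      out[i, j] <- stats::cor(a, b)
    }
  }
  new_spec <- grid_spec(nr, nc, cell_size = spec$cell_size,
                        origin_x = spec$origin_x, origin_y = spec$origin_y,
                        mask = is.na(out))
  list(values = out, spec = new_spec)
}
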