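#' Planar grid geometry
#'
#' A `grid_spec` describes the shared geometry of every gridded surface in a
#' climate stack: a planar km coordinate system with the origin at the
#' top-left corner of the grid, rows counted downwards (row 1 is the
#' northernmost row) and cell centers at half-cell offsets. An optional
#' nodata mask marks cells excluded from every computation.
#'
#' @param n_rows,n_cols grid dimensions (>= 2).
#' @param cell_size cell side length in km (> 0).
#' @param origin_x,origin_y coordinates (km) of the top-left grid corner.
#' @param mask logical matrix (`n_rows` x `n_cols`), `TRUE` = nodata. `NULL`
#'   means no masked cells.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size = 1, origin_x = 0, origin_y = NULL,
                      mask = NULL) {
  if (n_rows < 1 || n_cols < 1) stop("grid dimensions must be >= 1")
  if (cell_size <= 0) stop("cell_size must be > 0")
  if (is.null(origin_y)) origin_y <- n_rows * cell_size
  if (is.null(mask)) mask <- matrix(FALSE, n_rows, n_cols)
  stopifnot(is.logical(mask), all(dim(mask) == c(n_rows, n_cols)))
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size = cell_size, origin_x = origin_x, origin_y = origin_y,
                 mask = mask),
            class = "grid_spec")
}

#' Cell-center coordinates of a grid
#'
#' @param spec a [grid_spec()].
#' @return a data.frame with `row`, `col`, `x`, `y` (km) for every cell, in
#'   column-major order matching `as.vector(values)`.
#' @export
cell_centers <- function(spec) {
  rows <- rep(seq_len(spec$n_rows), times = spec$n_cols)
  cols <- rep(seq_len(spec$n_cols), each = spec$n_rows)
  data.frame(row = rows, col = cols,
             x = spec$origin_x + (cols - 0.5) * spec$cell_size,
             y = spec$origin_y - (rows - 0.5) * spec$cell_size)
}

same_spec <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$cell_size - b$cell_size) < tol &&
    abs(a$origin_x - b$origin_x) < tol && abs(a$origin_y - b$origin_y) < tol
}

#' Construct a climate stack
#'
#' A climate stack bundles named gridded surfaces (one matrix per bioclim-like
#' variable) sharing one [grid_spec()], together with provenance tags: the
#' dataset version (`"A"`/`"B"`, standing in for the two releases of a
#' gridded climate product), resolution, emission scenario, climate-model and
#' timeframe identifiers.
#'
#' @param spec a [grid_spec()].
#' @param values named list of numeric matrices, one per variable.
#' @param version_tag,resolution_tag,scenario_tag,gcm_tag,timeframe_tag
#'   provenance tags.
#' @return an object of class `climate_stack`.
#' @export
climate_stack <- function(spec, values, version_tag = "A", resolution_tag = "r1",
                          scenario_tag = "current", gcm_tag = NA_character_,
                          timeframe_tag = "current") {
  stopifnot(inherits(spec, "grid_spec"), is.list(values), length(values) >= 1,
            !is.null(names(values)))
  for (nm in names(values)) {
    v <- values[[nm]]
    if (!is.matrix(v) || !all(dim(v) == c(spec$n_rows, spec$n_cols)))
      stop("grid '", nm, "' does not match the grid_spec dimensions")
    if (any(!is.finite(v[!spec$mask])))
      stop("grid '", nm, "' has non-finite values on unmasked cells")
  }
  structure(list(spec = spec, values = values, version_tag = version_tag,
                 resolution_tag = resolution_tag, scenario_tag = scenario_tag,
                 gcm_tag = gcm_tag, timeframe_tag = timeframe_tag),
            class = "climate_stack")
}

#' @export
print.climate_stack <- function(x, ...) {
  cat(sprintf("climate_stack: %d x %d cells (%.3g km), %d variable(s)\n",
              x$spec$n_rows, x$spec$n_cols, x$spec$cell_size, length(x$values)))
  cat(sprintf("  version=%s resolution=%s scenario=%s gcm=%s timeframe=%s\n",
              x$version_tag, x$resolution_tag, x$scenario_tag,
              x$gcm_tag, x$timeframe_tag))
  invisible(x)
}

#' Block-mean aggregation to a coarser resolution
#'
#' Aggregates each variable by averaging `factor` x `factor` blocks of cells;
#' the cell size is multiplied by `factor`. Trailing partial blocks (when
#' `factor` does not divide a dimension) are averaged over the available
#' cells. Masked cells are excluded from block means; a block whose cells are
#' all masked is masked in the output.
#'
#' @param stack a [climate_stack()].
#' @param factor integer aggregation factor (>= 2).
#' @return a coarser [climate_stack()], with `resolution_tag` suffixed by
#'   `"x<factor>"`.
#' @export
aggregate_resolution <- function(stack, factor) {
  if (factor < 2 || factor != round(factor)) stop("factor must be an integer >= 2")
  sp <- stack$spec
  nr <- ceiling(sp$n_rows / factor); nc <- ceiling(sp$n_cols / factor)
  row_blk <- (seq_len(sp$n_rows) - 1L) %/% factor + 1L
  col_blk <- (seq_len(sp$n_cols) - 1L) %/% factor + 1L
  blk <- factor(outer(row_blk, (col_blk - 1L) * nr, `+`), levels = seq_len(nr * nc))
  keep <- !sp$mask
  counts <- as.vector(tapply(as.numeric(keep), blk, sum))
  new_mask <- matrix(counts == 0, nr, nc)
  vals <- lapply(stack$values, function(v) {
    s <- as.vector(tapply(ifelse(keep, v, 0), blk, sum))
    m <- matrix(s / pmax(counts, 1), nr, nc)
    m[new_mask] <- 0  # placeholder under mask; masked cells are never read
    m
  })
  new_spec <- grid_spec(nr, nc, cell_size = sp$cell_size * factor,
                        origin_x = sp$origin_x, origin_y = sp$origin_y,
                        mask = new_mask)
  climate_stack(new_spec, vals, version_tag = stack$version_tag,
                resolution_tag = paste0(stack$resolution_tag, "x", factor),
                scenario_tag = stack$scenario_tag, gcm_tag = stack$gcm_tag,
                timeframe_tag = stack$timeframe_tag)
}

#' Bilinear resampling onto a target grid geometry
#'
#' Each target cell-center value is the bilinear interpolation of the four
#' surrounding source cell centers; outside the hull of source cell centers
#' the nearest-edge value is used (coordinates are clamped). A target cell is
#' masked when any source cell contributing weight to it is masked, or when
#' the target cell itself is masked in the target spec.
#'
#' @param stack a [climate_stack()].
#' @param target a [grid_spec()] overlapping the source extent.
#' @return a [climate_stack()] on `target`.
#' @export
resample_bilinear <- function(stack, target) {
  sp <- stack$spec
  src_xmin <- sp$origin_x; src_xmax <- sp$origin_x + sp$n_cols * sp$cell_size
  src_ymax <- sp$origin_y; src_ymin <- sp$origin_y - sp$n_rows * sp$cell_size
  tgt_xmin <- target$origin_x; tgt_xmax <- target$origin_x + target$n_cols * target$cell_size
  tgt_ymax <- target$origin_y; tgt_ymin <- target$origin_y - target$n_rows * target$cell_size
  if (tgt_xmin >= src_xmax || tgt_xmax <= src_xmin ||
      tgt_ymin >= src_ymax || tgt_ymax <= src_ymin)
    stop("source and target extents are disjoint")
  cc <- cell_centers(target)
  # fractional source row/col of each target center (1-based, cell-center convention)
  fc <- (cc$x - sp$origin_x) / sp$cell_size + 0.5
  fr <- (sp$origin_y - cc$y) / sp$cell_size + 0.5
  fc <- pmin(pmax(fc, 1), sp$n_cols)  # clamp to the cell-center hull
  fr <- pmin(pmax(fr, 1), sp$n_rows)
  c0 <- pmin(floor(fc), sp$n_cols - 1L); r0 <- pmin(floor(fr), sp$n_rows - 1L)
  wx <- fc - c0; wy <- fr - r0
  i00 <- cbind(r0, c0); i01 <- cbind(r0, c0 + 1); i10 <- cbind(r0 + 1, c0); i11 <- cbind(r0 + 1, c0 + 1)
  w00 <- (1 - wy) * (1 - wx); w01 <- (1 - wy) * wx; w10 <- wy * (1 - wx); w11 <- wy * wx
  msk <- sp$mask
  bad <- (w00 > 0 & msk[i00]) | (w01 > 0 & msk[i01]) |
         (w10 > 0 & msk[i10]) | (w11 > 0 & msk[i11])
  new_mask <- matrix(bad, target$n_rows, target$n_cols) | target$mask
  vals <- lapply(stack$values, function(v) {
    out <- w00 * v[i00] + w01 * v[i01] + w10 * v[i10] + w11 * v[i11]
    m <- matrix(out, target$n_rows, target$n_cols)
    m[new_mask] <- 0
    m
  })
  new_spec <- grid_spec(target$n_rows, target$n_cols, cell_size = target$cell_size,
                        origin_x = target$origin_x, origin_y = target$origin_y,
                        mask = new_mask)
  climate_stack(new_spec, vals, version_tag = stack$version_tag,
                resolution_tag = stack$resolution_tag, scenario_tag = stack$scenario_tag,
                gcm_tag = stack$gcm_tag, timeframe_tag = stack$timeframe_tag)
}

#' Rescale temperature-like variables stored in tenths of a unit
#'
#' One dataset version stores temperature variables as tenths of degrees;
#' this divides the listed grids by `divisor` and leaves the rest untouched.
#' It is stateless: applying it twice divides twice.
#'
#' @param stack a [climate_stack()].
#' @param variables character vector of variable names to rescale.
#' @param divisor scalar divisor (default 10).
#' @return a [climate_stack()] with the listed variables divided.
#' @export
rescale_temperature_units <- function(stack, variables, divisor = 10) {
  missing_v <- setdiff(variables, names(stack$values))
  if (length(missing_v)) stop("unknown variable(s): ", paste(missing_v, collapse = ", "))
  for (v in variables) stack$values[[v]] <- stack$values[[v]] / divisor
  stack
}

#' Extract stack values at point coordinates
#'
#' Returns the per-variable values of the cells containing the given planar
#' km coordinates (half-open cell membership, consistent with
#' [assign_points_to_folds()]).
#'
#' @param stack a [climate_stack()].
#' @param x,y point coordinates (km).
#' @return data.frame, one column per stack variable.
#' @export
extract_values <- function(stack, x, y) {
  sp <- stack$spec
  col <- floor((x - sp$origin_x) / sp$cell_size) + 1L
  row <- floor((sp$origin_y - y) / sp$cell_size) + 1L
  if (any(col < 1 | col > sp$n_cols | row < 1 | row > sp$n_rows))
    stop("point(s) outside the grid extent")
  idx <- cbind(row, col)
  out <- lapply(stack$values, function(v) v[idx])
  as.data.frame(out)
}

#' Write / read a grid as an ESRI ASCII raster (plain text)
#'
#' Plain-text raster interchange used for all on-disk grids (no binary
#' formats). `write_ascii_grid()` stores one matrix with its geometry;
#' masked cells are written as the nodata value.
#'
#' @param values numeric matrix.
#' @param spec a [grid_spec()].
#' @param path output file path (conventionally `.asc`).
#' @param nodata nodata sentinel written for masked cells.
#' @export
write_ascii_grid <- function(values, spec, path, nodata = -9999) {
  hdr <- c(sprintf("ncols %d", spec$n_cols), sprintf("nrows %d", spec$n_rows),
           sprintf("xllcorner %.10g", spec$origin_x),
           sprintf("yllcorner %.10g", spec$origin_y - spec$n_rows * spec$cell_size),
           sprintf("cellsize %.10g", spec$cell_size),
           sprintf("NODATA_value %.10g", nodata))
  v <- values; v[spec$mask] <- nodata
  lines <- apply(v, 1L, function(r) paste(format(r, digits = 15, trim = TRUE,
                                                 scientific = FALSE), collapse = " "))
  writeLines(c(hdr, lines), path)
}

#' @rdname write_ascii_grid
#' @param path file written by [write_ascii_grid()].
#' @return a list with `values` (matrix, `NA` under mask) and `spec`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "[[:space:]]+")
  kv <- stats::setNames(vapply(hdr, function(h) as.numeric(h[2]), numeric(1)),
                        vapply(hdr, `[`, character(1), 1))
  nr <- as.integer(kv[["nrows"]]); nc <- as.integer(kv[["ncols"]])
  vals <- matrix(scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE),
                 nr, nc, byrow = TRUE)
  mask <- vals == kv[["nodata_value"]]
  vals[mask] <- NA_real_
  spec <- grid_spec(nr, nc, cell_size = kv[["cellsize"]],
                    origin_x = kv[["xllcorner"]],
                    origin_y = kv[["yllcorner"]] + nr * kv[["cellsize"]],
                    mask = mask)
  list(values = vals, spec = spec)
}

#' Write every variable of a stack as ASCII grids in a directory
#'
#' Files are named `<version>_<resolution>_<scenario>_<gcm>_<timeframe>_<variable>.asc`.
#'
#' @param stack a [climate_stack()].
#' @param dir output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gcm <- if (is.na(stack$gcm_tag)) "none" else stack$gcm_tag
  paths <- vapply(names(stack$values), function(v) {
    p <- file.path(dir, paste(stack$version_tag, stack$resolution_tag,
                              stack$scenario_tag, gcm, stack$timeframe_tag, v,
                              sep = "_"))
    p <- paste0(p, ".asc")
    write_ascii_grid(stack$values[[v]], stack$spec, p)
    p
  }, character(1))
  invisible(paths)
}
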