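#' Response functions linking a climate variable to suitability
#'
#' Four response shapes cover the simulated archetypes: increasing and
#' decreasing sigmoids, a Gaussian bell, and a threshold-like decreasing
#' logistic (a decreasing sigmoid with a small scale, so suitability drops
#' sharply past the inflection).
#'
#' @param kind one of `"increasing_sigmoid"`, `"decreasing_sigmoid"`,
#'   `"gaussian_bell"`, `"threshold_logistic"`.
#' @param variable_name stack variable the response reads.
#' @param x0 inflection point / mode, in variable units.
#' @param s scale / sd, in variable units (> 0). For
#'   `"threshold_logistic"` a small default (1) gives the sharp drop.
#' @return a `response_function`.
#' @export
response_function <- function(kind = c("increasing_sigmoid", "decreasing_sigmoid",
                                       "gaussian_bell", "threshold_logistic"),
                              variable_name, x0, s = 1) {
  kind <- match.arg(kind)
  if (s <= 0) stop("scale s must be > 0")
  structure(list(kind = kind, variable_name = variable_name, x0 = x0, s = s),
            class = "response_function")
}

#' Evaluate a response function
#'
#' `increasing_sigmoid(x) = 1 / (1 + exp(-(x - x0)/s))`; the decreasing kinds
#' are its complement; `gaussian_bell = exp(-(x - x0)^2 / (2 s^2))`. Output
#' is always in `[0, 1]`.
#'
#' @param fn a [response_function()].
#' @param x numeric vector (finite).
#' @return suitability values in `[0, 1]`.
#' @export
eval_response <- function(fn, x) {
  stopifnot(inherits(fn, "response_function"))
  inc <- 1 / (1 + exp(-(x - fn$x0) / fn$s))
  switch(fn$kind,
         increasing_sigmoid = inc,
         decreasing_sigmoid = 1 - inc,
         threshold_logistic = 1 - inc,
         gaussian_bell = exp(-(x - fn$x0)^2 / (2 * fn$s^2)))
}

rescale01 <- function(v, mask) {
  u <- v[!mask]
  rng <- range(u)
  if (diff(rng) == 0)
    stop("suitability is constant over unmasked cells; min-max rescale undefined")
  out <- (v - rng[1]) / diff(rng)
  out[mask] <- 0
  out
}

#' Suitability from customized response curves
#'
#' Per-cell product of the responses evaluated on the stack's variables,
#' min-max rescaled to `[0, 1]` over unmasked cells.
#'
#' @param stack a [climate_stack()].
#' @param fns list of [response_function()]s; each `variable_name` must be in
#'   the stack.
#' @return list with `values` (suitability matrix in `[0, 1]`) and `spec`.
#' @export
suitability_from_responses <- function(stack, fns) {
  sp <- stack$spec
  miss <- setdiff(vapply(fns, `[[`, character(1), "variable_name"),
                  names(stack$values))
  if (length(miss)) stop("variable(s) not in stack: ", paste(miss, collapse = ", "))
  hs <- matrix(1, sp$n_rows, sp$n_cols)
  for (fn in fns) hs <- hs * eval_response(fn, stack$values[[fn$variable_name]])
  list(values = rescale01(hs, sp$mask), spec = sp)
}

#' Niche defined in a 2D principal-component space
#'
#' @param niche_center `(PC1, PC2)` niche optimum.
#' @param niche_breadth `(sd1, sd2)` Gaussian niche breadths (> 0).
#' @param background_sample_size cells used to fit the PCA.
#' @return a `pca_niche`.
#' @export
pca_niche <- function(niche_center = c(0, 0), niche_breadth = c(1, 1),
                      background_sample_size = 1000L) {
  if (any(niche_breadth <= 0)) stop("niche_breadth must be > 0")
  structure(list(niche_center = niche_center, niche_breadth = niche_breadth,
                 background_sample_size = as.integer(background_sample_size)),
            class = "pca_niche")
}

#' Suitability from a PCA-space niche
#'
#' Fits a PCA on a seeded random background sample of standardized cell-value
#' vectors, scores every cell on the first two components, and sets
#' suitability to the product of Gaussian responses centered at the niche
#' center with the niche breadths, min-max rescaled over unmasked cells.
#' Broad breadths give a climate-tolerant species with a wide
#' high-suitability extent; narrow breadths a sparse, restricted one.
#'
#' @param stack a [climate_stack()].
#' @param niche a [pca_niche()].
#' @param seed integer seed for the background sample.
#' @return list with `values`, `spec`, and `pca` (the `prcomp` fit).
#' @export
suitability_from_pca_niche <- function(stack, niche, seed = 1L) {
  sp <- stack$spec
  cc <- cell_centers(sp)
  ok <- which(!sp$mask[cbind(cc$row, cc$col)])
  if (length(ok) < length(stack$values))
    stop("fewer unmasked cells than variables")
  xall <- vapply(stack$values, function(v) v[cbind(cc$row, cc$col)],
                 numeric(nrow(cc)))
  set.seed(derive_seed(seed, "pca_background"))
  bg <- sample(ok, min(niche$background_sample_size, length(ok)))
  pca <- stats::prcomp(xall[bg, , drop = FALSE], center = TRUE, scale. = TRUE)
  scores <- stats::predict(pca, xall)[, 1:2, drop = FALSE]
  hs_vec <- exp(-(scores[, 1] - niche$niche_center[1])^2 / (2 * niche$niche_breadth[1]^2)) *
            exp(-(scores[, 2] - niche$niche_center[2])^2 / (2 * niche$niche_breadth[2]^2))
  hs <- matrix(hs_vec, sp$n_rows, sp$n_cols)
  list(values = rescale01(hs, sp$mask), spec = sp, pca = pca)
}

#' Logistic conversion parameters (suitability to occurrence probability)
#'
#' `P = 1 / (1 + exp((HS - beta) / alpha))`; with `alpha < 0` the probability
#' increases with suitability and equals 0.5 exactly at `HS = beta`. Smaller
#' `|alpha|` gives a steeper conversion; `beta` sets how much suitability is
#' needed for a coin-flip occurrence chance. `detection_prob` is the chance a
#' truly present cell is recorded as present during virtual sampling.
#'
#' @param alpha logistic slope (non-zero; negative for increasing P).
#' @param beta inflection point in `[0, 1]`.
#' @param detection_prob detection probability in `[0, 1]`.
#' @return a `conversion_params`.
#' @export
conversion_params <- function(alpha = -0.05, beta = 0.5, detection_prob = 1) {
  if (alpha == 0) stop("alpha must be non-zero")
  if (beta < 0 || beta > 1) stop("beta must be in [0, 1]")
  if (detection_prob < 0 || detection_prob > 1) stop("detection_prob must be in [0, 1]")
  structure(list(alpha = alpha, beta = beta, detection_prob = detection_prob),
            class = "conversion_params")
}

#' Convert suitability to occurrence probability
#'
#' @param hs suitability values in `[0, 1]` (matrix or vector).
#' @param cp a [conversion_params()].
#' @return occurrence probabilities, same shape as `hs`.
#' @export
occurrence_probability <- function(hs, cp) {
  stopifnot(inherits(cp, "conversion_params"))
  if (any(hs < 0 | hs > 1, na.rm = TRUE)) stop("hs must be in [0, 1]")
  1 / (1 + exp((hs - cp$beta) / cp$alpha))
}

#' Realize a presence-absence map from occurrence probabilities
#'
#' Independent per-cell Bernoulli draws, deterministic given the seed.
#'
#' @param prob matrix of occurrence probabilities.
#' @param seed integer seed.
#' @return integer 0/1 matrix of the same dimension.
#' @export
realize_presence_absence <- function(prob, seed = 1L) {
  if (any(prob < 0 | prob > 1, na.rm = TRUE)) stop("probabilities must be in [0, 1]")
  set.seed(derive_seed(seed, "realize_pa"))
  matrix(stats::rbinom(length(prob), 1L, as.vector(prob)), nrow(prob), ncol(prob))
}

#' Draw presence-absence samples with optional buffering and imperfect detection
#'
#' The buffered strategy mirrors field sampling concentrated around known
#' occurrences: a seeded set of `n_seed_presences` presence cells is drawn
#' (all of them, with a warning, if fewer exist), the union of disks of
#' radius `buffer_km` around their centers forms the eligible area, and each
#' sample draws `n_points` cells uniformly without replacement from the
#' eligible unmasked cells. The whole-extent strategy samples from all
#' unmasked cells. A sampled presence is recorded as presence with
#' probability `detection_prob` (else as a false absence); absences are
#' recorded faithfully.
#'
#' @param pa 0/1 presence-absence matrix.
#' @param spec the [grid_spec()] of `pa`.
#' @param strategy `"whole_extent"` or `"buffered"`.
#' @param buffer_km buffer radius (km) for the buffered strategy.
#' @param n_seed_presences presence cells seeding the buffer (default 500).
#' @param n_points points per sample (default 300).
#' @param n_samples number of independent samples (default 50).
#' @param detection_prob detection probability in `[0, 1]`.
#' @param seed integer seed.
#' @param species_tag label stored with each sample.
#' @return list of `pres_abs_sample` objects: each a list with `sample_id`,
#'   `points` (data.frame `x`, `y`, `label`), `species_tag`, `provenance`.
#' @export
sample_presabs <- function(pa, spec, strategy = c("whole_extent", "buffered"),
                           buffer_km = 120, n_seed_presences = 500L,
                           n_points = 300L, n_samples = 50L,
                           detection_prob = 1, seed = 1L,
                           species_tag = "species") {
  strategy <- match.arg(strategy)
  cc <- cell_centers(spec)
  ok <- !spec$mask[cbind(cc$row, cc$col)]
  labs <- pa[cbind(cc$row, cc$col)]
  if (strategy == "buffered") {
    pres_idx <- which(ok & labs == 1L)
    if (length(pres_idx) == 0) stop("buffered strategy requires >= 1 presence cell")
    set.seed(derive_seed(seed, "buffer_seed_presences"))
    if (length(pres_idx) < n_seed_presences) {
      warning("fewer presence cells (", length(pres_idx), ") than n_seed_presences (",
              n_seed_presences, "); using all")
      seeds_idx <- pres_idx
    } else seeds_idx <- sample(pres_idx, n_seed_presences)
    # cell centers within buffer_km of any seed-presence center
    eligible <- rep(FALSE, nrow(cc))
    cand <- which(ok)
    for (block in split(seeds_idx, ceiling(seq_along(seeds_idx) / 200))) {
      d2 <- outer(cc$x[cand], cc$x[block], `-`)^2 + outer(cc$y[cand], cc$y[block], `-`)^2
      eligible[cand[rowSums(d2 <= buffer_km^2) > 0]] <- TRUE
      cand <- cand[!eligible[cand]]
      if (!length(cand)) break
    }
    pool <- which(eligible)
  } else pool <- which(ok)
  if (length(pool) < n_points)
    stop("eligible cells (", length(pool), ") fewer than n_points (", n_points, ")")
  lapply(seq_len(n_samples), function(s) {
    set.seed(derive_seed(seed, "sample", s))
    idx <- sample(pool, n_points)
    true_lab <- labs[idx]
    detected <- stats::rbinom(n_points, 1L, detection_prob)
    lab <- ifelse(true_lab == 1L, true_lab * detected, 0L)
    structure(list(sample_id = s,
                   points = data.frame(x = cc$x[idx], y = cc$y[idx], label = lab),
                   species_tag = species_tag,
                   provenance = list(strategy = strategy,
                                     buffer_km = if (strategy == "buffered") buffer_km else NA_real_,
                                     detection_prob = detection_prob, seed = seed)),
              class = "pres_abs_sample")
  })
}

#' Write / read presence-absence samples as CSV
#'
#' CSV with header `sample_id,x,y,label`; coordinates round-trip bit-exactly
#' (full double precision).
#'
#' @param samples list of `pres_abs_sample` objects.
#' @param path CSV path.
#' @export
write_samples_csv <- function(samples, path) {
  rows <- do.call(rbind, lapply(samples, function(s)
    data.frame(sample_id = s$sample_id, x = s$points$x, y = s$points$y,
               label = s$points$label)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("sample_id,x,y,label", con)
  writeLines(sprintf("%d,%s,%s,%d", rows$sample_id,
                     format(rows$x, digits = 17, trim = TRUE, scientific = FALSE),
                     format(rows$y, digits = 17, trim = TRUE, scientific = FALSE),
                     rows$label), con)
}

#' @rdname write_samples_csv
#' @param species_tag tag attached to the re-read samples.
#' @return `read_samples_csv()`: list of `pres_abs_sample` objects.
#' @export
read_samples_csv <- function(path, species_tag = "species") {
  df <- utils::read.csv(path)
  lapply(split(df, df$sample_id), function(d)
    structure(list(sample_id = d$sample_id[1],
                   points = data.frame(x = d$x, y = d$y, label = as.integer(d$label)),
                   species_tag = species_tag,
                   provenance = list(strategy = "file", buffer_km = NA_real_,
                                     detection_prob = NA_real_, seed = NA_integer_)),
              class = "pres_abs_sample"))
}

#' Virtual-species archetype presets
#'
#' Four archetypes spanning the niche typologies of the experiment, defined
#' on the synthetic variables (paper-inspired defaults; every number is
#' editable by building the preset by hand):
#' \describe{
#'   \item{alpine}{cold-adapted: decreasing sigmoid on `bio1` (temperature
#'     mean), increasing sigmoid on `bio2` (diurnal range), Gaussian bell on
#'     `bio3` centered at 2.5 degrees; `alpha = -0.05`, `beta = 0.6`,
#'     detection 0.75; buffered sampling, 120 km. Curve locations are set on
#'     the synthetic variables' scales so the extent-wide prevalence lands
#'     near the archetype's ~0.25.}
#'   \item{mediterranean}{warm/dry: increasing sigmoid on `bio1` selecting
#'     the warm (southern) extent, threshold-like drop past ~95 mm on `bio4`
#'     (warm-quarter precipitation analogue), giving a narrow warm-and-dry
#'     archetype (~0.1 extent prevalence); `alpha = -0.05`, `beta = 0.7`,
#'     detection 0.75; buffered sampling, 120 km.}
#'   \item{generalist}{climate-tolerant: broad PCA niche (breadth 2, 2);
#'     `alpha = -0.01`, `beta = 0.4`, detection 0.75; whole-extent sampling.}
#'   \item{restricted}{narrow PCA niche off-center (breadth 0.55, 0.55);
#'     `alpha = -0.05`, `beta = 0.8`, detection 0.9; buffered sampling with
#'     a tighter buffer than the other constrained archetypes (100 km vs
#'     120 km), scaled to the synthetic extent so the buffered area can hold
#'     a 300-point sample.}
#' }
#'
#' @param name preset name.
#' @return a `species_preset` list with fields `name`, `niche_kind`
#'   (`"responses"` or `"pca"`), `responses` or `niche`, `conversion`
#'   ([conversion_params()]), `sampling` (strategy and buffer).
#' @export
species_preset <- function(name = c("alpine", "mediterranean", "generalist",
                                    "restricted")) {
  name <- match.arg(name)
  p <- switch(name,
    alpine = list(
      niche_kind = "responses",
      responses = list(
        response_function("decreasing_sigmoid", "bio1", x0 = 12, s = 4),
        response_function("increasing_sigmoid", "bio2", x0 = 5, s = 3),
        response_function("gaussian_bell", "bio3", x0 = 2.5, s = 12)),
      conversion = conversion_params(alpha = -0.05, beta = 0.6, detection_prob = 0.75),
      sampling = list(strategy = "buffered", buffer_km = 120)),
    mediterranean = list(
      niche_kind = "responses",
      responses = list(
        response_function("increasing_sigmoid", "bio1", x0 = 12, s = 2),
        response_function("threshold_logistic", "bio4", x0 = 95, s = 4)),
      conversion = conversion_params(alpha = -0.05, beta = 0.7, detection_prob = 0.75),
      sampling = list(strategy = "buffered", buffer_km = 120)),
    generalist = list(
      niche_kind = "pca",
      niche = pca_niche(niche_center = c(0.5, 0), niche_breadth = c(2, 2)),
      conversion = conversion_params(alpha = -0.01, beta = 0.4, detection_prob = 0.75),
      sampling = list(strategy = "whole_extent", buffer_km = NA_real_)),
    restricted = list(
      niche_kind = "pca",
      niche = pca_niche(niche_center = c(-1.2, -1.2), niche_breadth = c(0.55, 0.55)),
      conversion = conversion_params(alpha = -0.05, beta = 0.8, detection_prob = 0.9),
      sampling = list(strategy = "buffered", buffer_km = 100)))
  structure(c(list(name = name), p), class = "species_preset")
}

#' Simulate a species' suitability on a stack from a preset
#'
#' @param stack a [climate_stack()].
#' @param preset a [species_preset()].
#' @param seed seed (used by the PCA background sample).
#' @return list with `values` (suitability matrix) and `spec`.
#' @export
simulate_suitability <- function(stack, preset, seed = 1L) {
  if (preset$niche_kind == "responses")
    suitability_from_responses(stack, preset$responses)
  else
    suitability_from_pca_niche(stack, preset$niche, seed = seed)
}
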