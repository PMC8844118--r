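test_that("Moran's I equals the naive double-sum oracle", {
  # hand case: 2x2 checkerboard values with rook-adjacency weights -> I = -1
  coords <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))
  vals <- c(1, 0, 0, 1)
  expect_equal(morans_i(vals, coords, d_min = 0.5, d_max = 1), -1)
  expect_equal(oracle_morans_i(vals, coords, 0.5, 1), -1)

  for (s in 1:20) {
    set.seed(s)
    n <- sample(10:200, 1)
    coords <- matrix(runif(2 * n, 0, 100), n, 2)
    vals <- rnorm(n)
    dmax <- runif(1, 20, 80)
    expect_equal(morans_i(vals, coords, 0, dmax),
                 oracle_morans_i(vals, coords, 0, dmax), tolerance = 1e-12)
  }
})

test_that("Moran's I with all pairs weighted equals the null expectation", {
  set.seed(11)
  n <- 50
  coords <- matrix(runif(2 * n), n, 2)
  expect_equal(morans_i(rnorm(n), coords, 0, Inf), -1 / (n - 1), tolerance = 1e-12)
})

test_that("Moran's I is positive at short range on a smooth gradient", {
  cc <- expand.grid(x = 1:10, y = 1:10)
  vals <- cc$x + cc$y
  expect_gt(morans_i(vals, as.matrix(cc), 0, 1.5), 0)
  expect_error(morans_i(rep(1, 10), matrix(runif(20), 10, 2)), "zero variance")
  expect_error(morans_i(rnorm(10), matrix(runif(20), 10, 2), 500, 600),
               "no weighted pairs")
})

test_that("correlograms decay for smooth fields and mask empty classes", {
  set.seed(3)
  n <- 120
  coords <- matrix(runif(2 * n, 0, 500), n, 2)
  # smooth field: long-wavelength sinusoid sampled at the points
  smooth_vals <- sin(coords[, 1] / 150) + cos(coords[, 2] / 150)
  cg <- build_correlogram(smooth_vals, coords, class_width = 100, max_distance = 600)
  expect_gt(cg$morans_i[1], 0)
  expect_gt(cg$morans_i[1], cg$morans_i[3])

  # white-noise residuals: small I everywhere, no positive short-range bias
  null_i <- replicate(20, {
    v <- rnorm(n)
    build_correlogram(v, coords, class_width = 100, max_distance = 600)$morans_i[1]
  })
  expect_lt(abs(mean(null_i)), 0.05)

  # classes beyond the data's span are masked
  tight <- matrix(runif(40, 0, 10), 20, 2)
  cg2 <- build_correlogram(rnorm(20), tight, class_width = 100, max_distance = 500)
  expect_false(is.na(cg2$morans_i[1]))
  expect_true(all(is.na(cg2$morans_i[-1])))
  expect_error(build_correlogram(rnorm(20), tight, class_width = -1), "class_width")
})

test_that("SAC range rule returns the first class at or below eps", {
  cg <- data.frame(class_low = c(0, 100, 200, 300),
                   class_high = c(100, 200, 300, 400),
                   class_center = c(50, 150, 250, 350) + 50,
                   morans_i = c(0.4, 0.2, 0.05, -0.02), pair_count = 10L)
  cg$class_center <- c(100, 200, 300, 400)  # centers as stated in the rule probe
  expect_equal(estimate_sac_range(cg, eps = 0.05), 300)
  cg$morans_i <- c(0.01, 0.2, 0.3, 0.4)
  expect_equal(estimate_sac_range(cg, eps = 0.05), 100)
  cg$morans_i <- rep(0.5, 4)
  expect_warning(rng <- estimate_sac_range(cg, eps = 0.05), "max distance")
  expect_equal(rng, 400)
  # monotonicity: raising every I cannot decrease the estimate
  set.seed(2)
  for (k in 1:20) {
    cg$morans_i <- runif(4, -0.1, 0.4)
    base <- suppressWarnings(estimate_sac_range(cg))
    cg2 <- cg; cg2$morans_i <- cg$morans_i + runif(1, 0, 0.2)
    expect_gte(suppressWarnings(estimate_sac_range(cg2)), base)
  }
})

test_that("block size is the maximum SAC range plus the 100 km margin", {
  expect_equal(choose_block_size(1500), 1600)
  expect_equal(choose_block_size(c(300, 500)), 600)
  expect_equal(choose_block_size(0), 100)
  expect_error(choose_block_size(numeric(0)), "no finite")
})

test_that("checkerboard designs satisfy the parity contract and its complement", {
  spec <- grid_spec(40, 60, cell_size = 10)
  d <- checkerboard_folds(spec, 150)
  b <- d$primary$blocks
  expect_equal(b$fold, ((b$block_row + b$block_col) %% 2L) + 1L)
  expect_equal(d$complement$blocks$fold, 3L - b$fold)
  # rook-adjacent blocks always differ in fold
  for (i in seq_len(nrow(b))) {
    nb <- b[abs(b$block_row - b$block_row[i]) + abs(b$block_col - b$block_col[i]) == 1, ]
    expect_true(all(nb$fold != b$fold[i]))
  }
  expect_error(checkerboard_folds(grid_spec(4, 4, cell_size = 1), 100), "smaller")
})

test_that("points inherit folds by half-open block membership", {
  spec <- grid_spec(40, 40, cell_size = 10)
  d <- checkerboard_folds(spec, 100)$primary
  # interior of block (0,0) -> fold 1; edge x = 100 belongs to block col 1
  expect_equal(assign_points_to_folds(data.frame(x = 50, y = 350), d), 1L)
  expect_equal(assign_points_to_folds(data.frame(x = 100, y = 350), d), 2L)
  dc <- checkerboard_folds(spec, 100)$complement
  expect_equal(assign_points_to_folds(data.frame(x = 50, y = 350), dc), 2L)
  expect_error(assign_points_to_folds(data.frame(x = -5, y = 50), d), "outside")
  # balanced extents split points roughly in half
  set.seed(6)
  pts <- data.frame(x = runif(1000, 0, 400), y = runif(1000, 0, 400))
  f <- assign_points_to_folds(pts, d)
  expect_lt(abs(mean(f == 1) - 0.5), 3 * sqrt(0.25 / 1000))
})

test_that("full-data residuals separate classes for a separable fit", {
  set.seed(10)
  spec <- grid_spec(20, 20, cell_size = 10)
  vals <- matrix(seq(0, 20, length.out = 400), 20, 20)
  stack <- climate_stack(spec, list(bio1 = vals, bio2 = matrix(rnorm(400), 20, 20)))
  cc <- cell_centers(spec)
  idx <- sample(400, 100)
  smp <- structure(list(sample_id = 1L,
                        points = data.frame(x = cc$x[idx], y = cc$y[idx],
                                            label = as.integer(vals[idx] > 10)),
                        species_tag = "toy",
                        provenance = list()), class = "pres_abs_sample")
  res <- full_data_residuals(smp, stack, algorithms = "glm", seed = 1)$glm
  expect_true(all(abs(res$residual) <= 1))
  # a separable fit leaves near-zero residuals of the right sign
  expect_lt(mean(abs(res$residual)), 0.1)
  expect_true(all(res$residual[smp$points$label == 1] >= 0))
  expect_true(all(res$residual[smp$points$label == 0] <= 0))
  smp$points$label <- rep(1L, 100)
  expect_error(full_data_residuals(smp, stack), "single-class")
})

test_that("longer climate correlation lengths give longer estimated SAC ranges", {
  med_range <- sapply(c(20, 120), function(len) {
    ranges <- sapply(1:8, function(s) {
      f <- hsmismatch:::gaussian_field(40, 40, 10, len, seed = 500 + s)
      spec <- grid_spec(40, 40, cell_size = 10)
      cc <- cell_centers(spec)
      set.seed(s)
      idx <- sample(1600, 150)
      cg <- build_correlogram(f[idx], cc[idx, c("x", "y")], class_width = 50,
                              max_distance = 300)
      suppressWarnings(estimate_sac_range(cg))
    })
    median(ranges)
  })
  expect_gte(med_range[2], med_range[1])
})
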