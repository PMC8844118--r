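test_that("generation is deterministic and honors degenerate settings", {
  cfg <- generator_config(n_rows = 20, n_cols = 20, n_variables = 2,
                          spatial_correlation_length = 30,
                          between_version_decorrelation = 0,
                          scenario_shift = list(scen45 = 0),
                          gcm_perturbation_sd = 0, gcms = "g1",
                          timeframes = "2050", seed = 42)
  p1 <- generate_climate_pair(cfg)
  p2 <- generate_climate_pair(cfg)
  expect_identical(p1$A$values, p2$A$values)
  expect_identical(p1$B$values, p2$B$values)
  # decorrelation 0 -> versions identical cell-by-cell
  expect_equal(p1$A$values, p1$B$values)
  # zero shift and zero GCM perturbation -> future equals current
  expect_equal(p1$future[["A_scen45_g1_2050"]]$values, p1$A$values)
})

test_that("mean between-version r decreases with the decorrelation parameter", {
  levels_d <- c(0, 0.25, 0.5, 0.75, 1)
  mean_r <- sapply(levels_d, function(d) {
    rs <- sapply(1:10, function(s) {
      cfg <- generator_config(n_rows = 20, n_cols = 20, n_variables = 1,
                              spatial_correlation_length = 20,
                              between_version_decorrelation = d,
                              scenario_shift = list(), gcms = character(0),
                              seed = 100 + s)
      p <- generate_climate_pair(cfg)
      cor(as.vector(p$A$values$bio1), as.vector(p$B$values$bio1))
    })
    mean(rs)
  })
  expect_true(all(diff(mean_r) < 0))
  expect_gt(mean_r[2], mean_r[3])  # adjacent-level ordering, d = 0.25 vs 0.5
})

test_that("block-mean aggregation averages blocks and conserves the mean", {
  s <- toy_stack(matrix(c(1, 5, 3, 7), 2, 2))  # rows x cols: [[1,3],[5,7]]
  agg <- aggregate_resolution(s, 2)
  expect_equal(dim(agg$values$bio1), c(1, 1))
  expect_equal(agg$values$bio1[1, 1], 4)
  expect_equal(agg$spec$cell_size, 2)

  cst <- toy_stack(matrix(2.5, 6, 6))
  expect_true(all(aggregate_resolution(cst, 3)$values$bio1 == 2.5))

  set.seed(9)
  r <- toy_stack(matrix(rnorm(64), 8, 8))
  expect_equal(mean(aggregate_resolution(r, 2)$values$bio1), mean(r$values$bio1))
  expect_error(aggregate_resolution(r, 1), "factor")
})

test_that("aggregation handles trailing partial blocks and masks", {
  v <- matrix(seq_len(9), 3, 3)
  agg <- aggregate_resolution(toy_stack(v), 2)
  expect_equal(dim(agg$values$bio1), c(2, 2))
  # trailing blocks averaged over available cells
  expect_equal(agg$values$bio1[1, 1], mean(v[1:2, 1:2]))
  expect_equal(agg$values$bio1[2, 2], v[3, 3])
  m <- matrix(FALSE, 2, 2); m[1, 1] <- TRUE
  s <- toy_stack(matrix(c(10, 2, 4, 6), 2, 2), mask = m)
  agg2 <- aggregate_resolution(s, 2)
  expect_equal(agg2$values$bio1[1, 1], mean(c(2, 4, 6)))  # masked cell excluded
})

test_that("bilinear resampling matches closed-form weights", {
  cst <- toy_stack(matrix(7, 4, 4))
  tgt <- grid_spec(8, 8, cell_size = 0.5)
  expect_true(all(resample_bilinear(cst, tgt)$values$bio1 == 7))

  src <- toy_stack(matrix(rnorm(16), 4, 4))
  same <- resample_bilinear(src, src$spec)
  expect_equal(same$values$bio1, src$values$bio1)

  # top rows 0, bottom rows 10: target center midway between four sources -> 5
  v <- rbind(matrix(0, 1, 2), matrix(10, 1, 2))
  s <- toy_stack(v, cell_size = 1)
  tgt2 <- grid_spec(2, 2, cell_size = 0.5, origin_x = 0.25, origin_y = 1.25)
  out <- resample_bilinear(s, tgt2)
  expect_equal(out$values$bio1[1, 1], 5)  # center at y = 1.0, midway
  expect_error(resample_bilinear(s, grid_spec(2, 2, cell_size = 1, origin_x = 100)),
               "disjoint")
})

test_that("temperature rescaling divides only the listed variables", {
  s <- random_stack(n = 4, n_vars = 2)
  out <- rescale_temperature_units(s, "bio1", divisor = 10)
  expect_equal(out$values$bio1, s$values$bio1 / 10)
  expect_equal(out$values$bio2, s$values$bio2)
  twice <- rescale_temperature_units(out, "bio1", divisor = 10)
  expect_equal(twice$values$bio1, s$values$bio1 / 100)
  expect_equal(rescale_temperature_units(s, "bio1", divisor = 1)$values$bio1,
               s$values$bio1)
  expect_error(rescale_temperature_units(s, "bio99"), "unknown variable")
})

test_that("stepwise VIF matches closed forms and the retention contract", {
  set.seed(21)
  n <- 200
  # near-orthogonal standard normals: all VIF close to 1, none dropped
  x <- as.data.frame(qr.Q(qr(matrix(rnorm(n * 3), n, 3))))
  names(x) <- c("a", "b", "c")
  rep1 <- vif_stepwise(x)
  expect_equal(unname(rep1$vif), rep(1, 3), tolerance = 1e-4)
  expect_setequal(rep1$retained, c("a", "b", "c"))

  # two correlated variables: VIF = 1 / (1 - r^2), both retained at 10
  z <- rnorm(n)
  x2 <- data.frame(u = z + rnorm(n, sd = 0.5), v = z + rnorm(n, sd = 0.5))
  r2 <- cor(x2$u, x2$v)^2
  rep2 <- vif_stepwise(x2)
  expect_equal(unname(rep2$vif), rep(1 / (1 - r2), 2), tolerance = 1e-8)
  expect_length(rep2$retained, 2)

  # exact collinearity: one variable removed, final VIFs finite and <= 10
  x3 <- data.frame(p = rnorm(n), q = rnorm(n))
  x3$r <- x3$p + x3$q
  rep3 <- vif_stepwise(x3)
  expect_length(rep3$dropped, 1)
  expect_true(all(is.finite(rep3$vif)) && max(rep3$vif) <= 10)
  expect_error(vif_stepwise(data.frame(a = rep(1, 10), b = rnorm(10))), "constant")
})

test_that("consensus selection keeps variables retained in a strict majority", {
  reports <- list(c("a", "b"), c("a", "b"), c("a", "b"), c("a", "c"),
                  c("a", "c"), c("a", "c"))
  kept <- consensus_variable_selection(reports)
  expect_true("a" %in% kept)          # 6 of 6
  expect_false("b" %in% kept)         # 3 of 6 is not a strict majority
  expect_false("c" %in% kept)
  reports4 <- c(reports[1:3], list(c("a", "b")), reports[4:5])
  expect_true("b" %in% consensus_variable_selection(reports4))  # 4 of 6
  expect_error(consensus_variable_selection(list()), "empty")
})

test_that("pairwise between-version r detects identity, sign flip and noise", {
  s <- random_stack(n = 15, n_vars = 2, seed = 5)
  same <- pairwise_between_version_r(s, s, n_points = 36, n_sets = 3, seed = 1)
  expect_equal(same$r, rep(1, nrow(same)), tolerance = 1e-12)
  neg <- s
  neg$values <- lapply(neg$values, function(v) -v)
  flip <- pairwise_between_version_r(s, neg, n_points = 36, n_sets = 3, seed = 1)
  expect_equal(flip$r, rep(-1, nrow(flip)), tolerance = 1e-12)
  # white noise of matching sd attenuates r to ~ 1/sqrt(2)
  set.seed(77)
  n <- 30
  spec <- grid_spec(n, n, cell_size = 10)
  a <- matrix(rnorm(n * n), n, n)
  sa <- climate_stack(spec, list(bio1 = a))
  sb <- climate_stack(spec, list(bio1 = a + matrix(rnorm(n * n, sd = sd(a)), n, n)),
                      version_tag = "B")
  att <- pairwise_between_version_r(sa, sb, n_points = 100, n_sets = 40, seed = 2)
  expect_equal(mean(att$r), 1 / sqrt(2), tolerance = 0.05)
})

test_that("local focal r equals the direct windowed Pearson oracle", {
  set.seed(31)
  a <- matrix(rnorm(100), 10, 10)
  b <- a + matrix(rnorm(100, sd = 0.5), 10, 10)
  spec <- grid_spec(10, 10)
  got <- local_focal_r(a, b, spec, window = 5)
  expect_equal(got$values, oracle_focal_r(a, b, 5), tolerance = 1e-12)

  ident <- local_focal_r(a, a, spec, window = 3)
  expect_equal(ident$values, matrix(1, 10, 10), tolerance = 1e-12)
  constant <- local_focal_r(a, matrix(2, 10, 10), spec, window = 5)
  expect_true(all(is.na(constant$values)))
  expect_true(all(constant$spec$mask))
  expect_error(local_focal_r(a, b, spec, window = 4), "odd")
})

test_that("ascii grid files round-trip values, geometry and mask", {
  set.seed(8)
  v <- matrix(rnorm(30), 5, 6)
  m <- matrix(FALSE, 5, 6); m[2, 3] <- TRUE
  spec <- grid_spec(5, 6, cell_size = 2.5, origin_x = 10, mask = m)
  f <- tempfile(fileext = ".asc")
  write_ascii_grid(v, spec, f)
  back <- read_ascii_grid(f)
  expect_equal(back$values[!m], v[!m], tolerance = 1e-12)
  expect_true(back$spec$mask[2, 3])
  expect_equal(back$spec$cell_size, 2.5)
  expect_equal(back$spec$origin_x, 10)
})
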