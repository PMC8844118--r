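test_that("response functions match their closed forms", {
  inc <- response_function("increasing_sigmoid", "bio1", x0 = 5, s = 1)
  expect_equal(eval_response(inc, 5), 0.5)
  expect_equal(eval_response(inc, 7), 1 / (1 + exp(-2)))
  dec <- response_function("decreasing_sigmoid", "bio1", x0 = 5, s = 1)
  expect_equal(eval_response(dec, 7), 1 - 1 / (1 + exp(-2)))
  bell <- response_function("gaussian_bell", "bio1", x0 = 2, s = 3)
  expect_equal(eval_response(bell, 2), 1)
  expect_equal(eval_response(bell, 5), exp(-0.5))
  expect_error(response_function("gaussian_bell", "bio1", 0, s = 0), "s must be")
  x <- seq(-50, 50, length.out = 101)
  for (fn in list(inc, dec, bell))
    expect_true(all(eval_response(fn, x) >= 0 & eval_response(fn, x) <= 1))
})

test_that("response-curve suitability is the rescaled product of responses", {
  # 3-cell toy (1 x 3 grid padded to 2 rows), hand-multiplied
  v <- matrix(c(0, 0, 5, 5, 10, 10), 2, 3)
  s <- toy_stack(v)
  s$values$bio2 <- matrix(c(100, 100, 90, 90, 80, 80), 2, 3)
  fns <- list(response_function("increasing_sigmoid", "bio1", x0 = 5, s = 2),
              response_function("decreasing_sigmoid", "bio2", x0 = 90, s = 5))
  hs <- suitability_from_responses(s, fns)
  raw <- eval_response(fns[[1]], v) * eval_response(fns[[2]], s$values$bio2)
  expect_equal(hs$values, (raw - min(raw)) / (max(raw) - min(raw)))
  expect_true(all(hs$values >= 0 & hs$values <= 1))

  expect_error(
    suitability_from_responses(toy_stack(matrix(1, 3, 3)),
      list(response_function("increasing_sigmoid", "bio1", 0, 1))),
    "constant")
  expect_error(suitability_from_responses(s,
    list(response_function("increasing_sigmoid", "bio9", 0, 1))), "not in stack")
})

test_that("PCA-niche suitability peaks at the niche center and widens with breadth", {
  s <- random_stack(n = 20, n_vars = 3, seed = 4)
  wide <- suitability_from_pca_niche(s, pca_niche(c(0, 0), c(2, 2), 200), seed = 9)
  narrow <- suitability_from_pca_niche(s, pca_niche(c(0, 0), c(0.3, 0.3), 200), seed = 9)
  expect_gt(mean(wide$values > 0.5), mean(narrow$values > 0.5))

  # center placed on one cell's own scores -> that cell attains the maximum
  scores <- predict(wide$pca, vapply(s$values, as.vector, numeric(400)))[, 1:2]
  target <- 137
  centered <- suitability_from_pca_niche(
    s, pca_niche(scores[target, ], c(1, 1), 200), seed = 9)
  expect_equal(which.max(centered$values), target)
})

test_that("logistic conversion has its inflection at beta and is monotone", {
  cp <- conversion_params(alpha = -0.05, beta = 0.6)
  expect_equal(occurrence_probability(0.6, cp), 0.5)
  expect_equal(occurrence_probability(1, cp), 1 / (1 + exp(-8)))
  # generalist parameters give higher P at low suitability than restricted ones
  gen <- conversion_params(-0.01, 0.4); res <- conversion_params(-0.05, 0.8)
  expect_gt(occurrence_probability(0.5, gen), occurrence_probability(0.5, res))
  hs <- seq(0, 1, by = 0.05)
  expect_true(all(diff(occurrence_probability(hs, cp)) > 0))
  expect_true(all(occurrence_probability(hs, cp) > 0 &
                  occurrence_probability(hs, cp) < 1))
  expect_error(conversion_params(alpha = 0), "non-zero")
  expect_error(occurrence_probability(1.5, cp), "hs must be")
})

test_that("presence-absence realization is seeded Bernoulli sampling", {
  ones <- matrix(1, 10, 10); zeros <- matrix(0, 10, 10)
  expect_true(all(realize_presence_absence(ones, 1) == 1))
  expect_true(all(realize_presence_absence(zeros, 1) == 0))
  p <- matrix(0.3, 100, 100)
  pa <- realize_presence_absence(p, seed = 5)
  expect_identical(pa, realize_presence_absence(p, seed = 5))
  expect_lt(abs(mean(pa) - 0.3), 3 * sqrt(0.3 * 0.7 / 1e4))
})

test_that("sampling applies detection only to presences and hits the binomial bound", {
  spec <- grid_spec(20, 20, cell_size = 10)
  all_pres <- matrix(1L, 20, 20)
  s1 <- sample_presabs(all_pres, spec, "whole_extent", n_points = 300,
                       n_samples = 3, detection_prob = 1, seed = 2)
  expect_true(all(vapply(s1, function(s) all(s$points$label == 1), logical(1))))
  expect_true(all(vapply(s1, function(s) nrow(s$points) == 300, logical(1))))
  s0 <- sample_presabs(all_pres, spec, "whole_extent", n_points = 300,
                       n_samples = 2, detection_prob = 0, seed = 2)
  expect_true(all(vapply(s0, function(s) all(s$points$label == 0), logical(1))))
  s75 <- sample_presabs(all_pres, spec, "whole_extent", n_points = 300,
                        n_samples = 50, detection_prob = 0.75, seed = 2)
  pooled <- mean(unlist(lapply(s75, function(s) s$points$label)))
  expect_lt(abs(pooled - 0.75), 3 * sqrt(0.75 * 0.25 / 15000))
})

test_that("buffered sampling raises sample prevalence for a sparse species", {
  wins <- 0
  for (s in 1:10) {
    set.seed(400 + s)
    spec <- grid_spec(30, 30, cell_size = 10)
    pa <- matrix(0L, 30, 30)
    # a sparse cluster of presences
    pa[cbind(sample(5:12, 30, TRUE), sample(5:12, 30, TRUE))] <- 1L
    buf <- sample_presabs(pa, spec, "buffered", buffer_km = 60,
                          n_seed_presences = 500, n_points = 100,
                          n_samples = 1, detection_prob = 1, seed = s)
    whole <- sample_presabs(pa, spec, "whole_extent", n_points = 100,
                            n_samples = 1, detection_prob = 1, seed = s)
    if (mean(buf[[1]]$points$label) >= mean(whole[[1]]$points$label)) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("prevalence ordering holds: generalist exceeds constrained archetypes", {
  for (s in 1:5) {
    clim <- generate_climate_pair(generator_config(n_rows = 30, n_cols = 30,
                                                   seed = 1000 + s))
    prev <- sapply(c("generalist", "alpine", "mediterranean", "restricted"),
      function(nm) {
        p <- species_preset(nm)
        hs <- simulate_suitability(clim$A, p, seed = s)
        mean(realize_presence_absence(
          occurrence_probability(hs$values, p$conversion), seed = s))
      })
    expect_true(all(prev["generalist"] > prev[-1]))
  }
})

test_that("sample coordinates round-trip through CSV bit-exactly", {
  spec <- grid_spec(12, 12, cell_size = sqrt(2))  # irrational coords
  pa <- matrix(rbinom(144, 1, 0.5), 12, 12)
  smp <- sample_presabs(pa, spec, "whole_extent", n_points = 50, n_samples = 2,
                        seed = 3)
  f <- tempfile(fileext = ".csv")
  write_samples_csv(smp, f)
  back <- read_samples_csv(f)
  expect_identical(back[[1]]$points$x, smp[[1]]$points$x)
  expect_identical(back[[2]]$points$y, smp[[2]]$points$y)
  expect_identical(back[[1]]$points$label, smp[[1]]$points$label)
})
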