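test_that("rmse follows its closed form", {
  expect_equal(rmse(c(0.2, 0.8), c(0, 1)), sqrt(mean(c(0.04, 0.04))))
  expect_equal(rmse(c(1, 0), c(1, 0)), 0)
  expect_equal(rmse(c(1, 0), c(0, 0)), sqrt(1 / 2))
  expect_equal(rmse(rep(0.5, 7), rbinom(7, 1, 0.5)), 0.5)
  expect_error(rmse(numeric(0), numeric(0)), "length")
})

test_that("AUC equals brute-force pair counting", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(auc(c(0.9, 0.4, 0.5, 0.2), c(1, 1, 0, 0)), 0.75)
  for (s in 1:25) {
    set.seed(s)
    n <- sample(5:60, 1)
    obs <- c(0, 1, rbinom(n - 2, 1, 0.5))
    pred <- round(runif(n), 2)  # ties likely
    expect_equal(auc(pred, obs), oracle_auc(pred, obs), tolerance = 1e-12)
  }
  expect_error(auc(runif(5), rep(1, 5)), "presence and")
})

test_that("best TSS equals the exhaustive scan and known confusion arithmetic", {
  # 40 TP / 10 FN / 30 TN / 20 FP at the optimum: tss = 0.8 + 0.6 - 1
  pred <- c(rep(0.9, 40), rep(0.1, 10), rep(0.2, 30), rep(0.95, 20))
  obs <- c(rep(1, 50), rep(0, 50))
  got <- tss_best(pred, obs)
  expect_equal(got$tss, 0.4)
  expect_equal(got$sensitivity, 0.8)
  expect_equal(got$specificity, 0.6)
  expect_equal(got$tss, got$sensitivity + got$specificity - 1)

  perfect <- tss_best(c(0.9, 0.8, 0.1), c(1, 1, 0))
  expect_equal(perfect$tss, 1)

  for (s in 1:25) {
    set.seed(100 + s)
    n <- sample(6:50, 1)
    obs <- c(0, 1, rbinom(n - 2, 1, 0.4))
    pred <- round(runif(n), 2)
    expect_equal(tss_best(pred, obs), oracle_tss(pred, obs), tolerance = 1e-12)
  }
})

test_that("model gating is inclusive at the thresholds", {
  m <- data.frame(auc = c(0.69, 0.7, 0.9, 0.71), tss = c(0.5, 0.4, 0.39, 0.8))
  expect_equal(select_models(m), c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(sum(select_models(data.frame(auc = 0.5, tss = 0.1))), 0)
})

test_that("all four learners separate a separable toy and predict in bounds", {
  toy <- separable_toy(n = 80, seed = 2)
  for (alg in c("glm", "gam", "gbm", "rf")) {
    fit <- fit_hsm(alg, toy[c("x1", "x2")], toy$y, seed = 7)
    p <- predict(fit, toy[c("x1", "x2")])
    expect_true(all(p >= 1e-6 & p <= 1 - 1e-6))
    expect_equal(auc(p, toy$y), 1)
  }
  expect_error(fit_hsm("glm", toy[c("x1", "x2")], rep(1, 80)), "single-class")
  dup <- data.frame(x1 = toy$x1, x2 = toy$x1)
  expect_error(fit_hsm("glm", dup, toy$y), "collinear")
})

test_that("null data yields near-chance test AUC for every learner", {
  aucs <- sapply(1:5, function(s) {
    set.seed(s)
    tr <- data.frame(x1 = rnorm(200), x2 = rnorm(200), y = rbinom(200, 1, 0.5))
    te <- data.frame(x1 = rnorm(200), x2 = rnorm(200), y = rbinom(200, 1, 0.5))
    fit <- fit_hsm("rf", tr[1:2], tr$y, seed = s)
    auc(predict(fit, te[1:2]), te$y)
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("AUC-weighted ensembles normalize weights and stay convex", {
  toy <- separable_toy(n = 60, seed = 3)
  m1 <- fit_hsm("glm", toy[1:2], toy$y)
  m2 <- fit_hsm("rf", toy[1:2], toy$y, seed = 1)
  ens <- ensemble_wmean(list(m1, m2), aucs = c(0.8, 0.9))
  expect_equal(ens$weights, c(0.8, 0.9) / 1.7)
  expect_equal(round(ens$weights, 4), c(0.4706, 0.5294))
  expect_equal(ens$tag, "EM_wmean")

  newx <- data.frame(x1 = rnorm(50), x2 = rnorm(50))
  pe <- predict(ens, newx)
  p1 <- predict(m1, newx); p2 <- predict(m2, newx)
  expect_equal(pe, p1 * ens$weights[1] + p2 * ens$weights[2])
  expect_true(all(pe >= pmin(p1, p2) - 1e-12 & pe <= pmax(p1, p2) + 1e-12))

  single <- ensemble_wmean(list(m1), aucs = 0.85)
  expect_equal(single$tag, "HSM_unique")
  expect_equal(predict(single, newx), p1)
  expect_error(ensemble_wmean(list(), numeric(0)), "empty")
})

test_that("standardized importance sums to 100 and ranks the stronger driver higher", {
  set.seed(5)
  n <- 300
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  y <- rbinom(n, 1, plogis(3 * d$x1 + 0.5 * d$x2))
  fit <- fit_hsm("glm", d, y)
  imp <- permutation_importance(fit, d, n_perm = 5, seed = 9)
  expect_equal(sum(imp$std_imp), 100, tolerance = 1e-9)
  expect_gt(imp$std_imp[imp$variable == "x1"], imp$std_imp[imp$variable == "x2"])

  # single-variable model concentrates all importance
  d1 <- data.frame(x1 = d$x1)
  f1 <- fit_hsm("glm", d1, y)
  imp1 <- permutation_importance(f1, d1, n_perm = 3, seed = 9)
  expect_equal(imp1$std_imp, 100)
})
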