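# Shared fixture builders for the test suite (all generated in code).

# A tiny stack with hand-set values: one variable, explicit matrix.
toy_stack <- function(values, cell_size = 1, mask = NULL, name = "bio1") {
  spec <- grid_spec(nrow(values), ncol(values), cell_size = cell_size, mask = mask)
  climate_stack(spec, stats::setNames(list(values), name))
}

# A multi-variable random stack on a small grid.
random_stack <- function(n = 12, n_vars = 3, seed = 1, cell_size = 10) {
  set.seed(seed)
  spec <- grid_spec(n, n, cell_size = cell_size)
  vals <- stats::setNames(
    lapply(seq_len(n_vars), function(j) matrix(rnorm(n * n, mean = j), n, n)),
    paste0("bio", seq_len(n_vars)))
  climate_stack(spec, vals)
}

# Labelled toy training data separable on x1.
separable_toy <- function(n = 60, seed = 1) {
  set.seed(seed)
  x1 <- c(rnorm(n / 2, -3, 0.5), rnorm(n / 2, 3, 0.5))
  data.frame(x1 = x1, x2 = rnorm(n),
             y = rep(c(0L, 1L), each = n / 2))
}

# Brute-force oracles -------------------------------------------------------

oracle_auc <- function(pred, obs) {
  p <- pred[obs == 1]; a <- pred[obs == 0]
  tot <- 0
  for (pi in p) for (ai in a)
    tot <- tot + if (pi > ai) 1 else if (pi == ai) 0.5 else 0
  tot / (length(p) * length(a))
}

oracle_tss <- function(pred, obs, step = 0.01) {
  best <- -Inf; out <- NULL
  for (t in seq(0, 1, by = step)) {
    sens <- mean(pred[obs == 1] >= t)
    spec <- mean(pred[obs == 0] < t)
    if (sens + spec - 1 > best + 1e-12) {
      best <- sens + spec - 1
      out <- list(tss = best, threshold = t, sensitivity = sens, specificity = spec)
    }
  }
  out
}

oracle_morans_i <- function(values, coords, d_min = 0, d_max = Inf) {
  n <- length(values)
  xb <- mean(values)
  num <- 0; s0 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    w <- (d > d_min && d <= d_max) || (d_min <= 0 && d == 0)
    if (w) {
      num <- num + (values[i] - xb) * (values[j] - xb)
      s0 <- s0 + 1
    }
  }
  (n / s0) * num / sum((values - xb)^2)
}

oracle_focal_r <- function(a, b, window) {
  h <- (window - 1) / 2
  out <- matrix(NA_real_, nrow(a), ncol(a))
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    ri <- max(1, i - h):min(nrow(a), i + h)
    cj <- max(1, j - h):min(ncol(a), j + h)
    va <- as.vector(a[ri, cj]); vb <- as.vector(b[ri, cj])
    if (sd(va) > 0 && sd(vb) > 0) out[i, j] <- cor(va, vb)
  }
  out
}
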