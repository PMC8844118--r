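#' Derive a reproducible sub-seed from a master seed and stage tags
#'
#' Every source of randomness in the workflow draws its seed through this
#' function, so that any single stage (one sample, one fold, one algorithm)
#' can be re-run in isolation from the master seed alone. The tags are hashed
#' with a small deterministic string hash (polynomial rolling hash mod a
#' Mersenne prime), mixed with the master seed, and reduced below 2^31 so the
#' result is always a valid R integer seed.
#'
#' @param master_seed integer master seed.
#' @param ... character or numeric tags naming the stage (coerced to
#'   character and concatenated).
#' @return an integer in `[0, 2^31 - 1]`.
#' @export
derive_seed <- function(master_seed, ...) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  tags <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = "_"),
                       character(1L)), collapse = "|")
  h <- 0
  m <- 2147483647  # 2^31 - 1
  for (code in utf8ToInt(tags)) h <- (h * 31 + code) %% m
  as.integer((abs(master_seed) %% m + h * 7919) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
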