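# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# Restores the caller's RNG stream afterwards so library calls never
# perturb user-level reproducibility.  seed = NULL runs on the current
# stream.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)  # materialise a stream so we can restore it
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Deterministic per-replicate sub-seeds from a master seed, so replicate k
# is reproducible in isolation.  Kept below 2^31 - 1.
replicate_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list((as.numeric(seed) + 1664525 * seq_len(n)) %% (.Machine$integer.max - 1) + 1)
}

# Normal draws with a hard lower truncation, by rejection.  Used for
# airway geometry where radii/lengths must stay positive and near the
# cast measurements.
rnorm_truncated <- function(n, mean, sd, lower) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n); lower <- rep_len(lower, n)
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower)
  guard <- 0L
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] < lower[bad]]
    guard <- guard + 1L
    if (guard > 1000L) {  # pathological sd; clamp rather than spin
      x[bad] <- lower[bad]
      break
    }
  }
  x
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}
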