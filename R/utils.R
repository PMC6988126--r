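# internal helpers shared across modules

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  code <- substitute(code)
  env <- parent.frame()
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  eval(code, env)
}

# normal(mean, sd) truncated at 0 by resampling (distances are physical)
rnorm_pos <- function(n, mean, sd) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < 0)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < 0]
  }
  out
}

# Wilson score 95% interval for a binomial proportion
wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
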