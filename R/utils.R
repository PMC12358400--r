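# Internal helpers shared across modules.

# Run code under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

.assertScalarNumeric <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a single finite number", call. = FALSE)
  invisible(x)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Truncated-normal draw by rejection on the cheap (scalar bounds, vector n).
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), if (length(mean) > 1) mean[bad] else mean,
                      if (length(sd) > 1) sd[bad] else sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}
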