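# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Inverse-CDF sampler for a normal truncated to [lo, hi]; deterministic in the
# RNG stream (one uniform per draw).
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (lo >= hi) stop("truncation bounds [", lo, ", ", hi, "] are empty")
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  if (phi - plo < .Machine$double.eps)
    stop("truncation to [", lo, ", ", hi, "] leaves no probability mass for mean=",
         mean, ", sd=", sd)
  u <- stats::runif(n, plo, phi)
  pmin(hi, pmax(lo, stats::qnorm(u, mean, sd)))
}

# Mean of a normal(mu, sd) truncated to [lo, hi].
truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# Location parameter mu such that the [lo, hi]-truncated normal(mu, sd)
# has the requested mean: truncation pulls the mean toward the interval
# center, so matching the target summary moment needs this offset.
match_truncnorm_mu <- function(target_mean, sd, lo, hi) {
  if (target_mean <= lo || target_mean >= hi)
    stop("target mean ", target_mean, " must lie inside (", lo, ", ", hi, ")")
  stats::uniroot(function(mu) truncnorm_mean(mu, sd, lo, hi) - target_mean,
                 interval = c(lo - 6 * sd, hi + 6 * sd), tol = 1e-10)$root
}

stopifnot_scalar <- function(x, name, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a single finite number")
  if (integer && x != round(x))
    stop("'", name, "' must be an integer")
  invisible(x)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
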