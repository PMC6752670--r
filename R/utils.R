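# Internal numerical and RNG helpers.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' previous RNG state, so simulation functions are reproducible without
#' clobbering the caller's random stream. A `NULL` seed leaves the RNG
#' untouched.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' log(sum(exp(x))) without overflow
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) {
    return(m)
  }
  m + log(sum(exp(x - m)))
}

#' Stop unless a scalar satisfies a predicate
#' @noRd
check_scalar <- function(x, name, ok) {
  if (length(x) != 1L || is.na(x) || !ok(x)) {
    stop(sprintf("invalid `%s`: %s", name, deparse(x)), call. = FALSE)
  }
  invisible(x)
}

is_count <- function(x) is.numeric(x) && x >= 0 && x == floor(x)
is_prob <- function(x) is.numeric(x) && x >= 0 && x <= 1

#' Credible interval of a discrete grid posterior
#'
#' Equal-tailed interval from the grid quantiles; when the posterior mode
#' sits on a boundary of [0, 1] the interval collapses to the one-sided
#' form anchored at that boundary (so a site with no alternative reads
#' reports ci_low = 0), keeping ci_low <= MAP <= ci_high.
#' @noRd
grid_interval <- function(grid, mass, level) {
  cdf <- cumsum(mass)
  mode_at <- which.max(mass)
  alpha <- (1 - level) / 2
  if (mode_at == 1L) {
    c(grid[1], grid[which(cdf >= level)[1]])
  } else if (mode_at == length(grid)) {
    c(grid[which(cdf >= 1 - level)[1]], grid[length(grid)])
  } else {
    c(grid[which(cdf >= alpha)[1]], grid[which(cdf >= 1 - alpha)[1]])
  }
}
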