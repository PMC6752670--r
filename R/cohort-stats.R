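# Cohort-level exact inference on a 2x2 table (sex x mosaic status):
# two-sided Fisher test by the point-probability method, the
# conditional-MLE odds ratio of the noncentral hypergeometric likelihood,
# and exact confidence bounds by test inversion. All hypergeometric mass
# is handled in log space (via lgamma through dhyper), so cohort-sized
# tables never overflow.

#' 2x2 contingency table of mosaic status by group
#'
#' Cell layout follows the cohort comparison: row 1 is males
#' (`a` mosaic, `b` non-mosaic), row 2 females (`c` mosaic, `d`
#' non-mosaic).
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return A `contingency_table` list.
#' @examples
#' contingency_table(3, 15, 2, 451)
#' @export
contingency_table <- function(a, b, c, d) {
  for (nm in c("a", "b", "c", "d")) {
    check_scalar(get(nm), nm, is_count)
  }
  if (a + b + c + d == 0) {
    stop("empty table: all cells zero")
  }
  structure(list(a = a, b = b, c = c, d = d), class = "contingency_table")
}

#' Build the 2x2 table from a cohort data frame
#'
#' @param cohort Data frame with `sex` (`"male"`/`"female"`) and a
#'   logical mosaic-status column.
#' @param status_col Name of the status column (default `"is_mosaic"`).
#' @return A [contingency_table()] (males on row 1).
#' @export
as_contingency <- function(cohort, status_col = "is_mosaic") {
  stopifnot(is.data.frame(cohort),
            all(c("sex", status_col) %in% names(cohort)))
  s <- cohort[[status_col]]
  contingency_table(
    a = sum(cohort$sex == "male" & s),
    b = sum(cohort$sex == "male" & !s),
    c = sum(cohort$sex == "female" & s),
    d = sum(cohort$sex == "female" & !s)
  )
}

# Support and log-mass of the (noncentral) hypergeometric distribution of
# the first cell given all margins; psi = 1 gives the central law.
nchg_support <- function(t) {
  m1 <- t$a + t$b
  m2 <- t$c + t$d
  k <- t$a + t$c
  max(0, k - m2):min(k, m1)
}

nchg_logmass <- function(t, psi) {
  x <- nchg_support(t)
  lw <- stats::dhyper(x, t$a + t$b, t$c + t$d, t$a + t$c, log = TRUE)
  if (psi != 1) {
    lw <- lw + x * log(psi)
  }
  lw - logsumexp(lw)
}

#' Two-sided Fisher exact test (point-probability method)
#'
#' With all margins fixed, the first cell follows the central
#' hypergeometric law; the two-sided p-value sums the probabilities of
#' every admissible table whose point probability does not exceed that of
#' the observed table (within a 1e-7 relative tolerance for ties). A
#' degenerate margin makes every admissible table identical, and p = 1
#' with a warning.
#'
#' @param t A [contingency_table()].
#' @return The two-sided p-value.
#' @examples
#' fisher_two_sided(contingency_table(3, 15, 2, 451))
#' @export
fisher_two_sided <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  if (t$a + t$b == 0 || t$c + t$d == 0 ||
      t$a + t$c == 0 || t$b + t$d == 0) {
    warning("degenerate margin: p = 1", call. = FALSE)
    return(1)
  }
  lm <- nchg_logmass(t, 1)
  x <- nchg_support(t)
  l_obs <- lm[x == t$a]
  sum(exp(lm[lm <= l_obs + 1e-7]))
}

#' Conditional-MLE odds ratio with exact bounds
#'
#' The point estimate maximizes the noncentral hypergeometric likelihood
#' of the observed first cell given all margins (the estimate exact-test
#' software reports), found as the root of the score equation
#' `E_psi[X] = a` in `log(psi)` to high precision. Exact confidence
#' bounds invert the one-tailed exact tests: the lower bound is the `psi`
#' at which `P(X >= a | psi)` equals the tail level, the upper bound
#' symmetric on the other tail. A zero cell on the corresponding diagonal
#' gives a 0 or unbounded (Inf) estimate, flagged in the result.
#'
#' @param t A [contingency_table()].
#' @param level Confidence level (default 0.95).
#' @param sides 2 for a two-sided interval (tail level `(1-level)/2` per
#'   side), 1 for a one-sided lower bound with an interval open above —
#'   the form used when reporting "CI lower -- inf".
#' @return An `odds_ratio_result` list: `or_cmle`, `ci_low`, `ci_high`,
#'   `p_two_sided`, `sides`, `level`, `boundary` flag.
#' @examples
#' odds_ratio_exact(contingency_table(3, 15, 2, 451), sides = 1)
#' @export
odds_ratio_exact <- function(t, level = 0.95, sides = 2) {
  stopifnot(inherits(t, "contingency_table"), sides %in% c(1, 2))
  check_scalar(level, "level", function(x) x > 0 && x < 1)
  est <- or_cmle(t)
  alpha <- if (sides == 2) (1 - level) / 2 else 1 - level
  ci_low <- or_exact_bound(t, level = 1 - alpha, side = "lower")
  ci_high <- if (sides == 2) {
    or_exact_bound(t, level = 1 - alpha, side = "upper")
  } else {
    Inf
  }
  structure(list(or_cmle = est, ci_low = ci_low, ci_high = ci_high,
                 p_two_sided = fisher_two_sided(t), sides = sides,
                 level = level,
                 boundary = !is.finite(est) || est == 0),
            class = "odds_ratio_result")
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  cat(sprintf(
    "conditional-MLE odds ratio = %.4g, %d%% CI [%.4g, %.4g] (%s), two-sided p = %.4g\n",
    x$or_cmle, round(100 * x$level), x$ci_low, x$ci_high,
    if (x$sides == 1) "one-sided" else "two-sided", x$p_two_sided))
  invisible(x)
}

# expected first cell under the noncentral law at log-odds lp
nchg_mean <- function(t, log_psi) {
  x <- nchg_support(t)
  sum(x * exp(nchg_logmass(t, exp(log_psi))))
}

#' Conditional maximum-likelihood odds ratio (point estimate)
#'
#' @param t A [contingency_table()].
#' @return The CMLE `psi`; 0 or `Inf` for boundary tables (observed cell
#'   at the edge of its support).
#' @export
or_cmle <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  supp <- nchg_support(t)
  if (length(supp) == 1) {
    return(1)   # margins fix the table completely; no information
  }
  if (t$a == min(supp)) {
    return(0)
  }
  if (t$a == max(supp)) {
    return(Inf)
  }
  score <- function(lp) nchg_mean(t, lp) - t$a
  lo <- -1
  while (score(lo) > 0) lo <- lo * 2
  hi <- 1
  while (score(hi) < 0) hi <- hi * 2
  root <- stats::uniroot(score, c(lo, hi), tol = 1e-10)$root
  exp(root)
}

#' Exact confidence bound for the odds ratio by test inversion
#'
#' @param t A [contingency_table()].
#' @param level One-sided confidence level of the bound (e.g. 0.975 for
#'   one side of a two-sided 95% interval, 0.95 for a one-sided bound).
#' @param side `"lower"` or `"upper"`.
#' @return The bound; 0 (lower) or `Inf` (upper) for boundary tables.
#' @export
or_exact_bound <- function(t, level = 0.975,
                           side = c("lower", "upper")) {
  stopifnot(inherits(t, "contingency_table"))
  side <- match.arg(side)
  check_scalar(level, "level", function(x) x > 0 && x < 1)
  alpha <- 1 - level
  supp <- nchg_support(t)
  if (length(supp) == 1) {
    return(if (side == "lower") 0 else Inf)
  }
  if (side == "lower" && t$a == min(supp)) {
    return(0)
  }
  if (side == "upper" && t$a == max(supp)) {
    return(Inf)
  }
  tail_prob <- function(lp) {
    lm <- nchg_logmass(t, exp(lp))
    if (side == "lower") {
      sum(exp(lm[supp >= t$a]))     # increasing in psi
    } else {
      sum(exp(lm[supp <= t$a]))     # decreasing in psi
    }
  }
  f <- function(lp) tail_prob(lp) - alpha
  want_lower <- side == "lower"
  lo <- -1
  while ((f(lo) > 0) == want_lower) lo <- lo * 2
  hi <- 1
  while ((f(hi) < 0) == want_lower) hi <- hi * 2
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-10)$root)
}

#' Rate summary with exact binomial interval
#'
#' @param x Successes (e.g. confirmed mosaic subjects).
#' @param n Trials (cohort size); at least 1.
#' @param level Confidence level.
#' @return A `rate_summary` list: `numerator`, `denominator`,
#'   `proportion`, `percent` (display value, one decimal),
#'   `ci_low`, `ci_high` (Clopper-Pearson on the proportion).
#' @examples
#' rate_summary(5, 471)
#' @export
rate_summary <- function(x, n, level = 0.95) {
  check_scalar(n, "n", function(z) is_count(z) && z >= 1)
  check_scalar(x, "x", function(z) is_count(z) && z <= n)
  alpha <- (1 - level) / 2
  structure(list(
    numerator = x, denominator = n, proportion = x / n,
    percent = round(100 * x / n, 1),
    ci_low = if (x == 0) 0 else stats::qbeta(alpha, x, n - x + 1),
    ci_high = if (x == n) 1 else stats::qbeta(1 - alpha, x + 1, n - x),
    level = level
  ), class = "rate_summary")
}

#' @export
print.rate_summary <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% (%d%% CI %.2f%%-%.2f%%)\n", x$numerator,
              x$denominator, x$percent, round(100 * x$level),
              100 * x$ci_low, 100 * x$ci_high))
  invisible(x)
}
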