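# Amplicon-validation stage (PASM): hierarchical Bayesian MAF estimation
# from ~12,000x amplicon counts. The hierarchy is a Beta-distributed
# per-base error rate learned from negative-control sites and
# marginalized out of the site likelihood by quadrature, so the MAF
# credible interval carries the uncertainty in the platform error rate.

#' Validation-stage thresholds
#'
#' Decision bands of the amplicon-validation caller. The hom-ref bound is
#' the same 0.5% as at screening; the het band is deliberately wider
#' (40--60% instead of 45--55%) because validation must not promote a
#' borderline constitutional heterozygote to a mosaic call.
#'
#' @param homref_lower_bound Lower-CI threshold (default 0.005).
#' @param het_band Length-2 MAP band for het (default `c(0.40, 0.60)`).
#' @return A `pasm_thresholds` list.
#' @export
pasm_thresholds <- function(homref_lower_bound = 0.005,
                            het_band = c(0.40, 0.60)) {
  stopifnot(homref_lower_bound > 0, homref_lower_bound < het_band[1],
            length(het_band) == 2, het_band[1] < het_band[2])
  structure(list(homref_lower_bound = homref_lower_bound,
                 het_band = het_band),
            class = "pasm_thresholds")
}

#' Fit the shared error-rate model from negative-control sites
#'
#' Control sites are amplicon positions known to be free of the variant;
#' their alt-read fractions are platform error. A Beta distribution is
#' moment-matched to the per-site alt fractions (mean and variance), with
#' the mean floored at `1e-6` so a run of perfectly clean controls still
#' yields a proper, near-zero error distribution. When the sample
#' variance is degenerate (fewer than two distinct fractions, or
#' incompatible with a Beta), the concentration falls back to the pooled
#' control depth, i.e. the tightest error posterior the data could
#' support.
#'
#' @param control_sites Data frame with `ref_count` and `alt_count`
#'   columns; at least 3 rows.
#' @return An `error_model` list: `alpha`, `beta`, `point_estimate`
#'   (the Beta mean), `n_controls`.
#' @examples
#' ctrl <- data.frame(ref_count = c(11988, 11990, 11985),
#'                    alt_count = c(12, 10, 15))
#' fit_error_model(ctrl)
#' @export
fit_error_model <- function(control_sites) {
  stopifnot(is.data.frame(control_sites),
            all(c("ref_count", "alt_count") %in% names(control_sites)))
  if (nrow(control_sites) < 3) {
    stop("need at least 3 control sites to fit the error model")
  }
  n <- control_sites$ref_count + control_sites$alt_count
  stopifnot(all(n >= 1))
  x <- control_sites$alt_count / n
  if (all(control_sites$alt_count == 0)) {
    warning("all control sites have zero alt reads; ",
            "error model floored at 1e-6", call. = FALSE)
  }
  m <- max(mean(x), 1e-6)
  if (m >= 0.5) {
    stop("control alt fraction >= 0.5: controls are not variant-free")
  }
  v <- stats::var(x)
  conc <- if (!is.finite(v) || v <= 0 || v >= m * (1 - m)) {
    sum(n)                      # degenerate variance: pooled-depth prior
  } else {
    m * (1 - m) / v - 1
  }
  conc <- max(conc, 2)
  structure(list(alpha = m * conc, beta = (1 - m) * conc,
                 point_estimate = m,
                 n_controls = nrow(control_sites)),
            class = "error_model")
}

#' A degenerate (point-mass) error model
#'
#' Convenience constructor for an error model concentrated at a known
#' rate; with it [pasm_maf()] reduces to the screening-stage posterior
#' [maf_posterior()].
#'
#' @param error_rate The fixed per-base error rate.
#' @param concentration Beta concentration (default `1e12`, effectively a
#'   point mass).
#' @return An `error_model` list.
#' @export
point_error_model <- function(error_rate, concentration = 1e12) {
  check_scalar(error_rate, "error_rate",
               function(x) is.numeric(x) && x >= 0 && x < 0.5)
  e <- max(error_rate, 1e-12)
  structure(list(alpha = e * concentration,
                 beta = (1 - e) * concentration,
                 point_estimate = e, n_controls = 0L),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf(
    "Beta error model: alpha=%.4g beta=%.4g (mean %.3g, %d controls)\n",
    x$alpha, x$beta, x$point_estimate, x$n_controls))
  invisible(x)
}

#' Hierarchical Bayesian MAF estimate from amplicon counts
#'
#' Grid posterior of the MAF `f` with the per-base error rate `e`
#' marginalized over its fitted Beta distribution: the site likelihood is
#' `L(f) = E_e[ Binomial(k; n, f (1 - e) + (1 - f) e) ]`, evaluated by
#' midpoint quadrature over `nodes` Beta quantiles (the error posterior
#' is tight at 12,000x, so 32 nodes are ample). MAP and equal-tailed 95%
#' credible interval are read off the grid as at screening.
#'
#' @param k Alternative-allele read count.
#' @param n Total amplicon depth; at least 1.
#' @param error_model An `error_model` from [fit_error_model()] or
#'   [point_error_model()].
#' @param grid_resolution Grid step (default `1e-4`).
#' @param nodes Number of quadrature nodes (default 32).
#' @param level Credible level (default 0.95).
#' @return A `maf_estimate` list: `map_maf`, `ci_low`, `ci_high`,
#'   `method = "pasm"`, `depth`, `k`.
#' @export
pasm_maf <- function(k, n, error_model, grid_resolution = 1e-4,
                     nodes = 32, level = 0.95) {
  check_scalar(n, "n", function(x) is_count(x) && x >= 1)
  check_scalar(k, "k", function(x) is_count(x) && x <= n)
  stopifnot(inherits(error_model, "error_model"))
  grid <- seq(0, 1, by = grid_resolution)
  e_nodes <- stats::qbeta((seq_len(nodes) - 0.5) / nodes,
                          error_model$alpha, error_model$beta)
  # log-likelihood matrix (grid x nodes), averaged over nodes in log space
  ll <- vapply(e_nodes, function(e) {
    stats::dbinom(k, n, grid * (1 - e) + (1 - grid) * e, log = TRUE)
  }, numeric(length(grid)))
  m <- apply(ll, 1, max)
  logpost <- m + log(rowMeans(exp(ll - m)))
  mass <- exp(logpost - max(logpost))
  mass <- mass / sum(mass)
  ci <- grid_interval(grid, mass, level)
  maf_estimate(
    map_maf = grid[which.max(mass)],
    ci_low = ci[1],
    ci_high = ci[2],
    method = "pasm", depth = n, k = k, level = level
  )
}

#' MAF estimate container
#'
#' The universal quantification result shared by the screening, amplicon
#' and ddPCR stages: a MAP (or point) MAF with its 95% interval and the
#' provenance of the estimate.
#'
#' @param map_maf Point estimate.
#' @param ci_low,ci_high Interval bounds.
#' @param method One of `"screen"`, `"pasm"`, `"ddpcr"`.
#' @param depth Read depth or droplet total behind the estimate.
#' @param k Mutant-supporting count.
#' @param level Interval level.
#' @param flag Optional quality flag (e.g. `"not_quantifiable"`,
#'   `"saturated"`).
#' @return A `maf_estimate` list.
#' @export
maf_estimate <- function(map_maf, ci_low, ci_high, method, depth = NA,
                         k = NA, level = 0.95, flag = NA_character_) {
  if (!is.na(map_maf)) {
    stopifnot(ci_low <= map_maf + 1e-12, map_maf <= ci_high + 1e-12,
              ci_low >= 0, ci_high <= 1)
  }
  structure(list(map_maf = map_maf, ci_low = ci_low, ci_high = ci_high,
                 method = method, depth = depth, k = k, level = level,
                 flag = flag),
            class = "maf_estimate")
}

#' @export
print.maf_estimate <- function(x, ...) {
  cat(sprintf("MAF [%s]: %.4f, %d%% CI [%.4f, %.4f]%s\n", x$method,
              x$map_maf, round(100 * x$level), x$ci_low, x$ci_high,
              if (!is.na(x$flag)) paste0(" <", x$flag, ">") else ""))
  invisible(x)
}

#' Validation decision for a candidate mosaic variant
#'
#' A candidate validates as mosaic when its lower 95% credible bound
#' clears the 0.5% hom-ref threshold and its MAP MAF lies outside the
#' 40--60% het band; a MAP inside the het band is called constitutional
#' het; anything else is not confirmed.
#'
#' @param est A `maf_estimate` (any method).
#' @param thresholds A [pasm_thresholds()].
#' @return One of `"mosaic_confirmed"`, `"het"`, `"not_confirmed"`.
#' @export
validate_candidate <- function(est, thresholds = pasm_thresholds()) {
  stopifnot(inherits(est, "maf_estimate"),
            inherits(thresholds, "pasm_thresholds"))
  if (is.na(est$map_maf)) {
    return("not_confirmed")
  }
  in_het <- est$map_maf >= thresholds$het_band[1] &&
    est$map_maf <= thresholds$het_band[2]
  if (in_het) {
    "het"
  } else if (est$ci_low >= thresholds$homref_lower_bound) {
    "mosaic_confirmed"
  } else {
    "not_confirmed"
  }
}
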