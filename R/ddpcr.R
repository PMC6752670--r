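# Droplet digital PCR quantification: rectangular-gate droplet
# classification, MAF = MU/(MU+WT) with an exact Clopper-Pearson
# interval, an optional Poisson occupancy correction, and a
# simulation-based limit-of-detection power analysis.

#' Droplet count container
#'
#' @param mu Mutant-positive droplets (MU; FAM channel).
#' @param wt Wild-type-only droplets (WT; VIC channel).
#' @param na Empty droplets (NA signal).
#' @return A `droplet_data` list with `total = mu + wt + na`.
#' @export
droplet_data <- function(mu, wt, na) {
  check_scalar(mu, "mu", is_count)
  check_scalar(wt, "wt", is_count)
  check_scalar(na, "na", is_count)
  structure(list(mu = as.numeric(mu), wt = as.numeric(wt),
                 na = as.numeric(na),
                 total = as.numeric(mu) + as.numeric(wt) + as.numeric(na)),
            class = "droplet_data")
}

#' @export
print.droplet_data <- function(x, ...) {
  cat(sprintf("droplets: MU=%g WT=%g NA=%g (total %g)\n",
              x$mu, x$wt, x$na, x$total))
  invisible(x)
}

#' Classify droplets from two-channel fluorescence
#'
#' Rectangular gating of the FAM (mutant) / VIC (wild-type) scatter: a
#' droplet at or above `fam_threshold` is MU regardless of VIC (the
#' mutant probe signal dominates); otherwise at or above `vic_threshold`
#' it is WT; otherwise empty. The lower bounds are closed: a droplet
#' exactly at threshold is positive. Records with non-finite intensities
#' are dropped with a warning reporting how many.
#'
#' @param records Data frame with numeric `fam` and `vic` columns.
#' @param fam_threshold,vic_threshold Positive gate thresholds.
#' @return A [droplet_data()]; the number of rejected records is attached
#'   as attribute `n_rejected`.
#' @export
classify_droplets <- function(records, fam_threshold, vic_threshold) {
  stopifnot(is.data.frame(records),
            all(c("fam", "vic") %in% names(records)))
  check_scalar(fam_threshold, "fam_threshold",
               function(x) is.numeric(x) && x > 0)
  check_scalar(vic_threshold, "vic_threshold",
               function(x) is.numeric(x) && x > 0)
  ok <- is.finite(records$fam) & is.finite(records$vic)
  if (any(!ok)) {
    warning(sum(!ok), " droplet record(s) with non-finite intensity ",
            "rejected", call. = FALSE)
    records <- records[ok, , drop = FALSE]
  }
  is_mu <- records$fam >= fam_threshold
  is_wt <- !is_mu & records$vic >= vic_threshold
  d <- droplet_data(mu = sum(is_mu), wt = sum(is_wt),
                    na = sum(!is_mu & !is_wt))
  attr(d, "n_rejected") <- sum(!ok)
  d
}

#' MAF from droplet counts with exact binomial interval
#'
#' The primary ddPCR estimate: `MAF = MU / (MU + WT)`, with the exact
#' Clopper-Pearson 95% confidence interval for `MU` successes in
#' `MU + WT` trials (beta-quantile form). A run with no positive droplets
#' is flagged `not_quantifiable`.
#'
#' @param d A [droplet_data()].
#' @param level Confidence level (default 0.95).
#' @return A [maf_estimate()] with `method = "ddpcr"`.
#' @examples
#' maf_from_droplets(droplet_data(mu = 1000, wt = 9000, na = 90000))
#' @export
maf_from_droplets <- function(d, level = 0.95) {
  stopifnot(inherits(d, "droplet_data"))
  n <- d$mu + d$wt
  if (n < 1) {
    return(maf_estimate(NA_real_, NA_real_, NA_real_, method = "ddpcr",
                        depth = d$total, k = d$mu,
                        flag = "not_quantifiable"))
  }
  alpha <- (1 - level) / 2
  ci_low <- if (d$mu == 0) 0 else stats::qbeta(alpha, d$mu, d$wt + 1)
  ci_high <- if (d$wt == 0) 1 else stats::qbeta(1 - alpha, d$mu + 1, d$wt)
  maf_estimate(map_maf = d$mu / n, ci_low = ci_low, ci_high = ci_high,
               method = "ddpcr", depth = n, k = d$mu, level = level)
}

#' Poisson occupancy-corrected MAF
#'
#' At higher droplet occupancy a positive droplet may hold several
#' template molecules, so raw positive-droplet fractions underestimate
#' concentrations. Per-channel concentrations are recovered as
#' `lambda = -log(1 - positives / total)` and the corrected MAF is
#' `lambda_mu / (lambda_mu + lambda_wt)`. The interval is the raw
#' Clopper-Pearson interval mapped through the same (monotone)
#' correction. A saturated channel (all droplets positive) has infinite
#' concentration and is flagged.
#'
#' @param d A [droplet_data()]; needs `na >= 1` so occupancy is
#'   estimable.
#' @param level Confidence level.
#' @return A [maf_estimate()] with `method = "ddpcr"`; `flag =
#'   "saturated"` (with `NA` estimate) when a channel saturates.
#' @export
poisson_corrected_maf <- function(d, level = 0.95) {
  stopifnot(inherits(d, "droplet_data"))
  if (d$mu == d$total || d$wt == d$total) {
    warning("saturated channel: infinite concentration", call. = FALSE)
    return(maf_estimate(NA_real_, NA_real_, NA_real_, method = "ddpcr",
                        depth = d$total, k = d$mu, flag = "saturated"))
  }
  if (d$na < 1) {
    stop("occupancy correction needs at least one empty droplet")
  }
  n_pos <- d$mu + d$wt
  if (n_pos < 1) {
    return(maf_estimate(NA_real_, NA_real_, NA_real_, method = "ddpcr",
                        depth = d$total, k = d$mu,
                        flag = "not_quantifiable"))
  }
  correct <- function(r) {
    # r = fraction of positives that are MU; fixed positive total n_pos
    lam_mu <- -log1p(-(r * n_pos) / d$total)
    lam_wt <- -log1p(-((1 - r) * n_pos) / d$total)
    if (lam_mu + lam_wt == 0) return(0.5)
    lam_mu / (lam_mu + lam_wt)
  }
  raw <- maf_from_droplets(d, level = level)
  maf_estimate(map_maf = correct(raw$map_maf),
               ci_low = correct(raw$ci_low),
               ci_high = correct(raw$ci_high),
               method = "ddpcr", depth = n_pos, k = d$mu, level = level)
}

#' Detection power of the ddPCR assay by simulation
#'
#' Estimates the probability that a run detects a mosaic at `true_maf`
#' given the template load and droplet count, by repeated simulation
#' through [simulate_droplets()]. The default decision rule calls a run
#' positive when at least 3 mutant droplets are observed; the assay's
#' quoted detection limit (1e-4 mutant fraction) corresponds to the load
#' at which this power saturates.
#'
#' @param true_maf True mutant fraction of the loaded template.
#' @param total_copies Template molecules loaded.
#' @param n_droplets Droplets per run.
#' @param reps Number of simulated runs (at least 100).
#' @param decision_rule Function of a [droplet_data()] returning `TRUE`
#'   for a detection; default `mu >= 3`.
#' @param false_mu_rate Assay false-positive rate passed to the
#'   simulator.
#' @param seed Integer RNG seed or `NULL`.
#' @return Detection probability (fraction of positive runs).
#' @export
lod_power <- function(true_maf, total_copies, n_droplets = 5e5,
                      reps = 500, decision_rule = function(d) d$mu >= 3,
                      false_mu_rate = 0, seed = NULL) {
  check_scalar(reps, "reps", function(x) is_count(x) && x >= 100)
  with_seed(seed, {
    hits <- vapply(seq_len(reps), function(i) {
      d <- simulate_droplets(droplet_sim_config(
        true_maf = true_maf, total_copies = total_copies,
        n_droplets = n_droplets, false_mu_rate = false_mu_rate))
      isTRUE(decision_rule(d))
    }, logical(1))
    mean(hits)
  })
}

#' Scatter plot of classified droplets
#'
#' @param records Data frame of `fam`, `vic` intensities.
#' @param fam_threshold,vic_threshold Gate thresholds, drawn as dashed
#'   lines.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the [droplet_data()] classification.
#' @export
plot_droplets <- function(records, fam_threshold, vic_threshold, ...) {
  d <- classify_droplets(records, fam_threshold, vic_threshold)
  cls <- ifelse(records$fam >= fam_threshold, "MU",
                ifelse(records$vic >= vic_threshold, "WT", "NA"))
  cols <- c(MU = "#d62728", WT = "#1f77b4", `NA` = "grey60")
  graphics::plot(records$vic, records$fam, col = cols[cls], pch = 16,
                 cex = 0.4, xlab = "VIC intensity (wild type)",
                 ylab = "FAM intensity (mutant)", ...)
  graphics::abline(h = fam_threshold, v = vic_threshold, lty = 2)
  invisible(d)
}
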