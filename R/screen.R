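# Screening-stage Bayesian genotyper: a grid posterior over the mutant
# allelic fraction (MAF) from per-site ref/alt read counts, and the
# credible-interval classification into hom-ref / het / hom-alt /
# mosaic-candidate used to nominate candidates from ~1000x panel data.

#' Screening-stage genotype thresholds
#'
#' The decision bands of the screening genotyper: a site whose 95%
#' credible interval reaches below `homref_lower_bound` (0.5%) is called
#' reference-homozygous; a MAP MAF inside `het_band` (45--55%) is
#' heterozygous; a MAP MAF inside `homalt_band` is
#' alternative-homozygous; anything else is a mosaic candidate.
#'
#' @param homref_lower_bound Lower-CI threshold for hom-ref (default
#'   0.005).
#' @param het_band Length-2 MAP band for het (default `c(0.45, 0.55)`).
#' @param homalt_band Length-2 MAP band for hom-alt (default
#'   `c(0.995, 1)`).
#' @return A `screen_thresholds` list.
#' @export
screen_thresholds <- function(homref_lower_bound = 0.005,
                              het_band = c(0.45, 0.55),
                              homalt_band = c(0.995, 1)) {
  stopifnot(homref_lower_bound > 0, homref_lower_bound < het_band[1],
            length(het_band) == 2, het_band[1] < het_band[2],
            length(homalt_band) == 2, het_band[2] < homalt_band[1],
            homalt_band[2] <= 1)
  structure(list(homref_lower_bound = homref_lower_bound,
                 het_band = het_band, homalt_band = homalt_band),
            class = "screen_thresholds")
}

#' Posterior distribution of the mutant allelic fraction at one site
#'
#' Computes the posterior of the MAF `f` given `k` alternative reads out
#' of `n`, on a uniform grid over `[0, 1]`. The likelihood folds the
#' sequencing error symmetrically: a read supports the alternative allele
#' with probability `p(f) = f (1 - e) + (1 - f) e`, so
#' `k ~ Binomial(n, p(f))`. The default prior is uniform on `[0, 1]`.
#' The reported interval is the equal-tailed 95% credible interval of the
#' discrete grid posterior.
#'
#' @param k Alternative-allele read count.
#' @param n Total read depth (`ref + alt`); must be at least 1.
#' @param error_rate Per-base miscall probability `e` in `[0, 0.5)`.
#' @param grid_resolution Grid step (default `1e-4`, more than 10x finer
#'   than the 0.5% decision boundary).
#' @param prior `"uniform"`, or a numeric vector of unnormalized prior
#'   weights over the grid.
#' @param level Credible level (default 0.95).
#' @return A `maf_posterior` object: `grid`, `density` (posterior mass,
#'   summing to 1), `map_maf`, `ci_low`, `ci_high`, plus the inputs.
#' @examples
#' post <- maf_posterior(k = 65, n = 1000, error_rate = 1e-3)
#' post$map_maf
#' @export
maf_posterior <- function(k, n, error_rate = 0, grid_resolution = 1e-4,
                          prior = "uniform", level = 0.95) {
  check_scalar(n, "n", function(x) is_count(x) && x >= 1)
  check_scalar(k, "k", function(x) is_count(x) && x <= n)
  check_scalar(error_rate, "error_rate",
               function(x) is.numeric(x) && x >= 0 && x < 0.5)
  grid <- seq(0, 1, by = grid_resolution)
  p <- grid * (1 - error_rate) + (1 - grid) * error_rate
  logpost <- stats::dbinom(k, n, p, log = TRUE)
  if (is.numeric(prior)) {
    stopifnot(length(prior) == length(grid), all(prior >= 0))
    logpost <- logpost + log(prior)
  } else if (!identical(prior, "uniform")) {
    stop("unknown prior: ", prior)
  }
  mass <- exp(logpost - max(logpost))
  mass <- mass / sum(mass)
  ci <- grid_interval(grid, mass, level)
  structure(list(
    grid = grid,
    density = mass,
    map_maf = grid[which.max(mass)],
    ci_low = ci[1],
    ci_high = ci[2],
    k = k, n = n, error_rate = error_rate, level = level
  ), class = "maf_posterior")
}

#' @export
print.maf_posterior <- function(x, ...) {
  cat(sprintf(
    "MAF posterior: k=%d n=%d e=%g | MAP=%.4f, %d%% CI [%.4f, %.4f]\n",
    x$k, x$n, x$error_rate, x$map_maf, round(100 * x$level),
    x$ci_low, x$ci_high))
  invisible(x)
}

#' Classify one site from its MAF posterior
#'
#' Applies the screening decision bands in order: hom-ref if the lower
#' 95% credible bound falls below 0.5%; else het if the MAP MAF lies in
#' 45--55%; else hom-alt if the MAP MAF lies in 99.5--100%; otherwise the
#' site is a mosaic candidate. The call is a pure function of the
#' posterior and the thresholds.
#'
#' @param post A [maf_posterior()].
#' @param thresholds A [screen_thresholds()].
#' @param site_id Optional identifier carried into the call.
#' @return A one-row data frame: `site_id`, `label`, `map_maf`, `ci_low`,
#'   `ci_high`.
#' @export
classify_site <- function(post, thresholds = screen_thresholds(),
                          site_id = NA_character_) {
  stopifnot(inherits(post, "maf_posterior"),
            inherits(thresholds, "screen_thresholds"))
  label <- if (post$ci_low < thresholds$homref_lower_bound) {
    "hom_ref"
  } else if (post$map_maf >= thresholds$het_band[1] &&
             post$map_maf <= thresholds$het_band[2]) {
    "het"
  } else if (post$map_maf >= thresholds$homalt_band[1] &&
             post$map_maf <= thresholds$homalt_band[2]) {
    "hom_alt"
  } else {
    "mosaic_candidate"
  }
  data.frame(site_id = site_id, label = label, map_maf = post$map_maf,
             ci_low = post$ci_low, ci_high = post$ci_high,
             stringsAsFactors = FALSE)
}

#' Screen a table of pileup sites
#'
#' Runs [maf_posterior()] and [classify_site()] over every row of a site
#' table, order-preserving. Malformed rows (missing or negative counts)
#' are reported by `site_id` in a warning and returned with label
#' `"malformed"`; the run continues.
#'
#' @param sites Data frame with columns `site_id`, `ref_count`,
#'   `alt_count`, and optionally `error_rate` (else `error_rate` applies).
#' @param thresholds A [screen_thresholds()].
#' @param error_rate Fallback per-base error rate for rows without one.
#' @param grid_resolution Posterior grid step.
#' @return Data frame of calls (one row per site) with a `summary`
#'   attribute of counts per label.
#' @export
screen_sites <- function(sites, thresholds = screen_thresholds(),
                         error_rate = 1e-3, grid_resolution = 1e-4) {
  stopifnot(is.data.frame(sites), nrow(sites) >= 1,
            all(c("site_id", "ref_count", "alt_count") %in% names(sites)))
  e_col <- if ("error_rate" %in% names(sites)) sites$error_rate else
    rep(error_rate, nrow(sites))
  calls <- vector("list", nrow(sites))
  bad <- character()
  for (i in seq_len(nrow(sites))) {
    rk <- sites$alt_count[i]
    rn <- sites$ref_count[i] + sites$alt_count[i]
    ok <- !is.na(rk) && !is.na(rn) && rk >= 0 && rn >= 1 && rk <= rn
    if (!ok) {
      bad <- c(bad, as.character(sites$site_id[i]))
      calls[[i]] <- data.frame(site_id = sites$site_id[i],
                               label = "malformed", map_maf = NA_real_,
                               ci_low = NA_real_, ci_high = NA_real_,
                               stringsAsFactors = FALSE)
      next
    }
    post <- maf_posterior(rk, rn, error_rate = e_col[i],
                          grid_resolution = grid_resolution)
    calls[[i]] <- classify_site(post, thresholds,
                                site_id = sites$site_id[i])
  }
  if (length(bad) > 0) {
    warning("malformed site rows skipped: ", paste(bad, collapse = ", "),
            call. = FALSE)
  }
  out <- do.call(rbind, calls)
  attr(out, "summary") <- table(out$label)
  out
}
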