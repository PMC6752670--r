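# Synthetic-data generators emulating the study's inputs: deep panel
# pileups, ultra-deep amplicon counts, droplet digital PCR runs, a
# sex-stratified cohort, and multi-tissue MAF panels. All generators are
# two-stage where the assay is: a finite pool of input genome copies is
# drawn first, then reads (or droplets) sample that pool, so the
# copy-number-limited sensitivity of the assays is reproduced.

#' Configuration for read-count simulation
#'
#' Describes one batch of simulated pileup sites: the true mutant allelic
#' fraction (MAF), the mean sequencing depth, the number of input genome
#' copies available to the library (the amplification bottleneck), and the
#' per-base miscall probability.
#'
#' @param true_maf True mutant allelic fraction in `[0, 1]`.
#' @param depth Mean read depth per site (panel default 1000x).
#' @param input_copies Number of genome copies entering amplification;
#'   10 ng of genomic DNA is roughly 3000 copies (panel default). Use
#'   `Inf` for a bottleneck-free binomial read model.
#' @param error_rate Per-base miscall probability, Phred-derived; default
#'   `1e-3` (Q30). Must be below 0.5 (the non-informative regime).
#' @param n_sites Number of sites to emit.
#' @param seed Integer RNG seed, or `NULL` to use the current stream.
#' @return A `sim_config` list.
#' @examples
#' cfg <- sim_config(true_maf = 0.2, depth = 1000, n_sites = 5, seed = 1)
#' simulate_pileup(cfg)
#' @export
sim_config <- function(true_maf, depth = 1000, input_copies = 3000,
                       error_rate = 1e-3, n_sites = 1, seed = NULL) {
  check_scalar(true_maf, "true_maf", is_prob)
  check_scalar(depth, "depth", function(x) is.numeric(x) && x >= 1)
  check_scalar(input_copies, "input_copies",
               function(x) (is.numeric(x) && x >= 1) || is.infinite(x))
  check_scalar(error_rate, "error_rate",
               function(x) is.numeric(x) && x >= 0 && x < 0.5)
  check_scalar(n_sites, "n_sites", function(x) is_count(x) && x >= 1)
  structure(list(true_maf = true_maf, depth = depth,
                 input_copies = input_copies, error_rate = error_rate,
                 n_sites = as.integer(n_sites), seed = seed),
            class = "sim_config")
}

#' Simulate deep-sequencing pileup sites
#'
#' Two-stage read model. For each site the number of mutant template
#' molecules is drawn `m ~ Binomial(input_copies, true_maf)`; the realized
#' depth is Poisson around the configured mean; each read samples a
#' template uniformly (so pre-error mutant reads are
#' `Binomial(n, m / input_copies)`); finally each read is miscalled
#' symmetrically (ref to alt and alt to ref) with probability
#' `error_rate`. With `input_copies = Inf` the template stage is skipped
#' and reads are plain `Binomial(n, f')` with
#' `f' = f (1 - e) + (1 - f) e`.
#'
#' @param config A [sim_config()].
#' @return A data frame with one row per site: `site_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `ref_count`, `alt_count`, `error_rate`, `true_maf`.
#' @export
simulate_pileup <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    ns <- config$n_sites
    e <- config$error_rate
    N <- config$input_copies
    template_frac <- if (is.infinite(N)) {
      rep(config$true_maf, ns)
    } else {
      stats::rbinom(ns, size = N, prob = config$true_maf) / N
    }
    depth <- stats::rpois(ns, config$depth)
    depth[depth < 1L] <- 1L    # a site with zero coverage carries no pileup
    alt_true <- stats::rbinom(ns, size = depth, prob = template_frac)
    # symmetric miscalls: true-alt reads read as ref, true-ref reads as alt
    alt_kept <- stats::rbinom(ns, size = alt_true, prob = 1 - e)
    ref_flipped <- stats::rbinom(ns, size = depth - alt_true, prob = e)
    alt_count <- alt_kept + ref_flipped
    data.frame(
      site_id = sprintf("site_%04d", seq_len(ns)),
      chrom = "X",
      pos = 154000000L + seq_len(ns),
      ref = "C",
      alt = "T",
      ref_count = depth - alt_count,
      alt_count = alt_count,
      error_rate = e,
      true_maf = config$true_maf,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate ultra-deep amplicon counts (PCR-bottleneck model)
#'
#' Identical to [simulate_pileup()] but with amplicon defaults: 20 ng of
#' input DNA (about 6000 genome copies) sequenced to about 12,000x. Because
#' depth exceeds the template pool, reads resample the finite pool and the
#' replicate variance of the alt fraction exceeds the pure binomial
#' variance — the amplification-bottleneck overdispersion that limits
#' validation sensitivity.
#'
#' @param config A [sim_config()]; `sim_config(f, depth = 12000,
#'   input_copies = 6000)` matches the assay.
#' @return A pileup data frame as in [simulate_pileup()].
#' @export
simulate_amplicon <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  simulate_pileup(config)
}

#' Configuration for droplet digital PCR simulation
#'
#' @param true_maf True mutant allelic fraction of the loaded template.
#' @param total_copies Number of template molecules loaded into the
#'   emulsion.
#' @param n_droplets Number of droplets generated; mean occupancy is
#'   `total_copies / n_droplets`.
#' @param false_mu_rate Probability that a droplet without mutant template
#'   still reads as mutant-positive (assay false-positive rate). Default 0;
#'   a nonzero value stresses the detection-limit analysis.
#' @param seed Integer RNG seed or `NULL`.
#' @return A `droplet_sim_config` list.
#' @export
droplet_sim_config <- function(true_maf, total_copies = 5e4,
                               n_droplets = 5e5, false_mu_rate = 0,
                               seed = NULL) {
  check_scalar(true_maf, "true_maf", is_prob)
  check_scalar(total_copies, "total_copies", is_count)
  check_scalar(n_droplets, "n_droplets", function(x) is_count(x) && x >= 1)
  check_scalar(false_mu_rate, "false_mu_rate", is_prob)
  structure(list(true_maf = true_maf, total_copies = total_copies,
                 n_droplets = n_droplets, false_mu_rate = false_mu_rate,
                 seed = seed),
            class = "droplet_sim_config")
}

#' Simulate a droplet digital PCR run
#'
#' Mutant molecule count is `Binomial(total_copies, true_maf)`; molecules
#' land in droplets uniformly at random (the conditional-on-total form of
#' Poisson loading). A droplet containing at least one mutant molecule
#' reads MU (the mutant FAM signal dominates); one with only wild-type
#' molecules reads WT; an empty droplet reads NA. Non-MU droplets flip to
#' MU with probability `false_mu_rate`.
#'
#' @param config A [droplet_sim_config()].
#' @return A [droplet_data()] object with counts `mu`, `wt`, `na`.
#' @export
simulate_droplets <- function(config) {
  stopifnot(inherits(config, "droplet_sim_config"))
  with_seed(config$seed, {
    nd <- config$n_droplets
    total <- config$total_copies
    if (total == 0) {
      return(droplet_data(mu = 0, wt = 0, na = nd))
    }
    n_mu <- stats::rbinom(1, size = total, prob = config$true_maf)
    n_wt <- total - n_mu
    mu_droplets <- unique(sample.int(nd, n_mu, replace = TRUE))
    wt_droplets <- unique(sample.int(nd, n_wt, replace = TRUE))
    mu <- length(mu_droplets)
    wt <- length(setdiff(wt_droplets, mu_droplets))
    na <- nd - mu - wt
    r <- config$false_mu_rate
    if (r > 0) {
      flip_wt <- stats::rbinom(1, wt, r)
      flip_na <- stats::rbinom(1, na, r)
      mu <- mu + flip_wt + flip_na
      wt <- wt - flip_wt
      na <- na - flip_na
    }
    droplet_data(mu = mu, wt = wt, na = na)
  })
}

#' Simulate two-channel droplet fluorescence
#'
#' Expands classified droplet counts into per-droplet FAM/VIC intensity
#' records drawn from separated Gaussian clusters, emulating the
#' scatter-plot readout of the instrument. MU droplets are high-FAM, WT
#' droplets high-VIC, empty droplets sit at baseline in both channels.
#'
#' @param d A [droplet_data()] object.
#' @param mu_fam,wt_vic Mean positive-cluster intensities.
#' @param baseline Mean negative-channel intensity.
#' @param sd Cluster standard deviation (common to all clusters).
#' @param seed Integer RNG seed or `NULL`.
#' @return Data frame of `fam`, `vic` intensities, one row per droplet,
#'   in randomized order.
#' @export
simulate_fluorescence <- function(d, mu_fam = 8000, wt_vic = 6000,
                                  baseline = 500, sd = 300, seed = NULL) {
  stopifnot(inherits(d, "droplet_data"))
  with_seed(seed, {
    n <- d$mu + d$wt + d$na
    fam <- c(stats::rnorm(d$mu, mu_fam, sd),
             stats::rnorm(d$wt + d$na, baseline, sd))
    vic <- c(stats::rnorm(d$mu, baseline, sd),
             stats::rnorm(d$wt, wt_vic, sd),
             stats::rnorm(d$na, baseline, sd))
    idx <- sample.int(n)
    data.frame(fam = pmax(fam, 0)[idx], vic = pmax(vic, 0)[idx])
  })
}

#' Configuration for cohort simulation
#'
#' @param n_male,n_female Subject counts by sex.
#' @param rate_male,rate_female Per-subject mosaicism probabilities.
#' @param maf_distribution Distribution of true MAFs for mosaic subjects:
#'   a list with `name` in `"uniform"` (`min`, `max`), `"beta"` (`shape1`,
#'   `shape2`) or `"fixed"` (`value`). The default spans the range of
#'   proband blood MAFs the assays are built to quantify (6.5--38%).
#' @param exact_counts If `TRUE`, exactly `round(rate * n)` subjects per
#'   sex are mosaic (assigned at random) instead of Bernoulli draws;
#'   used to build cohorts whose truth table matches given counts.
#' @param seed Integer RNG seed or `NULL`.
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_male = 18, n_female = 453,
                              rate_male = 3 / 18, rate_female = 2 / 453,
                              maf_distribution = list(name = "uniform",
                                                      min = 0.065,
                                                      max = 0.38),
                              exact_counts = FALSE, seed = NULL) {
  check_scalar(n_male, "n_male", is_count)
  check_scalar(n_female, "n_female", is_count)
  check_scalar(rate_male, "rate_male", is_prob)
  check_scalar(rate_female, "rate_female", is_prob)
  stopifnot(is.list(maf_distribution),
            maf_distribution$name %in% c("uniform", "beta", "fixed"))
  structure(list(n_male = as.integer(n_male),
                 n_female = as.integer(n_female),
                 rate_male = rate_male, rate_female = rate_female,
                 maf_distribution = maf_distribution,
                 exact_counts = isTRUE(exact_counts), seed = seed),
            class = "cohort_sim_config")
}

draw_maf <- function(dist, n) {
  switch(dist$name,
    uniform = stats::runif(n, dist$min, dist$max),
    beta = stats::rbeta(n, dist$shape1, dist$shape2),
    fixed = rep(dist$value, n)
  )
}

#' Simulate a sex-stratified cohort
#'
#' Each subject is mosaic with the sex-specific probability; mosaic
#' subjects receive a true MAF drawn from the configured distribution,
#' non-mosaic subjects carry `true_maf = 0`.
#'
#' @param config A [cohort_sim_config()].
#' @return Data frame with `subject_id`, `sex` (`"male"`/`"female"`),
#'   `is_mosaic`, `true_maf` (0 for non-mosaic subjects).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  with_seed(config$seed, {
    n <- config$n_male + config$n_female
    sex <- rep(c("male", "female"), c(config$n_male, config$n_female))
    if (n == 0) {
      return(data.frame(subject_id = character(), sex = character(),
                        is_mosaic = logical(), true_maf = numeric(),
                        stringsAsFactors = FALSE))
    }
    if (config$exact_counts) {
      k_m <- round(config$rate_male * config$n_male)
      k_f <- round(config$rate_female * config$n_female)
      is_mosaic <- logical(n)
      if (config$n_male > 0) {
        is_mosaic[sample.int(config$n_male, k_m)] <- TRUE
      }
      if (config$n_female > 0) {
        is_mosaic[config$n_male + sample.int(config$n_female, k_f)] <- TRUE
      }
    } else {
      p <- ifelse(sex == "male", config$rate_male, config$rate_female)
      is_mosaic <- stats::runif(n) < p
    }
    true_maf <- numeric(n)
    if (any(is_mosaic)) {
      true_maf[is_mosaic] <- draw_maf(config$maf_distribution,
                                      sum(is_mosaic))
    }
    data.frame(subject_id = sprintf("S%04d", seq_len(n)), sex = sex,
               is_mosaic = is_mosaic, true_maf = true_maf,
               stringsAsFactors = FALSE)
  })
}

#' Tissue vocabulary of the multi-tissue panels
#' @return Character vector of tissue keys; the four `semen_*` entries are
#'   the gradient-separated semen fractions (Sperm, Layer 1, Layer 2,
#'   Others).
#' @export
tissue_vocabulary <- function() {
  c("blood", "saliva", "hair", "buccal", "urine",
    "semen_Sp", "semen_L1", "semen_L2", "semen_Ot")
}

#' Simulate a multi-tissue droplet-count panel
#'
#' Generates the ddPCR inputs for one subject across the tissue panel
#' (blood, saliva, hair, buccal, urine and four semen fractions) under a
#' named mosaicism scenario:
#' \describe{
#'   \item{`germline_only`}{mutant template only in semen fractions —
#'     either confined to Layer 2 (`pattern = "L2_only"`) or present in
#'     Sperm and Others (`pattern = "sperm_ot"`); all somatic tissues are
#'     negative. This is the transmissible-but-blood-invisible case.}
#'   \item{`early_embryonic`}{mutant template in all semen fractions plus
#'     low-level somatic mosaicism (defaults: semen 7.55%, saliva 0.43%,
#'     blood 0.28%, matching the one father whose mutation preceded
#'     soma/germline separation).}
#'   \item{`negative_control`}{all tissues mutation-free.}
#' }
#'
#' @param scenario Scenario name (see above).
#' @param seed Integer RNG seed or `NULL`.
#' @param pattern Semen-fraction pattern for `germline_only`.
#' @param germline_maf MAF of the positive semen fraction(s) in
#'   `germline_only` (default 0.67%, the Layer-2-confined case).
#' @param semen_maf,saliva_maf,blood_maf Set-points for
#'   `early_embryonic`.
#' @param total_copies,n_droplets Per-tissue ddPCR loading parameters.
#' @param sample_id Subject label attached to the output.
#' @return Data frame with `sample_id`, `tissue`, `mu`, `wt`, `na`,
#'   `true_maf`, one row per tissue.
#' @export
simulate_tissue_panel <- function(scenario = c("germline_only",
                                               "early_embryonic",
                                               "negative_control"),
                                  seed = NULL,
                                  pattern = c("L2_only", "sperm_ot"),
                                  germline_maf = 0.0067,
                                  semen_maf = 0.0755,
                                  saliva_maf = 0.0043,
                                  blood_maf = 0.0028,
                                  total_copies = 5e4, n_droplets = 5e5,
                                  sample_id = "subject") {
  scenario <- match.arg(scenario)
  pattern <- match.arg(pattern)
  tissues <- tissue_vocabulary()
  maf <- stats::setNames(numeric(length(tissues)), tissues)
  if (scenario == "germline_only") {
    if (pattern == "L2_only") {
      maf["semen_L2"] <- germline_maf
    } else {
      maf[c("semen_Sp", "semen_Ot")] <- germline_maf
    }
  } else if (scenario == "early_embryonic") {
    maf[c("semen_Sp", "semen_L1", "semen_L2", "semen_Ot")] <- semen_maf
    maf["saliva"] <- saliva_maf
    maf["blood"] <- blood_maf
  }
  with_seed(seed, {
    rows <- lapply(tissues, function(tt) {
      d <- simulate_droplets(droplet_sim_config(
        true_maf = maf[[tt]], total_copies = total_copies,
        n_droplets = n_droplets))
      data.frame(sample_id = sample_id, tissue = tt, mu = d$mu, wt = d$wt,
                 na = d$na, true_maf = maf[[tt]], stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
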