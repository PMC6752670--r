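# Generators: distributional correctness, conservation, determinism.

test_that("pileup simulation matches binomial expectations in edge regimes", {
  # error-free homozygous: every read supports the alternative allele
  hom <- simulate_pileup(sim_config(true_maf = 1, depth = 100,
                                    error_rate = 0, n_sites = 20,
                                    seed = 11))
  expect_true(all(hom$ref_count == 0))
  expect_true(all(hom$alt_count >= 1))

  # pure error: mean alt count matches Binomial(depth, e) expectation
  err <- simulate_pileup(sim_config(true_maf = 0, depth = 10000,
                                    error_rate = 1e-3, n_sites = 1000,
                                    seed = 12))
  se <- sqrt(10000 * 1e-3) / sqrt(1000)   # Poisson-ish count variance
  expect_lt(abs(mean(err$alt_count) - 10), 3 * se)

  # symmetric heterozygous: mean alt fraction near 1/2
  het <- simulate_pileup(sim_config(true_maf = 0.5, depth = 10000,
                                    error_rate = 0, n_sites = 1000,
                                    seed = 13))
  frac <- het$alt_count / (het$ref_count + het$alt_count)
  se <- sqrt(oracle_two_stage_var(0.5, 3000, 10000) / 1000)
  expect_lt(abs(mean(frac) - 0.5), 3 * se)
})

test_that("identical seed and config give byte-identical pileups", {
  cfg <- sim_config(true_maf = 0.2, depth = 500, n_sites = 25, seed = 99)
  expect_identical(simulate_pileup(cfg), simulate_pileup(cfg))
  dcfg <- droplet_sim_config(0.05, 1e4, 1e5, seed = 99)
  expect_identical(simulate_droplets(dcfg), simulate_droplets(dcfg))
})

test_that("config validation rejects the noninformative error regime", {
  expect_error(sim_config(0.1, error_rate = 0.5), "error_rate")
  expect_error(sim_config(1.2), "true_maf")
  expect_error(sim_config(0.1, depth = 0), "depth")
})

test_that("amplicon bottleneck inflates replicate variance as the two-stage formula predicts", {
  reps <- 500
  frac_of <- function(copies, seed) {
    sites <- simulate_pileup(sim_config(
      true_maf = 0.05, depth = 12000, input_copies = copies,
      error_rate = 0, n_sites = reps, seed = seed))
    sites$alt_count / (sites$ref_count + sites$alt_count)
  }
  v_bottleneck <- var(frac_of(6000, 21))
  v_free <- var(frac_of(1e9, 22))
  v_binom <- 0.05 * 0.95 / 12000

  # overdispersion when depth exceeds the template pool
  expect_gt(v_bottleneck, v_binom)
  # bottleneck-free limit collapses to binomial sampling (10% band)
  expect_lt(abs(v_free / v_binom - 1), 0.10 + 3 * sqrt(2 / (reps - 1)))
  # two-stage analytic variance, within Monte-Carlo error of a variance
  # estimate (chi-square relative SE sqrt(2/(reps-1)))
  v_theory <- oracle_two_stage_var(0.05, 6000, 12000)
  expect_lt(abs(v_bottleneck / v_theory - 1), 3 * sqrt(2 / (reps - 1)))

  # degenerate single-template pool: jackpot fractions only
  jack <- simulate_pileup(sim_config(true_maf = 0.5, depth = 100,
                                     input_copies = 1, error_rate = 0,
                                     n_sites = 50, seed = 23))
  jfrac <- jack$alt_count / (jack$ref_count + jack$alt_count)
  expect_true(all(jfrac %in% c(0, 1)))
})

test_that("droplet loading conserves droplets and matches the molecule-level law", {
  # no mutant source, no false positives: MU identically zero
  d0 <- simulate_droplets(droplet_sim_config(0, 1e4, 1e5, seed = 31))
  expect_identical(d0$mu, 0)
  expect_identical(d0$mu + d0$wt + d0$na, 1e5)

  # empty run
  de <- simulate_droplets(droplet_sim_config(0.5, 0, 1000, seed = 32))
  expect_identical(c(de$mu, de$wt, de$na), c(0, 0, 1000))

  # low-occupancy regime: MU/(MU+WT) near the loaded mutant fraction;
  # expectation from the per-channel Poisson occupancy law
  d <- simulate_droplets(droplet_sim_config(0.1, 1e5, 1e6, seed = 33))
  expect_identical(d$total, 1e6)
  lam_mu <- 0.1 * 1e5 / 1e6
  lam_wt <- 0.9 * 1e5 / 1e6
  e_mu <- 1e6 * (1 - exp(-lam_mu))
  e_wt <- 1e6 * exp(-lam_mu) * (1 - exp(-lam_wt))
  expected <- e_mu / (e_mu + e_wt)
  se <- sqrt(expected * (1 - expected) / (e_mu + e_wt))
  expect_lt(abs(d$mu / (d$mu + d$wt) - expected), 3 * se)
  expect_lt(abs(d$mu / (d$mu + d$wt) - 0.1), 0.006)  # occupancy bias is small
})

test_that("cohort generator honors rates, sizes and the MAF distribution", {
  det <- simulate_cohort(cohort_sim_config(18, 453, rate_male = 1,
                                           rate_female = 0, seed = 41))
  expect_equal(sum(det$is_mosaic), 18)
  expect_true(all(det$sex[det$is_mosaic] == "male"))
  expect_equal(nrow(det), 471)
  expect_true(all(det$true_maf[!det$is_mosaic] == 0))
  expect_true(all(det$true_maf[det$is_mosaic] >= 0.065 &
                    det$true_maf[det$is_mosaic] <= 0.38))

  empty <- simulate_cohort(cohort_sim_config(0, 0, seed = 42))
  expect_equal(nrow(empty), 0)

  # binomial expectation over replicate cohorts
  counts <- withr::with_seed(43, replicate(2000, {
    co <- simulate_cohort(cohort_sim_config(18, 0, rate_male = 3 / 18))
    sum(co$is_mosaic)
  }))
  se <- sqrt(18 * (3 / 18) * (15 / 18) / 2000)
  expect_lt(abs(mean(counts) - 3), 3 * se)

  # exact-count mode pins the truth table
  ex <- simulate_cohort(cohort_sim_config(exact_counts = TRUE, seed = 44))
  expect_equal(sum(ex$is_mosaic & ex$sex == "male"), 3)
  expect_equal(sum(ex$is_mosaic & ex$sex == "female"), 2)
})

test_that("tissue panels place mutant template only where the scenario says", {
  neg <- simulate_tissue_panel("negative_control", seed = 51)
  expect_true(all(neg$mu == 0))
  expect_setequal(neg$tissue, tissue_vocabulary())

  germ <- simulate_tissue_panel("germline_only", seed = 52,
                                pattern = "L2_only")
  expect_true(all(germ$mu[germ$tissue != "semen_L2"] == 0))
  expect_gt(germ$mu[germ$tissue == "semen_L2"], 0)

  germ2 <- simulate_tissue_panel("germline_only", seed = 53,
                                 pattern = "sperm_ot")
  pos <- germ2$tissue[germ2$mu > 0]
  expect_true(all(pos %in% c("semen_Sp", "semen_Ot")))

  expect_error(simulate_tissue_panel("unknown_scenario"))
})

test_that("early-embryonic panel MAFs are recovered by occupancy-corrected ddPCR", {
  panel <- simulate_tissue_panel("early_embryonic", seed = 54)
  # 99% intervals: four simultaneous containment checks on one run
  for (tt in c("semen_Sp", "semen_L2", "saliva", "blood")) {
    row <- panel[panel$tissue == tt, ]
    est <- poisson_corrected_maf(droplet_data(row$mu, row$wt, row$na),
                                 level = 0.99)
    expect_gte(row$true_maf, est$ci_low)
    expect_lte(row$true_maf, est$ci_high)
  }
  # the set-points themselves: semen fractions high, somatic tissues low
  expect_equal(unique(panel$true_maf[grepl("^semen", panel$tissue)]),
               0.0755)
  expect_equal(panel$true_maf[panel$tissue == "saliva"], 0.0043)
  expect_equal(panel$true_maf[panel$tissue == "blood"], 0.0028)
})
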