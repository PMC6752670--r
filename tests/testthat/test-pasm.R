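# Amplicon validation: error-model fitting, marginalized posterior,
# validation decisions.

test_that("error model moment-matches control-site fractions", {
  # constant controls: point estimate equals the common fraction
  const <- data.frame(ref_count = rep(11988, 3), alt_count = rep(12, 3))
  em <- fit_error_model(const)
  expect_lt(abs(em$point_estimate - 0.001), 1e-5)

  # all-clean controls: floored, with a warning
  zero <- data.frame(ref_count = rep(12000, 4), alt_count = rep(0, 4))
  expect_warning(em0 <- fit_error_model(zero), "floored")
  expect_equal(em0$point_estimate, 1e-6)
  expect_gt(em0$alpha, 0)
  expect_gt(em0$beta, 0)

  # moment recovery from binomial controls at e = 0.002
  k <- withr::with_seed(71, rbinom(10, 12000, 0.002))
  ctrl <- data.frame(ref_count = 12000 - k, alt_count = k)
  emb <- fit_error_model(ctrl)
  se <- sqrt(0.002 * 0.998 / 12000 / 10)
  expect_lt(abs(emb$point_estimate - 0.002), 3 * se)

  expect_error(fit_error_model(const[1:2, ]), "at least 3")
  expect_error(
    fit_error_model(data.frame(ref_count = c(1, 1, 1),
                               alt_count = c(9, 9, 9))), "0.5")
})

test_that("marginalized posterior matches the dense-grid oracle", {
  em <- point_error_model(1e-3)
  est <- pasm_maf(780, 12000, em)
  oracle <- oracle_pasm_posterior(780, 12000, em$alpha, em$beta,
                                  res = 1e-5)
  expect_lt(abs(est$map_maf - oracle$map), 1e-4 + 1e-9)
  expect_lt(abs(est$ci_low - oracle$ci_low), 2e-4)
  expect_gt(est$ci_low, 0.005)   # 6.5% mosaic at 12,000x validates

  expect_equal(pasm_maf(0, 12000, em)$map_maf, 0)
  half <- pasm_maf(6000, 12000, em)
  expect_lt(abs(half$map_maf - 0.5), 0.005)
  expect_error(pasm_maf(1, 0, em), "n")
})

test_that("point-mass error model collapses to the screening posterior", {
  k <- 97
  n <- 12000
  e <- 1.5e-3
  screen_post <- maf_posterior(k, n, error_rate = e)
  pasm_est <- pasm_maf(k, n, point_error_model(e))
  expect_lt(abs(pasm_est$map_maf - screen_post$map_maf), 1e-9)
  expect_lt(abs(pasm_est$ci_low - screen_post$ci_low), 1e-9)
  expect_lt(abs(pasm_est$ci_high - screen_post$ci_high), 1e-9)
})

test_that("validation decisions follow the 0.5% bound and 40-60% het band", {
  thr <- pasm_thresholds()
  het <- maf_estimate(0.45, 0.42, 0.48, method = "pasm")
  expect_equal(validate_candidate(het, thr), "het")
  low <- maf_estimate(0.004, 0.002, 0.007, method = "pasm")
  expect_equal(validate_candidate(low, thr), "not_confirmed")
  mos <- maf_estimate(0.065, 0.06, 0.072, method = "pasm")
  expect_equal(validate_candidate(mos, thr), "mosaic_confirmed")
  # flagged estimates never confirm
  nq <- maf_estimate(NA_real_, NA_real_, NA_real_, method = "ddpcr",
                     flag = "not_quantifiable")
  expect_equal(validate_candidate(nq, thr), "not_confirmed")
})

test_that("MAP recovers a mid-range mosaic fraction at validation depth", {
  em <- point_error_model(1e-3)
  errs <- withr::with_seed(73, replicate(50, {
    site <- simulate_pileup(sim_config(0.065, depth = 12000,
                                       input_copies = Inf,
                                       error_rate = 1e-3))
    est <- pasm_maf(site$alt_count, site$ref_count + site$alt_count, em)
    abs(est$map_maf - 0.065)
  }))
  expect_lte(median(errs), 0.1 * 0.065)
})
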