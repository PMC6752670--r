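# Screening genotyper: posterior correctness, classification bands,
# batch behavior.

test_that("MAF posterior matches the dense-grid oracle and normalizes", {
  post <- maf_posterior(65, 1000, error_rate = 1e-3)
  oracle <- oracle_grid_posterior(65, 1000, 1e-3, res = 1e-5)
  expect_lt(abs(post$map_maf - oracle$map), 1e-4 + 1e-9)
  expect_lt(abs(post$ci_low - oracle$ci_low), 2e-4)
  expect_lt(abs(post$ci_high - oracle$ci_high), 2e-4)
  expect_gt(post$ci_low, 0.005)

  for (p in list(post, maf_posterior(0, 50), maf_posterior(12, 13, 0.01))) {
    expect_lt(abs(sum(p$density) - 1), 1e-9)
    expect_lte(p$ci_low, p$map_maf)
    expect_lte(p$map_maf, p$ci_high)
  }
})

test_that("posterior edge cases behave: no evidence, symmetry, errors", {
  p0 <- maf_posterior(0, 1000, error_rate = 0)
  expect_equal(p0$map_maf, 0)
  expect_equal(p0$ci_low, 0)

  p5 <- maf_posterior(500, 1000, error_rate = 0)
  expect_equal(p5$map_maf, 0.5)
  expect_lt(abs((p5$ci_low + p5$ci_high) / 2 - 0.5), 1e-4 + 1e-9)

  expect_error(maf_posterior(1, 0), "n")
  expect_error(maf_posterior(11, 10), "k")
  expect_error(maf_posterior(1, 10, error_rate = 0.6), "error_rate")
})

test_that("MAP MAF is non-decreasing in the alt count", {
  maps <- vapply(seq(0, 1000, by = 50), function(k) {
    maf_posterior(k, 1000, error_rate = 1e-3)$map_maf
  }, numeric(1))
  expect_true(all(diff(maps) >= 0))
})

test_that("classification applies the decision bands in order", {
  thr <- screen_thresholds()
  # deep clean site: lower CI bound below 0.5% -> hom_ref
  expect_equal(classify_site(maf_posterior(0, 1000, 1e-3), thr)$label,
               "hom_ref")
  # balanced site: MAP in the 45-55% band -> het
  call_het <- classify_site(maf_posterior(500, 1000, 1e-3), thr)
  expect_equal(call_het$label, "het")
  expect_gt(call_het$ci_low, 0.45)
  # saturated site -> hom_alt
  expect_equal(classify_site(maf_posterior(1000, 1000, 1e-3), thr)$label,
               "hom_alt")
  # intermediate fraction clear of every exclusion band -> candidate
  call_mos <- classify_site(maf_posterior(260, 1000, 1e-3), thr)
  expect_equal(call_mos$label, "mosaic_candidate")
  expect_lt(abs(call_mos$map_maf - 0.26), 0.01)
})

test_that("screening a site table has the advertised power and robustness", {
  homref <- simulate_pileup(sim_config(0, depth = 1000,
                                       input_copies = Inf,
                                       error_rate = 1e-3, n_sites = 100,
                                       seed = 61))
  calls <- screen_sites(homref)
  expect_gte(sum(calls$label == "hom_ref"), 99)

  het <- simulate_pileup(sim_config(0.5, depth = 1000,
                                    input_copies = Inf,
                                    error_rate = 1e-3, n_sites = 100,
                                    seed = 62))
  calls <- screen_sites(het)
  expect_gte(sum(calls$label == "het"), 95)

  clean <- data.frame(site_id = c("s1", "s2"),
                      ref_count = c(900, 1100), alt_count = c(0, 0),
                      error_rate = 0)
  expect_true(all(screen_sites(clean)$label == "hom_ref"))

  # malformed rows are reported by id and do not abort the run
  bad <- rbind(clean,
               data.frame(site_id = "s3", ref_count = NA,
                          alt_count = 5, error_rate = 0))
  expect_warning(out <- screen_sites(bad), "s3")
  expect_equal(nrow(out), 3)
  expect_equal(out$label[3], "malformed")
  expect_equal(unname(attr(out, "summary")[["hom_ref"]]), 2)
})

test_that("mosaic subjects at study MAFs are flagged at screening depth", {
  for (f in c(0.065, 0.20, 0.38)) {
    sites <- simulate_pileup(sim_config(f, depth = 1000,
                                        error_rate = 1e-3, n_sites = 20,
                                        seed = round(1000 * f)))
    calls <- screen_sites(sites)
    expect_true(all(calls$label == "mosaic_candidate"))
  }
})
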