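# Exact 2x2 inference: point-probability Fisher test, conditional-MLE
# odds ratio, exact bounds, rate summaries. stats::fisher.test serves as
# the independent cross-check throughout, never the implementation.

study_table <- contingency_table(3, 15, 2, 451)

test_that("cohort table statistics reproduce the exact-test reference", {
  p <- fisher_two_sided(study_table)
  ref <- fisher.test(matrix(c(3, 15, 2, 451), 2, byrow = TRUE))
  expect_lt(abs(p - ref$p.value), 1e-12)
  expect_equal(signif(p, 4), 4.492e-4)

  or <- or_cmle(study_table)
  # reference software reports the same maximizer to its default root
  # tolerance; the likelihood is flat at this scale
  expect_lt(abs(or / unname(ref$estimate) - 1), 1e-3)
  # score equation: expected first cell at the CMLE equals the observed
  x <- 0:5
  lw <- dhyper(x, 18, 453, 5, log = TRUE) + x * log(or)
  w <- exp(lw - max(lw))
  expect_lt(abs(sum(x * w) / sum(w) - 3), 1e-6)

  lower <- or_exact_bound(study_table, level = 0.95, side = "lower")
  ref1 <- fisher.test(matrix(c(3, 15, 2, 451), 2, byrow = TRUE),
                      alternative = "greater")
  expect_lt(abs(lower - ref1$conf.int[1]), 1e-4)
  expect_equal(round(lower, 2), 6.33)

  res <- odds_ratio_exact(study_table, sides = 1)
  expect_identical(res$ci_high, Inf)
  expect_false(res$boundary)
})

test_that("symmetric and boundary tables give the expected degenerate answers", {
  sym <- contingency_table(1, 1, 1, 1)
  expect_equal(fisher_two_sided(sym), 1)
  expect_equal(or_cmle(sym), 1)
  expect_lt(or_exact_bound(sym, 0.95, "lower"), 1)
  expect_gt(or_exact_bound(sym, 0.95, "upper"), 1)

  perfect <- contingency_table(5, 0, 0, 5)
  expect_identical(or_cmle(perfect), Inf)
  expect_true(odds_ratio_exact(perfect)$boundary)
  expect_identical(or_cmle(contingency_table(0, 5, 5, 0)), 0)
  expect_identical(or_exact_bound(contingency_table(0, 10, 5, 5),
                                  0.95, "lower"), 0)

  expect_warning(p1 <- fisher_two_sided(contingency_table(0, 3, 0, 4)),
                 "degenerate")
  expect_equal(p1, 1)
})

test_that("p-values equal brute-force enumeration on sampled small tables", {
  expect_lt(abs(fisher_two_sided(contingency_table(2, 3, 4, 5)) -
                  oracle_fisher_enum(2, 3, 4, 5)), 1e-12)
  set.seed(7)
  for (i in 1:200) {
    cells <- as.vector(rmultinom(1, sample(4:40, 1), rep(1 / 4, 4)))
    t <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    p_enum <- oracle_fisher_enum(cells[1], cells[2], cells[3], cells[4])
    expect_lt(abs(suppressWarnings(fisher_two_sided(t)) - p_enum), 1e-10)
  }
})

test_that("table symmetries hold: transposition inverts the odds ratio", {
  set.seed(8)
  for (i in 1:25) {
    cells <- as.vector(rmultinom(1, 30, c(0.1, 0.3, 0.25, 0.35))) + 1
    t <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    swapped <- contingency_table(cells[2], cells[1], cells[4], cells[3])
    expect_lt(abs(or_cmle(t) * or_cmle(swapped) - 1),
              1e-6 * or_cmle(t))
    # p invariant under row and column exchange
    rows <- contingency_table(cells[3], cells[4], cells[1], cells[2])
    expect_lt(abs(fisher_two_sided(t) - fisher_two_sided(rows)), 1e-12)
    cols <- contingency_table(cells[2], cells[1], cells[4], cells[3])
    expect_lt(abs(fisher_two_sided(t) - fisher_two_sided(cols)), 1e-12)
  }
})

test_that("rate summaries reproduce printed cohort proportions with exact intervals", {
  expect_equal(rate_summary(5, 471)$percent, 1.1)
  expect_equal(rate_summary(3, 18)$percent, 16.7)
  expect_equal(rate_summary(5, 21)$percent, 23.8)
  expect_equal(rate_summary(0, 100)$percent, 0)

  rs <- rate_summary(5, 471)
  bt <- binom.test(5, 471)$conf.int
  expect_lt(abs(rs$ci_low - bt[1]), 1e-10)
  expect_lt(abs(rs$ci_high - bt[2]), 1e-10)
  expect_error(rate_summary(5, 0), "n")
})

test_that("cohort data frames collapse to the correct 2x2 table", {
  co <- data.frame(sex = c("male", "male", "female", "female", "female"),
                   is_mosaic = c(TRUE, FALSE, TRUE, FALSE, FALSE))
  t <- as_contingency(co)
  expect_equal(c(t$a, t$b, t$c, t$d), c(1, 1, 1, 2))
})
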