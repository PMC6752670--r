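#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study inputs.
#
# Builds plain-text fixture bundles for every downstream step: a
# sex-stratified cohort whose truth table matches the study's confirmed
# counts (3/18 males, 2/453 females), a negative cohort, and the two
# multi-tissue ddPCR scenarios (germline-confined and early-embryonic
# mosaicism in fathers).

library(mosaicfrac)

out <- "results/fixtures"
for (sc in c("study_cohort", "negative", "tissue_germline_only",
             "tissue_early_embryonic")) {
  files <- generate_fixtures(sc, seed = 20, outdir = file.path(out, sc))
  cat(sprintf("[%s] wrote %d files under %s\n", sc, length(files),
              file.path(out, sc)))
}

cohort <- read_cohort_table(file.path(out, "study_cohort", "cohort.tsv"))
t <- as_contingency(cohort)
cat(sprintf(
  "cohort truth: %d/%d mosaic males, %d/%d mosaic females; MAFs %.1f%%-%.1f%%\n",
  t$a, t$a + t$b, t$c, t$c + t$d,
  100 * min(cohort$true_maf[cohort$is_mosaic]),
  100 * max(cohort$true_maf[cohort$is_mosaic])))
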