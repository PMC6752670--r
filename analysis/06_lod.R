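#!/usr/bin/env Rscript
# Step 6 — limit-of-detection power curve for the ddPCR assay.
#
# Detection probability (>= 3 mutant droplets) as a function of the true
# mutant fraction at 1e5 loaded template copies: the curve saturates
# around the assay's quoted 1e-4 detection limit.

library(mosaicfrac)

fs <- c(1e-5, 3e-5, 1e-4, 3e-4, 1e-3, 1e-2)
power <- vapply(seq_along(fs), function(i) {
  lod_power(fs[i], total_copies = 1e5, n_droplets = 5e5, reps = 300,
            seed = 60 + i)
}, numeric(1))

res <- data.frame(true_maf = fs, expected_mutant_copies = fs * 1e5,
                  detection_power = power)
write.table(res, "results/lod_power.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(res, row.names = FALSE)
cat(sprintf("power at the quoted 1e-4 limit: %.3f\n",
            power[fs == 1e-4]))
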