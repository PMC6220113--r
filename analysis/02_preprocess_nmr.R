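#!/usr/bin/env Rscript
# Push the simulated NMR panel through spectrum space and back: render each
# sample as a frequency-domain spectrum (Lorentzian peaks + water residual +
# baseline offset + noise + a global shift), then reference to the alanine
# doublet at 1.47 ppm, zero the baseline, excise water (4.33-5.13 ppm),
# normalize total area over 0.29-8.53 ppm and integrate the 30 regions.
# The default 32768-point axis samples the 0.0015-ppm linewidths with
# ~5 points, which region integration needs.

library(longmet)

seed <- 1
outdir <- "results/nmr"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- cohort_config(seed = seed)
clinical <- generate_cohort(cfg)
mrs <- simulate_metabolite_matrix(clinical, cfg, platform = "MRS")
set <- simulate_spectra(mrs, cfg)
q <- quantify_spectra(set)

write_metabolite_csv(q$matrix, file.path(outdir, "mrs_quantified.csv"))
utils::write.csv(data.frame(sample_id = names(q$shifts),
                            applied_shift = unname(q$shifts),
                            injected_shift = unname(set$truth$shift)),
                 file.path(outdir, "referencing_shifts.csv"), row.names = FALSE)

# how faithful is region integration to the simulated areas?
truth_norm <- set$truth$areas / set$truth$total_area
r2 <- vapply(colnames(q$matrix$values), function(nm)
  cor(q$matrix$values[, nm], truth_norm[, nm])^2, numeric(1))
utils::write.csv(data.frame(metabolite = names(r2), r_squared = unname(r2)),
                 file.path(outdir, "quantification_fidelity.csv"),
                 row.names = FALSE)
cat(sprintf("quantified %d spectra; median r^2 vs truth areas: %.4f (min %.4f)\n",
            nrow(q$matrix$values), median(r2), min(r2)))
cat(sprintf("shift recovery: max |applied + injected| = %.5f ppm (axis step %.5f)\n",
            max(abs(q$shifts + set$truth$shift)), 10.5 / 32768))
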