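#!/usr/bin/env Rscript
# Stage 6: oxygen-consumption-rate inhibition.
#
# Simple piecewise OCR traces are simulated for treated and vehicle wells
# (equilibration -> compound injection -> rotenone/antimycin A), per-well
# inhibition is computed from the baseline/post/non-mitochondrial
# arithmetic, and compound means are judged against the negative-control
# noise band (mean +/- 2 SD of vehicle wells).

suppressPackageStartupMessages(library(aopke))
seed <- 2026
set.seed(seed)

simulate_trace <- function(well, true_inhibition, nm_frac = 0.2,
                           noise = 0.02) {
  # 8 measurements: 1-3 baseline, 4-5 post-treatment, 6 pre rot/AA, 7-8 after
  base <- 10
  nm <- nm_frac * base
  post <- nm + (base - nm) * (1 - true_inhibition / 100)
  ocr <- c(rep(base, 3), rep(post, 3), rep(nm, 2)) *
    (1 + rnorm(8, 0, noise))
  ocr_trace(well, ocr, list(equilibration_end = 2, treatment = 3,
                            rot_aa_injection = 6))
}

plan <- rbind(
  data.frame(compound_id = "vehicle", true = 0, wells = 12),
  data.frame(compound_id = c("rotenone_like", "strobilurin_like",
                             "carboxin_like"),
             true = c(85, 60, 10), wells = 6))
traces <- do.call(rbind, lapply(seq_len(nrow(plan)), function(i)
  do.call(rbind, lapply(seq_len(plan$wells[i]), function(w) {
    tr <- simulate_trace(sprintf("%s_w%d", plan$compound_id[i], w),
                         plan$true[i])
    data.frame(compound_id = plan$compound_id[i],
               well_id = tr$well_id,
               inhibition = mito_inhibition(normalize_trace(tr)))
  }))))
write.csv(traces, "results/ocr_inhibition.csv", row.names = FALSE)

band <- noise_band(traces$inhibition[traces$compound_id == "vehicle"])
sm <- summarize_inhibition(traces[traces$compound_id != "vehicle", ])
sm$insignificant <- in_noise_band(sm$mean_inhibition, band)
write.csv(sm, "results/ocr_summary.csv", row.names = FALSE)

cat(sprintf("Noise band from %d vehicle wells: [%.1f, %.1f]%%\n",
            band$n, band$lower, band$upper))
print(sm, row.names = FALSE)
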