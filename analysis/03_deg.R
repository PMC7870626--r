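#!/usr/bin/env Rscript
# Stage 3: differential expression per treated concentration.
#
# The simulated count matrix is prefiltered (sample total >= 0.2 million,
# gene mean >= 1.5), normalized by median-of-ratios, and each
# concentration is tested against the vehicle controls with the NB Wald
# test. DEGs are called with the > 1.5-fold (0.59 log2) + FDR < 0.05 rule.

suppressPackageStartupMessages(library(aopke))

cd <- read_counts("results/counts.tsv", "results/samples.tsv")
pf <- prefilter(cd$counts, cd$meta)
cat(sprintf("Prefilter: %d genes x %d samples retained (%d removals)\n",
            nrow(pf$counts), ncol(pf$counts), nrow(pf$report)))

compound <- unique(pf$meta$compound_id[pf$meta$concentration > 0])[1]
concs <- sort(unique(pf$meta$concentration[pf$meta$concentration > 0]))
summary <- do.call(rbind, lapply(seq_along(concs), function(i) {
  tab <- test_differential_expression(pf$counts, pf$meta, compound,
                                      concs[i])
  write.csv(tab, sprintf("results/deg_c%02d.csv", i), row.names = FALSE)
  deg <- call_degs(tab)
  data.frame(compound_id = compound, concentration_M = concs[i],
             n_up = deg$n_up, n_down = deg$n_down, n_deg = deg$n_deg)
}))
write.csv(summary, "results/deg_summary.csv", row.names = FALSE)
cat("DEG counts by concentration:\n")
print(summary, row.names = FALSE)
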