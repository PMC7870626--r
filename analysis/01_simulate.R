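#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# A 14-compound respiratory-chain inhibitor panel (6 cI, 3 cII, 5 cIII)
# is simulated across the four key-event assays (KE1 respirometry, KE2
# mitochondrial dysfunction, KE3 proteostasis, KE4 neurite outgrowth),
# plus a viability endpoint for the specificity model, and a targeted
# 3000-gene count matrix (5 concentrations x 3 replicates + vehicle
# controls) for the lead compound. Every dataset carries its generating
# truth, written alongside for the recovery analyses in later stages.

suppressPackageStartupMessages(library(aopke))
seed <- 2026
dir.create("results", showWarnings = FALSE)

panel <- default_compound_panel(seed)
ke <- generate_ke_panel(panel, default_ke_offsets(), noise_sd = 5,
                        n_replicates = 3, seed = seed)

# viability datasets: cytotoxicity set several-fold less potent than the
# neurite endpoint for cI/cIII compounds (specific neurotoxicants exist),
# close to it for the weak cII class
viab <- lapply(panel, function(sp) {
  shift <- if (sp$moa_class %in% c("cI", "cIII")) 8 else 1.5
  vs <- sp
  vs$ec50 <- sp$ec50 * shift
  generate_dose_response(vs, "V", conc_grid(sp$max_test_conc),
                         noise_sd = 5, seed = seed)
})

write_assay_table(c(ke$datasets, viab), "results/assay.csv")
write.csv(ke$truth, "results/ke_truth.csv", row.names = FALSE)

cfg <- count_sim_config(n_genes = 3000, de_fraction = 0.1, max_log2fc = 3,
                        dispersion = 0.05, de_ec50 = c(13e-6 / 64, 13e-6 / 2),
                        seed = seed)
sim <- generate_counts(cfg, compound_id = panel[[1]]$compound_id)
write_counts(sim$counts, sim$meta, "results/counts.tsv",
             "results/samples.tsv")
write.csv(sim$truth, "results/counts_truth.csv", row.names = FALSE)

cat(sprintf("Simulated %d compounds x 4 KE endpoints + viability (%d wells)\n",
            length(panel), sum(vapply(c(ke$datasets, viab),
                                      function(d) nrow(d$data), 1))))
cat(sprintf("Simulated counts: %d genes x %d samples, %d planted DE genes\n",
            nrow(sim$counts), ncol(sim$counts),
            sum(sim$truth$true_log2fc[sim$truth$concentration ==
                                        max(cfg$concentrations)] != 0)))
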