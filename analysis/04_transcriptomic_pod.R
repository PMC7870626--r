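#!/usr/bin/env Rscript
# Stage 4: transcriptomic points of departure.
#
# Per-concentration DEG counts become (i) the positive-control normalized
# DEG response, fitted for EC10(DEG), and (ii) the degree of gene
# expression homeostasis (DGH = 100 - n_deg, floor 0), run through the
# benchmark-concentration machinery for BMC10(DEG). The two-concentration
# overlap signature and its masked cross-condition regulation matrix are
# built, and a PCA overview of the samples on the 100 most variable genes
# is written.

suppressPackageStartupMessages(library(aopke))
seed <- 2026

summary <- read.csv("results/deg_summary.csv")
truth <- read.csv("results/counts_truth.csv")
concs <- summary$concentration_M
n_deg <- summary$n_deg

# positive control: the top tested concentration of the lead compound
npos <- n_deg[length(n_deg)]
pts <- deg_response_points(concs, n_deg, npos)
write.csv(pts, "results/pod_points.csv", row.names = FALSE)

est <- ec10_deg(pts)
bmc <- bmc10_dgh(pts, n_bootstrap = 500, seed = seed)
pod <- data.frame(compound_id = summary$compound_id[1], npos = npos,
                  ec10_deg_M = est$concentration,
                  ec10_deg_pEC = est$pec,
                  ec10_extrapolated = est$extrapolated,
                  bmc10_dgh_M = bmc$bmc)
write.csv(pod, "results/pod.csv", row.names = FALSE)

# truth comparison: concentration at which the planted normalized
# response crosses 10%
truth_n <- vapply(concs, function(cc)
  sum(abs(truth$true_log2fc[truth$concentration == cc]) > 0.59), 1)
truth_resp <- pmin(truth_n / truth_n[length(truth_n)], 1) * 100
cstar <- exp(approx(truth_resp, log(concs), xout = 10,
                    ties = "ordered")$y)
cat(sprintf("EC10(DEG) = %.3g M; truth 10%% crossing = %.3g M (%.2f-fold)\n",
            est$concentration, cstar,
            max(est$concentration / cstar, cstar / est$concentration)))
cat(sprintf("BMC10(DGH) = %.3g M\n", bmc$bmc))

# overlap signature: DEGs shared by the top concentration and a 4x lower
# one (here: two top concentrations of the 4-fold series)
i_anchor <- length(concs)
i_low <- i_anchor - 1          # the series is 4-fold spaced
deg_anchor <- call_degs(read.csv(sprintf("results/deg_c%02d.csv",
                                         i_anchor)))$genes
deg_low <- call_degs(read.csv(sprintf("results/deg_c%02d.csv",
                                      i_low)))$genes
sig <- build_signature(deg_anchor, deg_low, concs[i_anchor],
                       dilution = concs[i_anchor] / concs[i_low],
                       compound_id = pod$compound_id)
jsonlite::write_json(list(compound_id = sig$compound_id,
                          anchor_concentration = sig$anchor_concentration,
                          low_concentration = sig$low_concentration,
                          gene_ids = sig$gene_ids),
                     "results/signature.json", auto_unbox = TRUE,
                     digits = NA)
cat(sprintf("Overlap signature: %d genes\n", length(sig$gene_ids)))

tables <- lapply(seq_along(concs), function(i)
  read.csv(sprintf("results/deg_c%02d.csv", i)))
names(tables) <- sprintf("c%02d", seq_along(concs))
rm_ <- regulation_matrix(sig, tables, mask_alpha = 0.1)
write.csv(data.frame(gene_id = rownames(rm_$log2fc), rm_$log2fc),
          "results/regulation_log2fc.csv", row.names = FALSE)
write.csv(data.frame(gene_id = rownames(rm_$status), rm_$status),
          "results/regulation_status.csv", row.names = FALSE)
cat(sprintf("Regulation matrix: %.0f%% of cells masked at FDR > 0.1\n",
            100 * mean(rm_$status == "masked")))

cd <- read_counts("results/counts.tsv", "results/samples.tsv")
pf <- prefilter(cd$counts, cd$meta)
pc <- pca_overview(pf$counts, pf$meta, n_top = 100)
write.csv(pc, "results/pca.csv", row.names = FALSE)
ve <- attr(pc, "var_explained")
cat(sprintf("PCA on 100 most variable genes: PC1 %.0f%%, PC2 %.0f%%\n",
            100 * ve[1], 100 * ve[2]))
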