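#!/usr/bin/env Rscript
# Stage 5: classification layers over the fitted potencies.
#
# (i) Specificity of neurotoxicity: EC25(V)/EC25(NA) ratio against the
#     > 4 prediction-model cut, with censored lower bounds when viability
#     stays unaffected.
# (ii) Fixed 50 uM virtual screen: >= 25% effect hit calls per KE assay
#     and their concordance with the KE4 anchor.
# (iii) Synoptic KE4/KEx sensitivity-ratio matrix with its category
#     boundaries (> 3 / > 10 / > 100, inverse < 1/3), compared against
#     the planted truth categories.

suppressPackageStartupMessages(library(aopke))

fits <- read.csv("results/fits.csv")
truth <- read.csv("results/ke_truth.csv")
datasets <- read_assay_table("results/assay.csv")

## specificity model (KE4 neurite potency vs viability potency)
compounds <- unique(fits$compound_id)
spec <- do.call(rbind, lapply(compounds, function(cid) {
  ec25 <- function(ep) {
    r <- fits[fits$compound_id == cid & fits$endpoint == ep, ]
    if (nrow(r) == 1 && r$converged) r$ec25_M else NA_real_
  }
  max_conc <- max(vapply(datasets[grepl(paste0("^", cid, "\\."),
                                        names(datasets))],
                         function(d) max(d$data$concentration), 1))
  s <- specificity_call(cid, ec25("V"), ec25("KE4"), max_conc)
  data.frame(compound_id = cid, ec25_v = s$ec25_v, ec25_na = s$ec25_na,
             ratio = s$ratio, bound = s$bound, category = s$category)
}))
write.csv(spec, "results/specificity.csv", row.names = FALSE)
cat("Specificity calls:\n")
print(table(spec$category))

## 50 uM virtual screen
is_ke <- grepl("\\.KE[1-4]\\.", names(datasets))
hits <- do.call(rbind, c(lapply(datasets[is_ke], function(d) {
  h <- try(hit_call(d, screen_concentration = 5e-5), silent = TRUE)
  data.frame(compound_id = d$compound_id, ke = d$endpoint,
             call = if (inherits(h, "hit_call")) h$call else NA_character_)
}), make.row.names = FALSE))
write.csv(hits, "results/hit_calls.csv", row.names = FALSE)
conc_tab <- concordance_table(hits)
write.csv(conc_tab, "results/concordance.csv", row.names = FALSE)
cat(sprintf("50 uM screen: %d/%d compounds fully concordant with KE4\n",
            sum(conc_tab$concordant, na.rm = TRUE), nrow(conc_tab)))

## KE sensitivity-ratio matrix vs planted truth
ke_fits <- fits[fits$endpoint != "V", c("compound_id", "endpoint",
                                        "ec25_M")]
names(ke_fits)[2] <- "ke"
ratios <- ke_ratio_matrix(ke_fits)
write.csv(ratios, "results/ke_ratios.csv", row.names = FALSE)
tr <- truth[truth$ke != "KE4", ]
tr$true_cat <- ke_ratio_category(tr$true_ratio)
mg <- merge(ratios, tr[, c("compound_id", "ke", "true_cat")])
cat(sprintf("KE ratio categories: %d/%d cells match the planted truth\n",
            sum(mg$category == mg$true_cat), nrow(mg)))
print(table(planted = mg$true_cat, assigned = mg$category))
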