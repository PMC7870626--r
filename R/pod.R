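#' Positive-control normalized DEG response
#'
#' Expresses a condition's total DEG count relative to the positive-control
#' DEG count, capped at 100 percent: `min(n_deg / N_pos, 1) * 100`. The
#' positive control (e.g. a strong complex I inhibitor at its EC10 of
#' viability) defines the full response.
#'
#' @param n_deg number of differentially expressed genes (>= 0); vectorized.
#' @param positive_control_count DEG count of the positive control (>= 1).
#' @return Normalized response(s) in percent, within \[0, 100\].
#' @export
deg_response <- function(n_deg, positive_control_count) {
  if (length(positive_control_count) != 1 || positive_control_count < 1)
    stop("positive_control_count must be a single value >= 1")
  if (any(n_deg < 0)) stop("n_deg must be >= 0")
  pmin(n_deg / positive_control_count, 1) * 100
}

#' Degree of gene-expression homeostasis (DGH)
#'
#' `DGH = 100 - n_deg`, with a lower limit of 0. A fully homeostatic
#' condition (no deregulated genes) scores 100; 100 or more DEGs exhaust
#' the scale.
#'
#' @param n_deg number of differentially expressed genes (>= 0); vectorized.
#' @return DGH value(s) in \[0, 100\].
#' @export
dgh <- function(n_deg) {
  if (any(n_deg < 0)) stop("n_deg must be >= 0")
  pmax(0, 100 - n_deg)
}

#' Per-concentration DEG response points
#'
#' Convenience constructor pairing each concentration's DEG count with its
#' positive-control normalized response and DGH value.
#'
#' @param concentration molar concentrations (one per condition).
#' @param n_deg DEG counts, parallel to `concentration`.
#' @param positive_control_count see [deg_response()].
#' @return A data.frame with columns `concentration`, `n_deg`,
#'   `normalized_response`, `dgh`.
#' @export
deg_response_points <- function(concentration, n_deg,
                                positive_control_count) {
  stopifnot(length(concentration) == length(n_deg))
  data.frame(concentration = concentration, n_deg = n_deg,
             normalized_response = deg_response(n_deg,
                                                positive_control_count),
             dgh = dgh(n_deg))
}

#' Transcriptomic point of departure: EC10 of the DEG response
#'
#' Fits the increasing Hill form (bottom 0, top 100) to the
#' positive-control normalized DEG response versus concentration and solves
#' it for a 10 percent response. The 10 percent level refers to the
#' normalized maximum, i.e. 10 percent of the positive-control DEG count.
#'
#' @param points data.frame from [deg_response_points()] (>= 4
#'   concentrations).
#' @param x response level in percent (default 10).
#' @return An [effective_concentration()] estimate.
#' @export
ec10_deg <- function(points, x = 10) {
  ds <- dr_dataset("deg_response", "DEGresp", "LUHMES",
                   points$concentration, points$normalized_response)
  fit <- fit_hill(ds, direction = "increasing", flat_threshold = x)
  if (!fit$converged)
    stop("FlatCurve: maximum normalized DEG response below ", x, "%")
  effective_concentration(fit, x)
}

#' Transcriptomic point of departure: BMC10 of the DGH
#'
#' Treats the concentration-dependent DGH values (decreasing from 100) as a
#' concentration-response series and delegates to
#' [benchmark_concentration()] with a 10 percent benchmark response, giving
#' the benchmark concentration of gene regulation, BMC10(DEG).
#'
#' @param points data.frame from [deg_response_points()].
#' @param n_bootstrap,seed passed to [benchmark_concentration()].
#' @return A [benchmark_concentration()] result.
#' @export
bmc10_dgh <- function(points, n_bootstrap = 1000, seed = 1) {
  ds <- dr_dataset("dgh", "DGH", "LUHMES", points$concentration, points$dgh)
  benchmark_concentration(ds, benchmark_response = 10,
                          n_bootstrap = n_bootstrap, seed = seed,
                          direction = "decreasing", flat_threshold = 10)
}

#' Two-concentration overlap gene signature
#'
#' Genes differentially expressed both at an anchor concentration (the
#' highest non-cytotoxic level) and at a `dilution`-fold lower
#' concentration. Requiring regulation at the lower, definitely
#' non-cytotoxic level excludes unspecific indicators of cell death.
#'
#' @param deg_anchor character vector: DEG ids at the anchor concentration.
#' @param deg_low character vector: DEG ids at the lower concentration.
#' @param anchor_concentration molar anchor concentration.
#' @param dilution fold difference between the two levels (default 4).
#' @param compound_id source compound.
#' @return An object of class `signature_set`: `gene_ids` (intersection),
#'   `anchor_concentration`, `low_concentration`, `compound_id`, `empty`
#'   flag.
#' @export
build_signature <- function(deg_anchor, deg_low, anchor_concentration,
                            dilution = 4, compound_id = NA_character_) {
  genes <- sort(intersect(deg_anchor, deg_low))
  structure(
    list(gene_ids = genes,
         anchor_concentration = anchor_concentration,
         low_concentration = anchor_concentration / dilution,
         dilution = dilution,
         compound_id = compound_id,
         empty = length(genes) == 0),
    class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf(
    "<signature_set> %d genes (%s, anchor %.3g M / low %.3g M)%s\n",
    length(x$gene_ids), x$compound_id, x$anchor_concentration,
    x$low_concentration, if (x$empty) " [EMPTY]" else ""))
  invisible(x)
}

#' Cross-condition regulation matrix of a gene signature
#'
#' Log2 fold changes of the signature genes across a set of conditions,
#' with cells masked where the FDR-adjusted p value exceeds `mask_alpha`
#' (shown white in a heatmap) and an explicit `absent` state for genes
#' missing from a condition's table.
#'
#' @param signature a [build_signature()] result.
#' @param tables named list of `deg_table`s, one per condition.
#' @param mask_alpha FDR threshold above which a regulation is masked
#'   (default 0.1).
#' @return An object of class `regulation_matrix`: `log2fc` (genes x
#'   conditions, NA where absent), `status` (character matrix: `"ok"`,
#'   `"masked"`, `"absent"`), `mask_alpha`.
#' @export
regulation_matrix <- function(signature, tables, mask_alpha = 0.1) {
  stopifnot(inherits(signature, "signature_set"))
  genes <- signature$gene_ids
  conds <- names(tables)
  lfc <- matrix(NA_real_, length(genes), length(conds),
                dimnames = list(genes, conds))
  status <- matrix("absent", length(genes), length(conds),
                   dimnames = list(genes, conds))
  for (j in seq_along(conds)) {
    tab <- tables[[j]]
    hit <- match(genes, tab$gene_id)
    found <- !is.na(hit)
    lfc[found, j] <- tab$log2fc[hit[found]]
    status[found, j] <- ifelse(tab$padj[hit[found]] > mask_alpha,
                               "masked", "ok")
  }
  structure(list(log2fc = lfc, status = status, mask_alpha = mask_alpha),
            class = "regulation_matrix")
}

#' PCA overview of a count matrix
#'
#' Principal components of the samples on the most variable genes: counts
#' are normalized (median of ratios), transformed to `log2(x + 1)`, genes
#' ranked by variance across samples, and the top `n_top` genes centred
#' per gene before the decomposition. Coordinates on the first two
#' components and their explained-variance fractions are returned.
#'
#' @param counts count matrix (genes x samples), typically prefiltered.
#' @param meta sample metadata merged onto the coordinates.
#' @param n_top number of most variable genes to use (default 100).
#' @return A data.frame with `sample_id`, `PC1`, `PC2` and the metadata
#'   columns; attribute `var_explained` holds the two fractions.
#' @export
pca_overview <- function(counts, meta, n_top = 100) {
  check_count_matrix(counts)
  if (nrow(counts) < n_top)
    stop("need at least n_top = ", n_top, " genes after prefiltering")
  sf <- size_factors(counts)
  lx <- log2(sweep(counts, 2, sf, "/") + 1)
  vars <- apply(lx, 1, stats::var)
  top <- order(vars, decreasing = TRUE)[seq_len(n_top)]
  xc <- lx[top, , drop = FALSE] - rowMeans(lx[top, , drop = FALSE])
  pc <- stats::prcomp(t(xc), center = FALSE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  out <- data.frame(sample_id = colnames(counts),
                    PC1 = pc$x[, 1], PC2 = pc$x[, 2], row.names = NULL)
  out <- merge(out, meta, by = "sample_id", sort = FALSE)
  attr(out, "var_explained") <- ve[1:2]
  out
}
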