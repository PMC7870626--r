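#' Prefilter a count matrix
#'
#' Quality filter applied before normalization and testing: samples with a
#' total (column) count below 0.2 million are removed first, then genes
#' whose mean count over the surviving samples is below 1.5.
#'
#' @param counts integer matrix, genes x samples, with dimnames.
#' @param meta data.frame with one row per sample (column `sample_id`
#'   matching `colnames(counts)`).
#' @param min_sample_total minimum column sum (default 2e5).
#' @param min_gene_mean minimum mean count per gene (default 1.5).
#' @return A list with the filtered `counts`, matching `meta`, and a
#'   `report` data.frame listing each removal with its reason.
#' @export
prefilter <- function(counts, meta, min_sample_total = 2e5,
                      min_gene_mean = 1.5) {
  check_count_matrix(counts)
  if (!all(colnames(counts) %in% meta$sample_id))
    stop("every sample in the count matrix needs a metadata row")
  totals <- colSums(counts)
  bad_samples <- colnames(counts)[totals < min_sample_total]
  counts <- counts[, totals >= min_sample_total, drop = FALSE]
  if (ncol(counts) == 0)
    stop("AllSamplesRemoved: no sample reaches a total count of ",
         min_sample_total)
  gene_means <- rowMeans(counts)
  bad_genes <- rownames(counts)[gene_means < min_gene_mean]
  counts <- counts[gene_means >= min_gene_mean, , drop = FALSE]
  if (nrow(counts) == 0)
    stop("AllSamplesRemoved: no gene reaches a mean count of ",
         min_gene_mean)
  report <- rbind(
    if (length(bad_samples))
      data.frame(id = bad_samples, kind = "sample",
                 reason = sprintf("total count < %g", min_sample_total)),
    if (length(bad_genes))
      data.frame(id = bad_genes, kind = "gene",
                 reason = sprintf("mean count < %g", min_gene_mean)))
  if (is.null(report))
    report <- data.frame(id = character(), kind = character(),
                         reason = character())
  list(counts = counts,
       meta = meta[meta$sample_id %in% colnames(counts), , drop = FALSE],
       report = report)
}

check_count_matrix <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("duplicate gene or sample ids")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  invisible(TRUE)
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors by the median-of-ratios method:
#' reference genes are those with strictly positive counts in every sample;
#' each sample's factor is the median over reference genes of the ratio of
#' its count to the gene's geometric mean across samples. Factors are not
#' rescaled further.
#'
#' @param counts integer matrix, genes x samples.
#' @return Named numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  check_count_matrix(counts)
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref))
    stop("NoReferenceGenes: every gene has a zero count in some sample")
  logc <- log(counts[ref, , drop = FALSE])
  loggeo <- rowMeans(logc)
  apply(logc, 2, function(x) exp(stats::median(x - loggeo)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjusted p values (step-up, capped at 1, monotone
#' in rank), delegating to [stats::p.adjust()].
#'
#' @param p numeric vector of p values in \[0, 1\].
#' @return Adjusted p values in the input order.
#' @export
benjamini_hochberg <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Negative-binomial Wald test for one condition vs control
#'
#' Simplified per-gene NB Wald test of a treated condition against its
#' vehicle control group. Counts are normalized by median-of-ratios size
#' factors (computed over all samples in `counts`); group means carry a
#' pseudocount of 0.5 so log fold changes stay finite. The per-gene NB
#' dispersion is estimated by method of moments on the normalized counts
#' pooled across the two groups, floored at 1e-8 and shrunk 50/50 toward a
#' log-linear mean-dispersion trend fitted across genes. The Wald statistic
#' is `z = (ln mu_t - ln mu_c) / sqrt(v_t + v_c)` with
#' `v = (1/n)(1/mu + alpha)` (delta-method variance of a log NB mean);
#' p values are two-sided normal and adjusted by Benjamini-Hochberg over
#' all genes of the contrast.
#'
#' Unlike a full DE framework there is no fold-change shrinkage, outlier
#' filtering or independent filtering; the downstream statistic only needs
#' calibrated per-condition DEG counts.
#'
#' @param counts prefiltered count matrix (genes x samples).
#' @param meta sample metadata (`sample_id`, `compound_id`,
#'   `concentration`, `replicate`); vehicle controls have concentration 0.
#' @param compound_id,concentration the treated condition to test.
#' @return A `deg_table` data.frame: `gene_id`, `mean_control`,
#'   `mean_treated`, `log2fc`, `p`, `padj`.
#' @export
test_differential_expression <- function(counts, meta, compound_id,
                                         concentration) {
  check_count_matrix(counts)
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  treated <- meta$compound_id == compound_id &
    abs(meta$concentration - concentration) <=
      1e-9 * max(concentration, 1e-300)
  control <- meta$concentration == 0
  if (sum(treated) < 2 || sum(control) < 2)
    stop("InsufficientReplicates: need >= 2 treated and >= 2 control ",
         "samples (", sum(treated), " treated, ", sum(control), " control)")

  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  xt <- norm[, treated, drop = FALSE]
  xc <- norm[, control, drop = FALSE]
  nt <- ncol(xt)
  nc <- ncol(xc)

  mu_t <- rowMeans(xt) + 0.5
  mu_c <- rowMeans(xc) + 0.5

  # method-of-moments dispersion pooled across the two groups: per-group
  # estimates combined with their degrees of freedom, so a true expression
  # difference does not masquerade as overdispersion
  mt0 <- rowMeans(xt)
  mc0 <- rowMeans(xc)
  vt0 <- apply(xt, 1, stats::var)
  vc0 <- apply(xc, 1, stats::var)
  a_t <- (vt0 - mt0) / pmax(mt0, 1e-8)^2
  a_c <- (vc0 - mc0) / pmax(mc0, 1e-8)^2
  alpha_mom <- pmax(((nt - 1) * a_t + (nc - 1) * a_c) / (nt + nc - 2), 1e-8)
  m <- rowMeans(cbind(xt, xc))

  # log-linear mean-dispersion trend across genes, fitted to binned
  # arithmetic means of the moment estimates (bin averaging keeps the
  # floored and the heavy-tailed estimates from biasing the trend)
  alpha_trend <- tryCatch({
    bins <- cut(log(pmax(m, 1e-8)), 20)
    bm <- tapply(m, bins, mean)
    ba <- tapply(alpha_mom, bins, mean)
    ok <- !is.na(bm) & bm > 0 & ba > 0
    if (sum(ok) < 3) stop("too few bins")
    co <- stats::coef(stats::lm(log(ba[ok]) ~ log(bm[ok])))
    pmax(exp(co[[1]] + co[[2]] * log(pmax(m, 1e-8))), 1e-8)
  }, error = function(e) rep(stats::median(alpha_mom), length(alpha_mom)))
  # 50/50 moderation toward the trend on the arithmetic scale: keeps genes
  # whose few-replicate moment estimate collapses to the floor from getting
  # a near-zero dispersion and an overshooting Wald statistic
  alpha <- 0.5 * alpha_mom + 0.5 * alpha_trend

  v_t <- (1 / nt) * (1 / mu_t + alpha)
  v_c <- (1 / nc) * (1 / mu_c + alpha)
  z <- (log(mu_t) - log(mu_c)) / sqrt(v_t + v_c)
  p <- 2 * stats::pnorm(-abs(z))

  out <- data.frame(gene_id = rownames(counts),
                    mean_control = unname(mu_c),
                    mean_treated = unname(mu_t),
                    log2fc = unname(log2(mu_t / mu_c)),
                    p = unname(p),
                    padj = benjamini_hochberg(unname(p)))
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Call differentially expressed genes
#'
#' Applies the DEG definition to a test table. Under the default
#' `fdr_and_fc` rule a gene is a DEG iff its regulation exceeds 1.5-fold
#' (|log2FC| > 0.59) and its FDR-adjusted p value is below 0.05; the
#' `fdr_only` variant uses `padj <= alpha` alone.
#'
#' @param table a `deg_table` from [test_differential_expression()].
#' @param lfc_cut absolute log2 fold-change cut (default 0.59, i.e.
#'   1.5-fold).
#' @param alpha FDR level (default 0.05).
#' @param rule `"fdr_and_fc"` (default) or `"fdr_only"`.
#' @return A list with `genes` (character vector of DEG ids), `n_up`,
#'   `n_down` and `n_deg = n_up + n_down`.
#' @export
call_degs <- function(table, lfc_cut = 0.59, alpha = 0.05,
                      rule = c("fdr_and_fc", "fdr_only")) {
  rule <- match.arg(rule)
  if (nrow(table) == 0)
    return(list(genes = character(), n_up = 0L, n_down = 0L, n_deg = 0L))
  sel <- if (rule == "fdr_and_fc")
    abs(table$log2fc) > lfc_cut & table$padj < alpha
  else
    table$padj <= alpha
  sel[is.na(sel)] <- FALSE
  up <- sel & table$log2fc > 0
  list(genes = table$gene_id[sel],
       n_up = sum(up), n_down = sum(sel & !up), n_deg = sum(sel))
}
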