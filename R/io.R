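assay_columns <- c("compound_id", "endpoint", "cell_model",
                   "concentration_M", "replicate", "response_pct")

#' Write concentration-response datasets to a CSV assay table
#'
#' Long-format interchange table with one row per well; concentrations are
#' serialized in molar (scientific notation), never as pEC.
#'
#' @param datasets a list of [dr_dataset()] objects (or a single one).
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_assay_table <- function(datasets, path) {
  if (inherits(datasets, "dr_dataset")) datasets <- list(datasets)
  rows <- lapply(datasets, function(d) {
    reps <- stats::ave(d$data$concentration, d$data$concentration,
                       FUN = seq_along)
    data.frame(compound_id = d$compound_id, endpoint = d$endpoint,
               cell_model = d$cell_model,
               concentration_M = format(d$data$concentration,
                                        scientific = TRUE, digits = 10),
               replicate = as.integer(reps),
               response_pct = d$data$response)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a CSV assay table into concentration-response datasets
#'
#' Validates the schema, parses molar concentrations, reports malformed
#' rows with their line numbers, and groups rows by compound x endpoint x
#' cell model.
#'
#' @param path CSV path with columns `compound_id`, `endpoint`,
#'   `cell_model`, `concentration_M`, `replicate`, `response_pct`.
#' @return Named list of [dr_dataset()] objects
#'   (`compound.endpoint.cell_model`).
#' @export
read_assay_table <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE)
  missing <- setdiff(assay_columns, names(raw))
  if (length(missing))
    stop("SchemaError: missing column(s): ", paste(missing,
                                                   collapse = ", "))
  conc <- suppressWarnings(as.numeric(raw$concentration_M))
  resp <- suppressWarnings(as.numeric(raw$response_pct))
  bad <- which(is.na(conc) | is.na(resp) | conc <= 0)
  if (length(bad))
    stop("SchemaError: unparseable or non-positive values at data line(s) ",
         paste(utils::head(bad + 1L, 10), collapse = ", "),
         " (1 = header)")
  key <- paste(raw$compound_id, raw$endpoint, raw$cell_model, sep = ".")
  out <- lapply(split(seq_len(nrow(raw)), key), function(i)
    dr_dataset(raw$compound_id[i[1]], raw$endpoint[i[1]],
               raw$cell_model[i[1]], conc[i], resp[i]))
  out[unique(key)]
}

#' Write a count matrix and sample metadata
#'
#' Genes x samples TSV with a leading `gene_id` column, plus a samples TSV
#' sidecar.
#'
#' @param counts integer matrix with dimnames.
#' @param meta sample metadata data.frame.
#' @param counts_path,meta_path output paths.
#' @return `counts_path`, invisibly.
#' @export
write_counts <- function(counts, meta, counts_path, meta_path) {
  check_count_matrix(counts)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(meta, meta_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(counts_path)
}

#' Read a count matrix and sample metadata
#'
#' @param counts_path genes x samples TSV with a `gene_id` column.
#' @param meta_path samples TSV with a `sample_id` column.
#' @return A list with `counts` (integer matrix) and `meta`.
#' @export
read_counts <- function(counts_path, meta_path) {
  df <- utils::read.delim(counts_path, check.names = FALSE)
  if (!"gene_id" %in% names(df))
    stop("SchemaError: counts file needs a gene_id column")
  counts <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$gene_id
  meta <- utils::read.delim(meta_path, check.names = FALSE)
  if (!"sample_id" %in% names(meta))
    stop("SchemaError: samples file needs a sample_id column")
  check_count_matrix(counts)
  list(counts = counts, meta = meta)
}

#' Run the full synthetic analysis pipeline
#'
#' Chains the stages end to end on simulated inputs: key-event assay panel
#' -> Hill fits and EC25s -> specificity and concordance classification;
#' count simulation -> DEG testing per concentration -> transcriptomic
#' points of departure. All thresholds and seeds are recorded in a
#' manifest with per-file checksums so a rerun with the same config is
#' byte-identical.
#'
#' @param config list; recognised elements (all optional): `seed` (default
#'   1), `out_dir` (default `tempfile()`), `n_compounds` (subset of the
#'   default panel), `n_genes`, `de_fraction`, `dispersion`, `npos`
#'   (positive-control DEG count; default the simulated top-concentration
#'   DEG count), `lfc_cut` (0.59), `alpha` (0.05), `mask_alpha` (0.1),
#'   `deg_rule` (`"fdr_and_fc"`), `dilution` (4), `specificity_cut` (4),
#'   `hit_cut` (25), `screen_conc` (5e-5), `noise_sd` (5),
#'   `n_bootstrap` (200).
#' @return A list with `manifest` (also written as JSON), and the main
#'   stage outputs (`fits`, `specificity`, `hits`, `concordance`,
#'   `ke_ratios`, `pod`).
#' @export
run_report <- function(config = list()) {
  cfg <- utils::modifyList(list(
    seed = 1L, out_dir = tempfile("aopke_report_"), n_compounds = 6,
    n_genes = 1000, de_fraction = 0.1, dispersion = 0.05, npos = NULL,
    lfc_cut = 0.59, alpha = 0.05, mask_alpha = 0.1,
    deg_rule = "fdr_and_fc", dilution = 4, specificity_cut = 4,
    hit_cut = 25, screen_conc = 5e-5, noise_sd = 5, n_bootstrap = 200),
    config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  ## stage 1: simulate KE panel + fit + classify
  panel <- default_compound_panel(cfg$seed)[seq_len(cfg$n_compounds)]
  ke <- generate_ke_panel(panel, default_ke_offsets(),
                          noise_sd = cfg$noise_sd, seed = cfg$seed)
  write_assay_table(ke$datasets, file.path(cfg$out_dir, "assay.csv"))

  fits <- lapply(ke$datasets, fit_hill)
  fit_rows <- lapply(fits, function(f) {
    ec25 <- if (f$converged) effective_concentration(f, 25)$concentration
            else NA_real_
    data.frame(compound_id = f$compound_id, ke = f$endpoint,
               ec50_M = if (f$converged) f$ec50 else NA_real_,
               hill = if (f$converged) f$hill_coef else NA_real_,
               ec25_M = ec25, converged = f$converged, flat = f$flat)
  })
  fits_df <- do.call(rbind, c(fit_rows, make.row.names = FALSE))
  utils::write.csv(fits_df, file.path(cfg$out_dir, "fits.csv"),
                   row.names = FALSE)

  ke_ratios <- ke_ratio_matrix(fits_df[, c("compound_id", "ke", "ec25_M")])
  utils::write.csv(ke_ratios, file.path(cfg$out_dir, "ke_ratios.csv"),
                   row.names = FALSE)

  hits <- do.call(rbind, c(lapply(ke$datasets, function(d) {
    h <- try(hit_call(d, cfg$screen_conc, cfg$hit_cut), silent = TRUE)
    if (inherits(h, "try-error"))
      return(data.frame(compound_id = d$compound_id, ke = d$endpoint,
                        call = NA_character_))
    data.frame(compound_id = h$compound_id, ke = h$assay, call = h$call)
  }), make.row.names = FALSE))
  concord <- concordance_table(hits)
  utils::write.csv(hits, file.path(cfg$out_dir, "hit_calls.csv"),
                   row.names = FALSE)
  utils::write.csv(concord, file.path(cfg$out_dir, "concordance.csv"),
                   row.names = FALSE)

  spec_calls <- do.call(rbind, c(lapply(panel, function(sp) {
    f_na <- fits[[paste(sp$compound_id, "KE4", sep = ".")]]
    ec25_na <- if (f_na$converged)
      effective_concentration(f_na, 25)$concentration else NA_real_
    # viability simulated as 3x less sensitive than neurites for cI/cIII
    shift <- if (sp$moa_class %in% c("cI", "cIII")) 8 else 1.5
    v_spec <- sp
    v_spec$ec50 <- spec_param(sp$ec50, "KE4") * shift
    v_spec$max_test_conc <- sp$max_test_conc
    ds_v <- generate_dose_response(v_spec, "V",
                                   conc_grid(sp$max_test_conc),
                                   noise_sd = cfg$noise_sd,
                                   seed = cfg$seed)
    f_v <- fit_hill(ds_v)
    ec25_v <- if (f_v$converged)
      effective_concentration(f_v, 25)$concentration else NA_real_
    s <- specificity_call(sp$compound_id, ec25_v, ec25_na,
                          sp$max_test_conc, cfg$specificity_cut)
    data.frame(compound_id = s$compound_id, ec25_v = s$ec25_v,
               ec25_na = s$ec25_na, ratio = s$ratio, bound = s$bound,
               category = s$category)
  }), make.row.names = FALSE))
  utils::write.csv(spec_calls, file.path(cfg$out_dir, "specificity.csv"),
                   row.names = FALSE)

  ## stage 2: counts -> DEG -> transcriptomic PoD
  cs <- count_sim_config(n_genes = cfg$n_genes,
                         de_fraction = cfg$de_fraction,
                         dispersion = cfg$dispersion, seed = cfg$seed)
  sim <- generate_counts(cs, compound_id = panel[[1]]$compound_id)
  write_counts(sim$counts, sim$meta,
               file.path(cfg$out_dir, "counts.tsv"),
               file.path(cfg$out_dir, "samples.tsv"))
  pf <- prefilter(sim$counts, sim$meta, min_sample_total = 0)
  n_deg <- vapply(cs$concentrations, function(cc) {
    tab <- test_differential_expression(pf$counts, pf$meta,
                                        panel[[1]]$compound_id, cc)
    call_degs(tab, cfg$lfc_cut, cfg$alpha, cfg$deg_rule)$n_deg
  }, numeric(1))
  npos <- if (is.null(cfg$npos)) max(n_deg, 1) else cfg$npos
  pts <- deg_response_points(cs$concentrations, n_deg, npos)
  pod <- list(ec10_deg = try(ec10_deg(pts), silent = TRUE),
              bmc10 = try(bmc10_dgh(pts, n_bootstrap = cfg$n_bootstrap,
                                    seed = cfg$seed), silent = TRUE))
  pod_df <- data.frame(
    compound_id = panel[[1]]$compound_id, npos = npos,
    ec10_deg_M = if (inherits(pod$ec10_deg, "ec_estimate"))
      pod$ec10_deg$concentration else NA_real_,
    bmc10_dgh_M = if (inherits(pod$bmc10, "bmc_result"))
      pod$bmc10$bmc else NA_real_,
    flat = !inherits(pod$ec10_deg, "ec_estimate"))
  utils::write.csv(cbind(pod_df,
                         t(stats::setNames(n_deg,
                                           paste0("n_deg_c",
                                                  seq_along(n_deg))))),
                   file.path(cfg$out_dir, "pod.csv"), row.names = FALSE)

  files <- list.files(cfg$out_dir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("aopke")),
    seed = cfg$seed,
    thresholds = cfg[c("lfc_cut", "alpha", "mask_alpha", "deg_rule",
                       "dilution", "specificity_cut", "hit_cut",
                       "screen_conc", "n_bootstrap")],
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, fits = fits_df,
                 specificity = spec_calls, hits = hits,
                 concordance = concord, ke_ratios = ke_ratios,
                 pod = pod_df, out_dir = cfg$out_dir))
}
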