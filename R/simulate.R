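# Named sub-stream seeds: one global seed expands deterministically into
# per-stream seeds so adding a stream never perturbs existing fixtures.
stream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 10007) %% 2147483587L)
}

#' Compound specification for the synthetic panel
#'
#' Ground-truth description of one test compound: its nominal
#' respiratory-chain target class and the true Hill parameters per endpoint
#' that the generators sample from.
#'
#' @param compound_id compound identifier.
#' @param moa_class one of `"cI"`, `"cII"`, `"cIII"`, `"other"` (nominal
#'   respiratory-chain complex targeted).
#' @param ec50 named numeric vector of true EC50s (molar) per endpoint, or a
#'   single unnamed value used for every endpoint.
#' @param hill named numeric vector of true Hill coefficients per endpoint,
#'   or a single value; each must lie in (0.1, 10].
#' @param max_test_conc highest concentration (molar) tested for this
#'   compound.
#' @return An object of class `compound_spec`.
#' @export
compound_spec <- function(compound_id, moa_class = c("cI", "cII", "cIII",
                                                     "other"),
                          ec50, hill = 1.5, max_test_conc = 1e-4) {
  moa_class <- match.arg(moa_class)
  if (any(ec50 <= 0)) stop("true EC50 must be positive")
  if (any(hill <= 0.1 | hill > 10))
    stop("true Hill coefficient must lie in (0.1, 10]")
  if (max_test_conc <= 0) stop("max_test_conc must be positive")
  structure(list(compound_id = as.character(compound_id),
                 moa_class = moa_class, ec50 = ec50, hill = hill,
                 max_test_conc = max_test_conc),
            class = "compound_spec")
}

spec_param <- function(x, endpoint) {
  if (is.null(names(x))) return(unname(x[1]))
  if (endpoint %in% names(x)) return(unname(x[[endpoint]]))
  unname(x[[1]])
}

#' Log-spaced concentration grid
#'
#' Serial-dilution grid as used in screening practice: `n` points ending at
#' `top`, each a constant `dilution` factor apart, returned in increasing
#' order.
#'
#' @param top highest concentration (molar).
#' @param dilution dilution factor between adjacent concentrations
#'   (default `sqrt(10)`, a half-log series).
#' @param n number of concentrations.
#' @return Increasing numeric vector of length `n`.
#' @export
conc_grid <- function(top, dilution = sqrt(10), n = 8) {
  stopifnot(top > 0, dilution > 1, n >= 1)
  top / dilution^((n - 1):0)
}

#' Simulate a concentration-response dataset
#'
#' Draws replicate percent-of-control responses from the compound's true
#' Hill curve (asymptotes 100/0) plus Gaussian noise on the percent scale,
#' truncated to \[-10, 110\] to admit the slight overshoot seen with
#' metabolic-reduction readouts. The generating truth is stored on the
#' returned dataset.
#'
#' @param spec a [compound_spec()].
#' @param endpoint endpoint identifier.
#' @param concentrations molar concentration grid (defaults to an 8-point
#'   half-log series ending at `spec$max_test_conc`).
#' @param noise_sd replicate noise SD in percent points (>= 0).
#' @param n_replicates replicates per concentration.
#' @param seed integer seed (expanded into a named sub-stream).
#' @param cell_model cell model label.
#' @return A [dr_dataset()] whose `truth` records `ec50`, `hill`,
#'   `noise_sd`.
#' @export
generate_dose_response <- function(spec, endpoint = "NA",
                                   concentrations = NULL,
                                   noise_sd = 5, n_replicates = 3,
                                   seed = 1, cell_model = "LUHMES") {
  stopifnot(inherits(spec, "compound_spec"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(concentrations))
    concentrations <- conc_grid(spec$max_test_conc)
  if (any(concentrations <= 0))
    stop("concentrations must be strictly positive")
  if (any(concentrations > spec$max_test_conc * (1 + 1e-12)))
    stop("concentrations must not exceed max_test_conc")
  ec50 <- spec_param(spec$ec50, endpoint)
  hill <- spec_param(spec$hill, endpoint)
  conc <- rep(sort(concentrations), each = n_replicates)
  mu <- hill_predict(conc, ec50, hill, direction = "decreasing")
  set.seed(stream_seed(seed, paste("responses", spec$compound_id, endpoint)))
  resp <- mu + stats::rnorm(length(mu), 0, noise_sd)
  resp <- pmin(pmax(resp, -10), 110)
  dr_dataset(spec$compound_id, endpoint, cell_model, conc, resp,
             truth = list(ec50 = ec50, hill = hill, noise_sd = noise_sd,
                          seed = seed))
}

#' Configuration for count-matrix simulation
#'
#' Parameters of the negative-binomial count generator emulating a targeted
#' sequencing panel: gene number, replication, the concentration series, the
#' planted differentially expressed fraction and its dose dependence, the NB
#' dispersion and the baseline-mean distribution.
#'
#' @param n_genes number of genes (default 3000, the size of a targeted
#'   neurotoxicity panel).
#' @param n_replicates replicates per condition, including the vehicle
#'   control group (default 3 independent differentiations).
#' @param concentrations strictly increasing molar series (default a 5-point
#'   4-fold dilution ending at 13 uM).
#' @param de_fraction fraction of genes planted as differentially expressed.
#' @param max_log2fc saturating absolute log2 fold change of DE genes.
#' @param dispersion NB dispersion alpha (> 0), `Var = mu + alpha mu^2`.
#' @param de_ec50 concentration (molar) at which a DE gene reaches half its
#'   saturating log2 fold change (default: geometric mean of the series). A
#'   length-2 vector gives a range from which per-gene midpoints are drawn
#'   log-uniformly, yielding a smooth planted DEG-count dose curve.
#' @param de_hill Hill coefficient of the log2FC dose curve.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   per-gene baseline mean counts.
#' @param sf_sdlog log-normal sdlog of per-sample size factors (meanlog 0).
#' @param seed integer seed (required; expanded into named sub-streams).
#' @return An object of class `count_sim_config`.
#' @export
count_sim_config <- function(n_genes = 3000, n_replicates = 3,
                             concentrations = 13e-6 / 4^(4:0),
                             de_fraction = 0.1, max_log2fc = 2,
                             dispersion = 0.05, de_ec50 = NULL,
                             de_hill = 1, baseline_meanlog = 4,
                             baseline_sdlog = 1.5, sf_sdlog = 0.1,
                             seed = 1) {
  if (is.unsorted(concentrations, strictly = TRUE))
    stop("concentrations must be strictly increasing")
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (de_fraction < 0 || de_fraction > 1)
    stop("de_fraction must lie in [0, 1]")
  if (de_fraction > 0 && de_fraction * n_genes < 1)
    stop("de_fraction * n_genes must be >= 1 when DE is requested")
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (is.null(de_ec50)) de_ec50 <- exp(mean(log(concentrations)))
  if (is.null(seed)) stop("seed is required")
  structure(list(n_genes = n_genes, n_replicates = n_replicates,
                 concentrations = concentrations,
                 de_fraction = de_fraction, max_log2fc = max_log2fc,
                 dispersion = dispersion, de_ec50 = de_ec50,
                 de_hill = de_hill, baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog, sf_sdlog = sf_sdlog,
                 seed = as.integer(seed)),
            class = "count_sim_config")
}

#' Simulate a gene x sample count matrix with planted DE genes
#'
#' Counts are drawn `NB(mean = sf_j * baseline_g * 2^lfc_g(c), dispersion
#' alpha)`. For planted DE genes the log2 fold change follows a Hill curve
#' in concentration saturating at `max_log2fc` (sign drawn at random per
#' gene); all other genes have log2FC identically zero. Per-sample size
#' factors are log-normal (meanlog 0, sdlog `sf_sdlog`). Vehicle controls
#' (concentration 0) are included.
#'
#' @param config a [count_sim_config()].
#' @param compound_id label used in the sample metadata.
#' @return A list with `counts` (integer matrix, genes x samples), `meta`
#'   (data.frame: sample_id, compound_id, concentration, replicate),
#'   `truth` (data.frame: gene_id, concentration, true_log2fc for every
#'   gene x treated concentration), `baseline` (true per-gene baseline
#'   means) and `size_factors_true`.
#' @export
generate_counts <- function(config, compound_id = "compound") {
  stopifnot(inherits(config, "count_sim_config"))
  ng <- config$n_genes
  nr <- config$n_replicates
  concs <- config$concentrations
  genes <- sprintf("g%04d", seq_len(ng))

  set.seed(stream_seed(config$seed, "baseline"))
  baseline <- stats::rlnorm(ng, config$baseline_meanlog, config$baseline_sdlog)

  n_de <- round(config$de_fraction * ng)
  de_idx <- if (n_de > 0) seq_len(n_de) else integer(0)
  set.seed(stream_seed(config$seed, "lfc_signs"))
  signs <- numeric(ng)
  if (n_de > 0) signs[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE)

  # per-gene midpoint of the log2FC dose curve (scalar or log-uniform range)
  set.seed(stream_seed(config$seed, "de_ec50"))
  gene_ec50 <- rep(config$de_ec50[1], ng)
  if (length(config$de_ec50) == 2 && n_de > 0)
    gene_ec50[de_idx] <- exp(stats::runif(n_de, log(config$de_ec50[1]),
                                          log(config$de_ec50[2])))

  # saturating Hill dose curve of the planted log2FC
  lfc_at <- function(conc) {
    sat <- conc^config$de_hill /
      (conc^config$de_hill + gene_ec50^config$de_hill)
    signs * config$max_log2fc * sat
  }

  all_conc <- c(0, concs)
  sample_conc <- rep(all_conc, each = nr)
  sample_rep <- rep(seq_len(nr), times = length(all_conc))
  sample_id <- sprintf("%s_c%02d_r%d", compound_id,
                       rep(seq_along(all_conc) - 1L, each = nr), sample_rep)
  ns <- length(sample_id)

  set.seed(stream_seed(config$seed, "size_factors"))
  sf <- stats::rlnorm(ns, 0, config$sf_sdlog)

  counts <- matrix(0L, ng, ns, dimnames = list(genes, sample_id))
  set.seed(stream_seed(config$seed, "counts"))
  for (j in seq_len(ns)) {
    lfc <- if (sample_conc[j] > 0) lfc_at(sample_conc[j]) else numeric(ng)
    mu <- pmin(sf[j] * baseline * 2^lfc, 1e8)
    counts[, j] <- as.integer(stats::rnbinom(ng, mu = mu,
                                             size = 1 / config$dispersion))
  }

  truth <- do.call(rbind, lapply(concs, function(cc)
    data.frame(gene_id = genes, concentration = cc,
               true_log2fc = lfc_at(cc))))
  meta <- data.frame(sample_id = sample_id, compound_id = compound_id,
                     concentration = sample_conc, replicate = sample_rep)
  list(counts = counts, meta = meta, truth = truth,
       baseline = stats::setNames(baseline, genes), size_factors_true = sf)
}

#' Simulate a key-event assay panel with known potency offsets
#'
#' For each compound, generates one concentration-response dataset per key
#' event (KE) endpoint. The KE4 (neurite) EC50 comes from the compound spec;
#' upstream KEs are shifted by MoA-class-specific multipliers:
#' `EC50(KE) = EC50(KE4) / multiplier`, so the planted KE4/KE sensitivity
#' ratio equals the multiplier. The Hill coefficient is shared across the
#' KEs of a compound, which makes the EC25 ratio equal the EC50 ratio
#' exactly. Truth ratios are returned for concordance-recovery tests.
#'
#' @param compounds list of [compound_spec()] objects.
#' @param ke_offset_map named list: MoA class -> named numeric vector of
#'   multipliers per KE endpoint (all > 0). KE4 is the anchor and implicitly
#'   has multiplier 1.
#' @param kes character vector of upstream KE endpoint names.
#' @param noise_sd,n_replicates,seed passed to the response generator.
#' @param grid_points,grid_dilution concentration grid shape; each KE's grid
#'   is centred on its own true EC50 so the EC25 is always within range.
#' @return A list with `datasets` (list of [dr_dataset()], including KE4)
#'   and `truth` (data.frame: compound_id, ke, true_ec50, true_ratio).
#' @export
generate_ke_panel <- function(compounds, ke_offset_map,
                              kes = c("KE1", "KE2", "KE3"),
                              noise_sd = 5, n_replicates = 3, seed = 1,
                              grid_points = 8, grid_dilution = sqrt(10)) {
  datasets <- list()
  truth <- list()
  for (sp in compounds) {
    stopifnot(inherits(sp, "compound_spec"))
    mult <- ke_offset_map[[sp$moa_class]]
    if (is.null(mult)) stop("no KE offsets for MoA class ", sp$moa_class)
    if (any(mult <= 0)) stop("KE multipliers must be > 0")
    ec50_ke4 <- spec_param(sp$ec50, "KE4")
    hill <- spec_param(sp$hill, "KE4")
    for (ke in c("KE4", kes)) {
      m <- if (ke == "KE4") 1 else unname(mult[[ke]])
      ec50 <- ec50_ke4 / m
      grid <- conc_grid(ec50 * grid_dilution^(grid_points / 2),
                        grid_dilution, grid_points)
      sp_ke <- sp
      sp_ke$ec50 <- ec50
      sp_ke$hill <- hill
      sp_ke$max_test_conc <- max(grid)
      ds <- generate_dose_response(sp_ke, endpoint = ke,
                                   concentrations = grid,
                                   noise_sd = noise_sd,
                                   n_replicates = n_replicates,
                                   seed = stream_seed(seed, paste("ke", ke)))
      datasets[[paste(sp$compound_id, ke, sep = ".")]] <- ds
      truth[[paste(sp$compound_id, ke, sep = ".")]] <-
        data.frame(compound_id = sp$compound_id, ke = ke,
                   moa_class = sp$moa_class, true_ec50 = ec50,
                   true_ratio = m)
    }
  }
  list(datasets = datasets, truth = do.call(rbind, c(truth,
                                                     make.row.names = FALSE)))
}

#' Default synthetic compound panel
#'
#' A 14-compound panel of respiratory-chain inhibitors spanning the three
#' complex classes, with class-typical neurite (KE4) potencies: complex I
#' inhibitors sub-micromolar to micromolar, complex III inhibitors
#' micromolar, complex II inhibitors weak (tens of micromolar).
#'
#' @param seed integer seed for the per-compound potency draws.
#' @return A list of [compound_spec()] objects.
#' @export
default_compound_panel <- function(seed = 1) {
  set.seed(stream_seed(seed, "panel"))
  classes <- c(rep("cI", 6), rep("cII", 3), rep("cIII", 5))
  # class-typical KE4 EC50 ranges (molar), sampled log-uniformly
  lo <- c(cI = 1e-7, cII = 2e-5, cIII = 1e-6)
  hi <- c(cI = 5e-6, cII = 1e-4, cIII = 2e-5)
  lapply(seq_along(classes), function(i) {
    cl <- classes[i]
    ec50 <- exp(stats::runif(1, log(lo[[cl]]), log(hi[[cl]])))
    hill <- stats::runif(1, 1, 3)
    compound_spec(sprintf("%s_%02d", tolower(cl), i), cl,
                  ec50 = ec50, hill = hill,
                  max_test_conc = min(ec50 * 100, 1e-4))
  })
}

#' Default key-event potency offset map
#'
#' Class-specific multipliers expressing how much more sensitive upstream
#' KE assays are than the neurite (KE4) endpoint: respiratory-chain
#' inhibition (KE1) is triggered orders of magnitude below neurite damage
#' for complex I and III inhibitors, mitochondrial dysfunction (KE2) sits
#' in between, and proteostasis (KE3) potency is close to KE4. The values
#' are deliberately at least 1.5-fold away from the ratio-category
#' boundaries (1/3, 3, 10, 100) so the planted category of every cell is
#' unambiguous.
#'
#' @return Named list: MoA class -> named multiplier vector over KE1..KE3.
#' @export
default_ke_offsets <- function() {
  list(cI = c(KE1 = 300, KE2 = 30, KE3 = 1),
       cII = c(KE1 = 30, KE2 = 5, KE3 = 1),
       cIII = c(KE1 = 200, KE2 = 30, KE3 = 1),
       other = c(KE1 = 1, KE2 = 1, KE3 = 1))
}
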