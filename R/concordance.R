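#' Specific-neurotoxicity classification
#'
#' The screening prediction model for specific neurotoxicity: the ratio of
#' cytotoxic to neurite potency, `EC25(V) / EC25(NA)`, computed on the
#' linear molar scale. A ratio above 4 classifies the compound as a
#' specific neurotoxicant; at or below 4 as unspecific. When viability is
#' unaffected in the tested range (EC25(V) undefined), a lower bound
#' `max_tested_conc / EC25(NA)` is used: a bound of at least 2 yields
#' `potential_lower_bound` (potentially specific), otherwise the call is
#' `not_determinable` — as is any compound without a neurite EC25.
#'
#' @param compound_id compound identifier.
#' @param ec25_v EC25 of viability (molar) or `NA` if not reached.
#' @param ec25_na EC25 of the neurite endpoint (molar) or `NA`.
#' @param max_tested_conc highest tested concentration (molar), used as
#'   censoring value when `ec25_v` is undefined.
#' @param specificity_cut ratio cut for the specific call (default 4; the
#'   rule is a strict `> 4`, so exactly 4 is unspecific).
#' @param bound_cut minimum censored bound for the potential call
#'   (default 2).
#' @return An object of class `specificity_call`: `compound_id`, `ec25_v`,
#'   `ec25_na`, `ratio` (NA when censored), `bound` (NA unless censored),
#'   `category`.
#' @export
specificity_call <- function(compound_id, ec25_v, ec25_na, max_tested_conc,
                             specificity_cut = 4, bound_cut = 2) {
  ratio <- NA_real_
  bound <- NA_real_
  if (is.na(ec25_na)) {
    category <- "not_determinable"
  } else if (!is.na(ec25_v)) {
    ratio <- ec25_v / ec25_na
    category <- if (ratio > specificity_cut) "specific" else "unspecific"
  } else {
    bound <- max_tested_conc / ec25_na
    category <- if (bound >= bound_cut) "potential_lower_bound"
                else "not_determinable"
  }
  structure(list(compound_id = compound_id, ec25_v = ec25_v,
                 ec25_na = ec25_na, ratio = ratio, bound = bound,
                 category = category),
            class = "specificity_call")
}

#' Fixed-concentration hit call
#'
#' Virtual single-concentration screen: a compound is a hit (`"+"`) at the
#' screen concentration (default 50 uM) when its effect there is at least
#' 25 percent, otherwise inactive (`"O"`). The effect is `100 - response`
#' interpolated from the fitted Hill curve, so compounds tested on
#' different grids are compared at a common concentration; for flat
#' (unfittable) curves the mean observed responses are interpolated in log
#' concentration instead.
#'
#' @param dataset a [dr_dataset()].
#' @param screen_concentration molar screen concentration (default 5e-5,
#'   i.e. 50 uM).
#' @param effect_cut minimum effect in percent for a hit (default 25; the
#'   rule is `>= 25`).
#' @param fit optional pre-computed [fit_hill()] result for the dataset.
#' @return An object of class `hit_call`: `compound_id`, `assay`,
#'   `screen_concentration`, `effect_at_conc`, `call` (`"+"` or `"O"`),
#'   `extrapolated`.
#' @export
hit_call <- function(dataset, screen_concentration = 5e-5,
                     effect_cut = 25, fit = NULL) {
  stopifnot(inherits(dataset, "dr_dataset"))
  rng <- range(dataset$data$concentration)
  if (is.null(fit))
    fit <- fit_hill(dataset)
  extrapolated <- screen_concentration < rng[1] ||
    screen_concentration > rng[2]
  if (isTRUE(fit$converged)) {
    response <- hill_predict(screen_concentration, fit$ec50, fit$hill_coef,
                             fit$direction)
  } else if (!extrapolated) {
    mr <- tapply(dataset$data$response, dataset$data$concentration, mean)
    response <- stats::approx(log(as.numeric(names(mr))), as.numeric(mr),
                              xout = log(screen_concentration))$y
  } else {
    stop("UndefinedAtConcentration: neither the data range nor a ",
         "converged fit covers the screen concentration")
  }
  effect <- 100 - response
  structure(list(compound_id = dataset$compound_id,
                 assay = dataset$endpoint,
                 screen_concentration = screen_concentration,
                 effect_at_conc = effect,
                 call = if (effect >= effect_cut) "+" else "O",
                 extrapolated = extrapolated),
            class = "hit_call")
}

#' Categorize a key-event sensitivity ratio
#'
#' Ratio categories of the synoptic KE matrix: `strong` (> 100), `marked`
#' (> 10), `moderate` (> 3), `neutral` (within \[1/3, 3\]), `inverse`
#' (< 1/3), `n.a.` for undefined ratios. All rules are strict
#' inequalities, so boundary values fall in the lower category.
#'
#' @param ratio numeric vector of KE sensitivity ratios.
#' @return Character vector of categories.
#' @export
ke_ratio_category <- function(ratio) {
  vapply(ratio, function(r) {
    if (is.na(r)) return("n.a.")
    if (r > 100) "strong"
    else if (r > 10) "marked"
    else if (r > 3) "moderate"
    else if (r >= 1 / 3) "neutral"
    else "inverse"
  }, character(1))
}

#' Synoptic key-event sensitivity ratio matrix
#'
#' For each compound, expresses the EC25 of the anchor KE assay (default
#' KE4, the neurite endpoint) relative to each upstream KE assay:
#' `ratio = EC25(anchor) / EC25(other)`, on the linear molar scale. Ratios
#' above 1 mean the upstream assay responds at lower concentrations than
#' the anchor. Compounds without an anchor EC25 get `n.a.` throughout; an
#' undefined upstream EC25 yields `n.a.` for that cell, with an optional
#' censored lower-bound ratio when `max_tested_conc` is supplied.
#'
#' @param ec25_table data.frame with columns `compound_id`, `ke`,
#'   `ec25_M` (NA when not reached) and optionally `max_tested_conc`.
#' @param anchor_ke anchor assay (default `"KE4"`).
#' @return A data.frame with `compound_id`, `ke`, `ratio`, `category`,
#'   `censored_bound`.
#' @export
ke_ratio_matrix <- function(ec25_table, anchor_ke = "KE4") {
  stopifnot(all(c("compound_id", "ke", "ec25_M") %in% names(ec25_table)))
  out <- list()
  for (cid in unique(ec25_table$compound_id)) {
    sub <- ec25_table[ec25_table$compound_id == cid, , drop = FALSE]
    anchor <- sub$ec25_M[sub$ke == anchor_ke]
    anchor <- if (length(anchor)) anchor[1] else NA_real_
    others <- sub[sub$ke != anchor_ke, , drop = FALSE]
    for (i in seq_len(nrow(others))) {
      ratio <- anchor / others$ec25_M[i]           # NA-propagating
      bound <- NA_real_
      if (!is.na(anchor) && is.na(others$ec25_M[i]) &&
          "max_tested_conc" %in% names(others))
        bound <- anchor / others$max_tested_conc[i]
      out[[length(out) + 1L]] <-
        data.frame(compound_id = cid, ke = others$ke[i], ratio = ratio,
                   category = ke_ratio_category(ratio),
                   censored_bound = bound)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Qualitative key-event concordance summary
#'
#' Compares fixed-concentration hit calls across the KE assays of each
#' compound with the anchor (KE4) call: a compound is fully concordant
#' when every available KE assay agrees with KE4. Missing assays are
#' tolerated and flagged as a partial comparison.
#'
#' @param hits data.frame with columns `compound_id`, `ke`, `call`
#'   (`"+"` or `"O"`), e.g. assembled from [hit_call()] results.
#' @param anchor_ke anchor assay (default `"KE4"`).
#' @param kes KE assays expected per compound.
#' @return A data.frame with `compound_id`, one `"+"`/`"O"`/NA column per
#'   KE, `concordant` (logical) and `partial` (logical).
#' @export
concordance_table <- function(hits, anchor_ke = "KE4",
                              kes = c("KE1", "KE2", "KE3", "KE4")) {
  stopifnot(all(c("compound_id", "ke", "call") %in% names(hits)))
  rows <- lapply(unique(hits$compound_id), function(cid) {
    sub <- hits[hits$compound_id == cid, , drop = FALSE]
    calls <- stats::setNames(sub$call[match(kes, sub$ke)], kes)
    anchor <- calls[[anchor_ke]]
    avail <- !is.na(calls)
    if (sum(avail) < 2 || is.na(anchor))
      conc <- NA
    else
      conc <- all(calls[avail] == anchor)
    cbind(data.frame(compound_id = cid),
          as.data.frame(as.list(calls)),
          data.frame(concordant = conc, partial = !all(avail)))
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
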