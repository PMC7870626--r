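#' Oxygen-consumption-rate trace for one well
#'
#' Ordered OCR measurements with the three event indices the inhibition
#' arithmetic needs: the end of equilibration, the last measurement before
#' compound treatment, and the last measurement before the rotenone +
#' antimycin A injection that abolishes mitochondrial respiration.
#'
#' @param well_id well identifier.
#' @param ocr numeric vector of OCR values (pmol O2/min; any consistent
#'   unit) in measurement order.
#' @param events named list or vector of measurement indices:
#'   `equilibration_end`, `treatment` (last pre-treatment measurement),
#'   `rot_aa_injection` (last measurement before the rotenone/antimycin A
#'   injection). Must satisfy
#'   `equilibration_end <= treatment < rot_aa_injection`.
#' @return An object of class `ocr_trace`.
#' @export
ocr_trace <- function(well_id, ocr, events) {
  ocr <- as.numeric(ocr)
  if (any(!is.finite(ocr))) stop("OCR values must be finite")
  ev <- lapply(events[c("equilibration_end", "treatment",
                        "rot_aa_injection")], as.integer)
  if (any(vapply(ev, length, 1L) != 1) || any(is.na(unlist(ev))))
    stop("events must name equilibration_end, treatment, rot_aa_injection")
  if (!(ev$equilibration_end <= ev$treatment &&
        ev$treatment < ev$rot_aa_injection))
    stop("events must be ordered equilibration_end <= treatment < ",
         "rot_aa_injection")
  if (ev$rot_aa_injection >= length(ocr))
    stop("need at least one measurement after the rot/AA injection")
  structure(list(well_id = well_id, ocr = ocr, events = ev),
            class = "ocr_trace")
}

#' Internal normalization of an OCR trace
#'
#' Divides every OCR value of a well by its value at the end of
#' equilibration, removing well-to-well seeding and sensor differences;
#' the equilibration point becomes 1.0.
#'
#' @param trace an [ocr_trace()].
#' @return The trace with normalized OCR values.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "ocr_trace"))
  base <- trace$ocr[trace$events$equilibration_end]
  if (base == 0) stop("ZeroBaseline: OCR at equilibration end is zero")
  trace$ocr <- trace$ocr / base
  trace
}

#' Mitochondrial respiration inhibition of one well
#'
#' Inhibition is the drop from the baseline (the last measurement before
#' treatment) to the first measurement after treatment, after subtracting
#' non-mitochondrial respiration `nm` (the mean OCR after the rotenone +
#' antimycin A injection) from both:
#' `100 * ((baseline - nm) - (post - nm)) / (baseline - nm)`.
#' The value is not clamped; over-shooting wells report > 100 or < 0 and
#' are left to the caller to flag.
#'
#' @param trace an [ocr_trace()].
#' @return Percent inhibition of mitochondrial respiration.
#' @export
mito_inhibition <- function(trace) {
  stopifnot(inherits(trace, "ocr_trace"))
  ev <- trace$events
  baseline <- trace$ocr[ev$treatment]
  post <- trace$ocr[ev$treatment + 1L]
  nm <- mean(trace$ocr[(ev$rot_aa_injection + 1L):length(trace$ocr)])
  if (baseline <= nm)
    stop("NonPositiveMitoBaseline: baseline OCR does not exceed ",
         "non-mitochondrial OCR")
  100 * ((baseline - nm) - (post - nm)) / (baseline - nm)
}

#' Negative-control noise band
#'
#' The assay's insignificance band from vehicle-control inhibition values:
#' mean plus/minus two standard deviations. Compound inhibitions inside
#' the band are regarded as insignificant.
#'
#' @param control_inhibitions percent inhibition values of vehicle-control
#'   wells (>= 6 values).
#' @return A list with `lower`, `upper`, `mean`, `sd`, `n` and a helper
#'   predicate is applied via [in_noise_band()].
#' @export
noise_band <- function(control_inhibitions) {
  if (length(control_inhibitions) < 6)
    stop("TooFewControls: need >= 6 vehicle-control inhibition values")
  m <- mean(control_inhibitions)
  s <- stats::sd(control_inhibitions)
  list(lower = m - 2 * s, upper = m + 2 * s, mean = m, sd = s,
       n = length(control_inhibitions))
}

#' Flag inhibition values inside the noise band
#'
#' @param values percent inhibition values.
#' @param band a [noise_band()].
#' @return Logical vector: TRUE where the value lies inside the band
#'   (insignificant).
#' @export
in_noise_band <- function(values, band) {
  values >= band$lower & values <= band$upper
}

#' Summarize per-well inhibition per compound
#'
#' Mean plus/minus standard error across wells, the usual reporting form
#' for the respirometry assay.
#'
#' @param inhibitions data.frame with columns `compound_id`, `inhibition`.
#' @return A data.frame with `compound_id`, `mean_inhibition`, `sem`, `n`.
#' @export
summarize_inhibition <- function(inhibitions) {
  stopifnot(all(c("compound_id", "inhibition") %in% names(inhibitions)))
  rows <- lapply(split(inhibitions, inhibitions$compound_id), function(s)
    data.frame(compound_id = s$compound_id[1],
               mean_inhibition = mean(s$inhibition),
               sem = stats::sd(s$inhibition) / sqrt(nrow(s)),
               n = nrow(s)))
  do.call(rbind, c(rows, make.row.names = FALSE))
}
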