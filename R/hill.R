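#' Concentration-response dataset
#'
#' Container for replicate percent-of-control responses measured across a
#' concentration series for one compound x endpoint x cell model. This is the
#' unit of data consumed by [fit_hill()] and [benchmark_concentration()].
#'
#' @param compound_id compound identifier.
#' @param endpoint endpoint identifier, e.g. `"V"` (viability), `"NA"`
#'   (neurite area), `"MMP"`, `"ATP"`, `"DGH"`.
#' @param cell_model cell model label (e.g. `"LUHMES"`).
#' @param concentration numeric vector of molar concentrations, one entry per
#'   measured well (replicates repeat the concentration).
#' @param response numeric vector of responses in percent of vehicle control,
#'   parallel to `concentration`.
#' @param truth optional list of generating parameters (kept by the synthetic
#'   data generators so recovery tests need no external files).
#'
#' @return An object of class `dr_dataset`: a list with elements
#'   `compound_id`, `endpoint`, `cell_model`, `data` (a data.frame with
#'   columns `concentration`, `response`) and `truth`.
#' @export
dr_dataset <- function(compound_id, endpoint, cell_model = "LUHMES",
                       concentration, response, truth = NULL) {
  concentration <- as.numeric(concentration)
  response <- as.numeric(response)
  if (length(concentration) != length(response))
    stop("concentration and response must have equal length")
  if (any(!is.finite(concentration)) || any(concentration <= 0))
    stop("concentrations must be finite and strictly positive")
  if (any(!is.finite(response)))
    stop("responses must be finite")
  structure(
    list(compound_id = as.character(compound_id),
         endpoint = as.character(endpoint),
         cell_model = as.character(cell_model),
         data = data.frame(concentration = concentration,
                           response = response),
         truth = truth),
    class = "dr_dataset")
}

#' @export
print.dr_dataset <- function(x, ...) {
  cat(sprintf("<dr_dataset> %s / %s / %s: %d points, %d concentrations\n",
              x$compound_id, x$endpoint, x$cell_model, nrow(x$data),
              length(unique(x$data$concentration))))
  invisible(x)
}

#' Predicted Hill response with fixed asymptotes
#'
#' Evaluates the constrained Hill model (top 100, bottom 0):
#' `100 / (1 + (c / EC50)^h)` for decreasing endpoints,
#' `100 / (1 + (EC50 / c)^h)` for increasing ones.
#'
#' @param conc molar concentration(s).
#' @param ec50 midpoint concentration (molar).
#' @param hill Hill coefficient (> 0).
#' @param direction `"decreasing"` or `"increasing"`.
#' @return Predicted response(s) in percent of control.
#' @export
hill_predict <- function(conc, ec50, hill, direction = "decreasing") {
  lr <- hill * (log(conc) - log(ec50))
  if (direction == "decreasing") {
    100 / (1 + exp(lr))
  } else {
    100 / (1 + exp(-lr))
  }
}

#' Fit the constrained four-parameter Hill model
#'
#' Least-squares fit of the Hill concentration-response model with the upper
#' and lower asymptotes fixed at 100 and 0 percent of control. Only the
#' midpoint (EC50) and the Hill coefficient are free. The optimisation runs
#' in `(log10 EC50, log h)` space with box constraints (EC50 within
#' `[min conc / 100, max conc * 100]`, h within `[0.2, 10]`) and is
#' multi-started from three EC50 guesses at the geometric quartiles of the
#' tested range; the lowest residual sum of squares wins, ties going to the
#' smaller Hill coefficient.
#'
#' A dataset in which no tested concentration reaches the flat-curve effect
#' threshold (default 25 percent effect) is reported as a flat curve: the fit
#' is marked non-converged and no EC50 is reported, mirroring screening
#' practice of not deriving potencies from inactive curves.
#'
#' @param dataset a [dr_dataset()].
#' @param direction `"decreasing"` for inhibition endpoints (response falls
#'   from 100 towards 0) or `"increasing"` for responses that rise from 0
#'   towards 100 (e.g. the normalized DEG response).
#' @param flat_threshold minimum effect (percent) that some tested
#'   concentration must reach for the curve to be considered fittable.
#' @return An object of class `hill_fit` with elements `ec50`, `hill_coef`,
#'   `top` (100), `bottom` (0), `rss`, `converged`, `flat`, `n_points`,
#'   `direction` and `conc_range`.
#' @export
fit_hill <- function(dataset, direction = c("decreasing", "increasing"),
                     flat_threshold = 25) {
  direction <- match.arg(direction)
  stopifnot(inherits(dataset, "dr_dataset"))
  d <- dataset$data
  concs <- sort(unique(d$concentration))
  if (length(concs) < 4)
    stop("DegenerateInput: need >= 4 distinct concentrations, got ",
         length(concs))

  mean_resp <- tapply(d$response, d$concentration, mean)
  effect <- if (direction == "decreasing") 100 - mean_resp else mean_resp
  flat <- max(effect) < flat_threshold

  out <- structure(
    list(compound_id = dataset$compound_id, endpoint = dataset$endpoint,
         ec50 = NA_real_, hill_coef = NA_real_, top = 100, bottom = 0,
         rss = NA_real_, converged = FALSE, flat = flat,
         n_points = nrow(d), direction = direction,
         conc_range = range(d$concentration)),
    class = "hill_fit")
  if (flat) return(out)

  cc <- d$concentration
  yy <- d$response
  sgn <- if (direction == "decreasing") 1 else -1
  obj <- function(p) {
    lr <- sgn * exp(p[2]) * (log(cc) - p[1] * log(10))
    sum((yy - 100 / (1 + exp(lr)))^2)
  }
  grad <- function(p) {
    h <- exp(p[2])
    lr <- sgn * h * (log(cc) - p[1] * log(10))
    e <- exp(lr)
    f <- 100 / (1 + e)
    r <- yy - f
    dfdlr <- -100 * e / (1 + e)^2
    dlr_dp1 <- -sgn * h * log(10)
    dlr_dp2 <- sgn * h * (log(cc) - p[1] * log(10))
    c(-2 * sum(r * dfdlr * dlr_dp1), -2 * sum(r * dfdlr * dlr_dp2))
  }

  lo <- c(log10(min(cc)) - 2, log(0.2))
  hi <- c(log10(max(cc)) + 2, log(10))
  qs <- log10(min(cc)) + c(0.25, 0.5, 0.75) * (log10(max(cc)) - log10(min(cc)))
  best <- NULL
  for (q in qs) {
    fit <- try(stats::optim(c(q, log(1)), obj, gr = grad,
                            method = "L-BFGS-B", lower = lo, upper = hi),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value - 1e-9 ||
        (abs(fit$value - best$value) <= 1e-9 && fit$par[2] < best$par[2]))
      best <- fit
  }
  if (is.null(best)) return(out)

  out$ec50 <- 10^best$par[1]
  out$hill_coef <- exp(best$par[2])
  out$rss <- best$value
  out$converged <- TRUE
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<hill_fit> %s/%s EC50 = %.4g M, h = %.3g, RSS = %.3g\n",
                x$compound_id, x$endpoint, x$ec50, x$hill_coef, x$rss))
  } else {
    cat(sprintf("<hill_fit> %s/%s not converged%s\n", x$compound_id,
                x$endpoint, if (isTRUE(x$flat)) " (flat curve)" else ""))
  }
  invisible(x)
}

#' Solve the Hill equation for an effective concentration
#'
#' Computes the concentration producing an `x` percent effect from a
#' converged Hill fit, analytically:
#' `ECx = EC50 * (x / (100 - x))^(1 / h)`. The same closed form holds for
#' both curve directions (an `x` percent reduction for decreasing endpoints,
#' an `x` percent response for increasing ones).
#'
#' @param fit a converged [fit_hill()] result.
#' @param x effect level in percent, strictly between 0 and 100.
#' @return An object of class `ec_estimate` with elements `x`,
#'   `concentration` (molar), `pec` (`-log10` molar) and `extrapolated`
#'   (TRUE when the solution lies outside the tested concentration range).
#' @export
effective_concentration <- function(fit, x) {
  stopifnot(inherits(fit, "hill_fit"))
  if (!isTRUE(fit$converged))
    stop("UndefinedEC: fit did not converge (flat or degenerate curve)")
  if (!is.numeric(x) || length(x) != 1 || x <= 0 || x >= 100)
    stop("effect level x must lie strictly between 0 and 100")
  conc <- fit$ec50 * (x / (100 - x))^(1 / fit$hill_coef)
  structure(
    list(x = x, concentration = conc, pec = -log10(conc),
         extrapolated = conc < fit$conc_range[1] | conc > fit$conc_range[2],
         endpoint = fit$endpoint, compound_id = fit$compound_id),
    class = "ec_estimate")
}

#' @export
print.ec_estimate <- function(x, ...) {
  cat(sprintf("<ec_estimate> EC%g = %.4g M (pEC %.3f)%s\n", x$x,
              x$concentration, x$pec,
              if (x$extrapolated) " [extrapolated]" else ""))
  invisible(x)
}

#' Benchmark concentration with bootstrap confidence interval
#'
#' Point estimate: the effective concentration at the benchmark response
#' (default 10 percent effect) from the Hill fit of the full dataset.
#' Confidence interval: case-resampling bootstrap of replicates within each
#' concentration, refitting per resample (single-started from the full-data
#' fit) and taking the 2.5/97.5 percentile interval of the resampled
#' benchmark concentrations. The point estimate does not depend on the seed.
#'
#' @param dataset a [dr_dataset()].
#' @param benchmark_response benchmark response in percent effect (default 10).
#' @param n_bootstrap number of bootstrap resamples (default 1000).
#' @param seed integer seed for the resampling.
#' @inheritParams fit_hill
#' @return An object of class `bmc_result` with elements
#'   `benchmark_response`, `bmc`, `ci_lower`, `ci_upper`, `n_bootstrap`,
#'   `seed`, `failed_fraction` and the underlying `fit`.
#' @export
benchmark_concentration <- function(dataset, benchmark_response = 10,
                                    n_bootstrap = 1000, seed = 1,
                                    direction = "decreasing",
                                    flat_threshold = 25) {
  fit <- fit_hill(dataset, direction = direction,
                  flat_threshold = flat_threshold)
  if (!fit$converged)
    stop("FlatCurve: benchmark concentration undefined for a flat curve")
  point <- effective_concentration(fit, benchmark_response)

  d <- dataset$data
  groups <- split(seq_len(nrow(d)), d$concentration)
  set.seed(seed)
  bmcs <- rep(NA_real_, n_bootstrap)
  for (b in seq_len(n_bootstrap)) {
    idx <- unlist(lapply(groups, function(g) g[sample.int(length(g),
                                                          replace = TRUE)]),
                  use.names = FALSE)
    ds_b <- dataset
    ds_b$data <- d[idx, , drop = FALSE]
    fb <- refit_hill_from(ds_b, fit, flat_threshold = flat_threshold)
    if (!is.null(fb) && fb$converged)
      bmcs[b] <- fb$ec50 *
        (benchmark_response / (100 - benchmark_response))^(1 / fb$hill_coef)
  }
  ok <- bmcs[!is.na(bmcs)]
  ci <- if (length(ok) >= 2) stats::quantile(ok, c(0.025, 0.975), names = FALSE)
        else c(NA_real_, NA_real_)
  structure(
    list(benchmark_response = benchmark_response,
         bmc = point$concentration,
         ci_lower = ci[1], ci_upper = ci[2],
         n_bootstrap = n_bootstrap, seed = seed,
         failed_fraction = 1 - length(ok) / n_bootstrap,
         fit = fit),
    class = "bmc_result")
}

# single-start refit used inside the bootstrap: warm start at the full-data
# optimum; skips the flat-curve screen only when the resample is flat
refit_hill_from <- function(dataset, fit0, flat_threshold) {
  d <- dataset$data
  cc <- d$concentration
  yy <- d$response
  mean_resp <- tapply(yy, cc, mean)
  effect <- if (fit0$direction == "decreasing") 100 - mean_resp else mean_resp
  if (max(effect) < flat_threshold) return(NULL)
  sgn <- if (fit0$direction == "decreasing") 1 else -1
  obj <- function(p) {
    lr <- sgn * exp(p[2]) * (log(cc) - p[1] * log(10))
    sum((yy - 100 / (1 + exp(lr)))^2)
  }
  lo <- c(log10(min(cc)) - 2, log(0.2))
  hi <- c(log10(max(cc)) + 2, log(10))
  p0 <- pmin(pmax(c(log10(fit0$ec50), log(fit0$hill_coef)), lo), hi)
  fit <- try(stats::optim(p0, obj, method = "L-BFGS-B",
                          lower = lo, upper = hi), silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  list(ec50 = 10^fit$par[1], hill_coef = exp(fit$par[2]),
       rss = fit$value, converged = TRUE)
}

#' @export
print.bmc_result <- function(x, ...) {
  cat(sprintf(
    "<bmc_result> BMC%g = %.4g M [%.4g, %.4g], %d bootstraps (%.1f%% failed)\n",
    x$benchmark_response, x$bmc, x$ci_lower, x$ci_upper, x$n_bootstrap,
    100 * x$failed_fraction))
  invisible(x)
}

#' Potency shift between two effective concentrations
#'
#' Fold change `ec_a / ec_b` on the linear molar scale, e.g. to express how
#' much more sensitive one exposure scenario is than another at the same
#' effect level.
#'
#' @param ec_a,ec_b [effective_concentration()] estimates at the same effect
#'   level.
#' @return A single fold-change value (dimensionless).
#' @export
potency_shift <- function(ec_a, ec_b) {
  stopifnot(inherits(ec_a, "ec_estimate"), inherits(ec_b, "ec_estimate"))
  if (!isTRUE(all.equal(ec_a$x, ec_b$x)))
    stop("potency shift requires matching effect levels")
  if (!is.finite(ec_a$concentration) || !is.finite(ec_b$concentration))
    stop("UndefinedEC: both estimates must be defined")
  ec_a$concentration / ec_b$concentration
}
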