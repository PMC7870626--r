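# shared fixtures, built in code at test time

# noise-free decreasing Hill dataset with known parameters
make_clean_dataset <- function(ec50 = 1e-6, hill = 1.5, top_conc = 1e-4,
                               n_conc = 8, n_rep = 3, endpoint = "NA") {
  grid <- conc_grid(top_conc, sqrt(10), n_conc)
  conc <- rep(grid, each = n_rep)
  dr_dataset("fixture", endpoint, "LUHMES", conc,
             hill_predict(conc, ec50, hill),
             truth = list(ec50 = ec50, hill = hill))
}

# brute-force Benjamini-Hochberg step-up, written from the definition:
# padj for the i-th smallest p is the minimum over ranks j >= i of
# p_(j) * n / j, capped at 1
bh_brute_force <- function(p) {
  n <- length(p)
  ord <- order(p)
  padj_sorted <- numeric(n)
  for (i in seq_len(n)) {
    cand <- vapply(i:n, function(j) p[ord[j]] * n / j, numeric(1))
    padj_sorted[i] <- min(1, min(cand))
  }
  out <- numeric(n)
  out[ord] <- padj_sorted
  out
}

# bisection solve of the decreasing Hill curve for x% effect
ecx_bisect <- function(ec50, hill, x, lo = 1e-15, hi = 1e5,
                       tol = 1e-12) {
  f <- function(c) hill_predict(c, ec50, hill) - (100 - x)
  for (i in 1:2000) {
    mid <- sqrt(lo * hi)    # geometric bisection on the log scale
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi / lo - 1 < tol) break
  }
  sqrt(lo * hi)
}

# assemble an EC25 table from fitted KE panel datasets
fit_ke_ec25 <- function(ke) {
  do.call(rbind, lapply(ke$datasets, function(d) {
    f <- fit_hill(d)
    data.frame(compound_id = d$compound_id, ke = d$endpoint,
               ec25_M = if (f$converged)
                 effective_concentration(f, 25)$concentration
               else NA_real_)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
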