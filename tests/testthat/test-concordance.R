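test_that("specificity calls follow the ratio prediction model", {
  s <- specificity_call("a", ec25_v = 8e-6, ec25_na = 1e-6,
                        max_tested_conc = 1e-4)
  expect_equal(s$ratio, 8)
  expect_equal(s$category, "specific")

  s2 <- specificity_call("b", 2e-6, 1e-6, 1e-4)
  expect_equal(s2$category, "unspecific")

  # ratio exactly 4 is unspecific (the rule is a strict > 4)
  s3 <- specificity_call("c", 4e-6, 1e-6, 1e-4)
  expect_equal(s3$category, "unspecific")

  # censored: no viability effect up to 100 uM, neurite EC25 at 10 uM
  s4 <- specificity_call("d", NA, 1e-5, 1e-4)
  expect_equal(s4$bound, 10)
  expect_equal(s4$category, "potential_lower_bound")

  s5 <- specificity_call("e", NA, 8e-5, 1e-4)   # bound 1.25 < 2
  expect_equal(s5$category, "not_determinable")
  expect_equal(specificity_call("f", NA, NA, 1e-4)$category,
               "not_determinable")
})

test_that("fixed-concentration hit calls use the 25% effect rule", {
  # curve passing through 60% response at 50 uM -> 40% effect -> hit
  mk <- function(ec50, hill = 1) {
    grid <- conc_grid(1e-3, sqrt(10), 8)
    dr_dataset("c", "KE4", "LUHMES", rep(grid, each = 2),
               rep(hill_predict(grid, ec50, hill), each = 2))
  }
  ec50_for <- function(resp_at_50uM, hill = 1)
    5e-5 * ((100 - resp_at_50uM) / resp_at_50uM)^(-1 / hill)
  h1 <- hit_call(mk(ec50_for(60)))
  expect_equal(h1$effect_at_conc, 40, tolerance = 1e-3)
  expect_equal(h1$call, "+")
  h2 <- hit_call(mk(ec50_for(80)))
  expect_equal(h2$effect_at_conc, 20, tolerance = 1e-3)
  expect_equal(h2$call, "O")
  # the 25% rule is inclusive: an effect at (or a hair above) the cut is a
  # hit, a hair below is not
  grid25 <- conc_grid(1e-3, sqrt(10), 8)
  carrier <- dr_dataset("c", "KE4", "LUHMES", grid25,
                        hill_predict(grid25, 1e-4, 1))
  mkfit <- function(resp_at_screen) {
    ec50 <- 5e-5 * ((100 - resp_at_screen) / resp_at_screen)^(-1)
    structure(list(compound_id = "c", endpoint = "KE4", ec50 = ec50,
                   hill_coef = 1, top = 100, bottom = 0, converged = TRUE,
                   flat = FALSE, direction = "decreasing",
                   conc_range = range(grid25)),
              class = "hill_fit")
  }
  expect_equal(hit_call(carrier, fit = mkfit(74.999))$call, "+")
  expect_equal(hit_call(carrier, fit = mkfit(75.001))$call, "O")

  # flat curve, screen concentration inside the tested range: data
  # interpolation, no hit
  grid <- conc_grid(1e-3, sqrt(10), 8)
  flat <- dr_dataset("c", "KE4", "LUHMES", rep(grid, each = 2),
                     rep(100, 16))
  hf <- hit_call(flat)
  expect_equal(hf$call, "O")
  # neither data nor fit covers the screen concentration
  low <- dr_dataset("c", "KE4", "LUHMES",
                    rep(conc_grid(1e-6, sqrt(10), 5), each = 2),
                    rep(100, 10))
  expect_error(hit_call(low), "UndefinedAtConcentration")
})

test_that("KE ratio categories respect the strict boundaries", {
  expect_equal(ke_ratio_category(48), "marked")
  expect_equal(ke_ratio_category(1), "neutral")
  expect_equal(ke_ratio_category(0.2), "inverse")
  # boundary values resolve to the lower category
  expect_equal(ke_ratio_category(c(3, 10, 100, 1 / 3)),
               c("neutral", "moderate", "marked", "neutral"))
  expect_equal(ke_ratio_category(c(3.001, 10.001, 100.001, 0.3332)),
               c("moderate", "marked", "strong", "inverse"))
  expect_equal(ke_ratio_category(NA), "n.a.")
  # order preservation: the category index never decreases with the ratio
  r <- sort(c(0.1, 0.5, 2, 4, 20, 200))
  lev <- c("inverse", "neutral", "moderate", "marked", "strong")
  idx <- match(ke_ratio_category(r), lev)
  expect_true(all(diff(idx) >= 0))
})

test_that("the KE ratio matrix anchors on KE4 and censors missing ECs", {
  tab <- data.frame(
    compound_id = rep(c("a", "b"), each = 4),
    ke = rep(c("KE4", "KE1", "KE2", "KE3"), 2),
    ec25_M = c(1e-5, 2e-7, 2e-6, NA, NA, 1e-6, 1e-6, 1e-6),
    max_tested_conc = 1e-4)
  rm <- ke_ratio_matrix(tab)
  a <- rm[rm$compound_id == "a", ]
  expect_equal(a$ratio[a$ke == "KE1"], 50)
  expect_equal(a$category[a$ke == "KE1"], "marked")
  expect_equal(a$ratio[a$ke == "KE2"], 5)
  expect_equal(a$category[a$ke == "KE3"], "n.a.")
  expect_equal(a$censored_bound[a$ke == "KE3"], 1e-5 / 1e-4)
  # no anchor: the whole row is n.a.
  b <- rm[rm$compound_id == "b", ]
  expect_true(all(b$category == "n.a."))
})

test_that("ratios, categories and calls are invariant to unit rescaling", {
  panel <- default_compound_panel(seed = 3)[1:3]
  ke <- generate_ke_panel(panel, default_ke_offsets(), noise_sd = 3,
                          seed = 3)
  ec25 <- fit_ke_ec25(ke)
  rm1 <- ke_ratio_matrix(ec25)
  scaled <- ec25
  scaled$ec25_M <- scaled$ec25_M * 1e3
  rm2 <- ke_ratio_matrix(scaled)
  expect_equal(rm1$ratio, rm2$ratio, tolerance = 1e-12)
  expect_identical(rm1$category, rm2$category)
})

test_that("concordance summaries compare KE calls against the anchor", {
  hits <- data.frame(
    compound_id = rep(c("a", "b", "c"), each = 4),
    ke = rep(c("KE1", "KE2", "KE3", "KE4"), 3),
    call = c("+", "+", "+", "+",
             "+", "O", "O", "O",
             "+", "+", NA, "+"))
  ct <- concordance_table(hits)
  expect_true(ct$concordant[ct$compound_id == "a"])
  expect_false(ct$concordant[ct$compound_id == "b"])   # KE4 O, KE1 +
  # missing KE3: computed over the available assays, flagged partial
  expect_true(ct$concordant[ct$compound_id == "c"])
  expect_true(ct$partial[ct$compound_id == "c"])
  expect_false(ct$partial[ct$compound_id == "a"])
})
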