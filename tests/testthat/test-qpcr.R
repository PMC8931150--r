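test_that("standard-curve fit recovers the published dilution-series line", {
  m <- c(20, 10, 5, 2.5, 1.25)
  sc <- fit_standard_curve(m, 38.476 - 3.324 * log10(m))
  expect_equal(sc$slope, -3.324, tolerance = 1e-10)
  expect_equal(sc$y_intercept, 38.476, tolerance = 1e-10)
  expect_equal(sc$r_squared, 1.0, tolerance = 1e-10)
  expect_equal(round(sc$efficiency_percent, 1), 99.9)

  # perfect doubling: slope -1/log10(2)
  sc2 <- fit_standard_curve(m, 30 - log10(m) / log10(2))
  expect_equal(round(sc2$efficiency_percent, 1), 100.0)
  expect_equal(sc2$amplification_factor, 2, tolerance = 1e-10)

  # two points: R^2 = 1 by construction
  expect_equal(fit_standard_curve(c(20, 10), c(30, 33.3))$r_squared, 1.0)

  expect_error(fit_standard_curve(c(10, 10), c(30, 31)), "underdetermined")
  expect_error(fit_standard_curve(c(-1, 10), c(30, 31)), "domain")
})

test_that("efficiency from slope matches the published percentages", {
  expect_equal(round(efficiency_from_slope(-3.324)$efficiency_percent, 1), 99.9)
  expect_equal(round(efficiency_from_slope(-3.341)$efficiency_percent, 1), 99.2)
  expect_equal(round(efficiency_from_slope(-3.3219)$efficiency_percent, 1), 100.0)
  expect_error(efficiency_from_slope(0.5), "domain")
  expect_error(efficiency_from_slope(Inf), "domain")
})

test_that("efficiency round-trips through noise-free generated points", {
  for (e_true in c(1.85, 1.95, 2.0)) {
    slope <- -1 / log10(e_true)
    m <- c(20, 10, 5, 2.5, 1.25)
    sc <- fit_standard_curve(m, 35 + slope * log10(m))
    expect_equal(sc$amplification_factor, e_true, tolerance = 1e-9)
  }
})

test_that("slope-difference rule separates comparable from divergent curves", {
  r <- validate_slope_difference(ld_target_curve(), ld_reference_curve())
  expect_equal(r$difference, 0.017, tolerance = 1e-12)
  expect_true(r$pass)
  expect_true(validate_slope_difference(-3.3, -3.3)$pass)
  r2 <- validate_slope_difference(-3.2, -3.5)
  expect_equal(r2$difference, 0.3)
  expect_false(r2$pass)
})

test_that("technical-replicate aggregation means, flags, and errors", {
  expect_equal(mean_ct(c(21, 21, 21)),
               list(mean = 21, sd = 0, n_used = 3L, flagged = FALSE))
  r <- mean_ct(c(20.9, 21.0, 21.1))
  expect_equal(r$mean, 21)
  expect_equal(r$sd, 0.1)
  expect_false(r$flagged)
  # dispersed triplet: sd = sqrt(3) > 0.5, flagged but still averaged
  r2 <- mean_ct(c(21, 21, 24))
  expect_equal(r2$mean, 22)
  expect_true(r2$flagged)
  # one dropout: mean of the remaining two, flagged
  r3 <- mean_ct(c(21, NA, 22))
  expect_equal(r3$mean, 21.5)
  expect_true(r3$flagged)
  expect_identical(r3$n_used, 2L)
  expect_error(mean_ct(c(NA_real_, NA_real_)), "no-amplification")
})

test_that("calibrator selection: random known male, or latest-target putative male", {
  specimens <- data.frame(
    specimen_id = c("a", "b", "c", "d"),
    mean_ct_target = c(21, 21, 22, 21),
    mean_ct_reference = c(21, 21, 21, 21),
    known_sex = c("M", "M", "M", "F"),
    stringsAsFactors = FALSE
  )
  picks <- vapply(1:20, function(i) select_calibrator(specimens, seed = 7),
                  character(1))
  expect_length(unique(picks), 1L)  # reproducible under a fixed seed
  expect_true(unique(picks) %in% c("a", "b", "c"))
  varied <- vapply(1:50, function(i) select_calibrator(specimens, seed = i),
                   character(1))
  expect_true(all(varied %in% c("a", "b", "c")))  # never the female

  # unknown sexes: the specimen whose target lags the reference most
  unk <- specimens[, 1:3]
  expect_identical(select_calibrator(unk), "c")
  only_f <- data.frame(specimen_id = "x", mean_ct_target = 21,
                       mean_ct_reference = 21, known_sex = "F")
  expect_error(select_calibrator(only_f), "no-calibrator")
})

test_that("Pfaffl ratio: closed-form cases and monotonicity", {
  expect_equal(pfaffl_cnv(2, 2, 0, 0), 1)
  expect_equal(pfaffl_cnv(2, 2, 1, 0), 2)
  expect_equal(pfaffl_cnv(1.999, 1.992, 1.0, 0.05), 1.999 / 1.992^0.05,
               tolerance = 1e-12)
  expect_equal(round(pfaffl_cnv(1.999, 1.992, 1.0, 0.05), 4), 1.9313)
  # equal efficiencies reduce to E^(dCt_t - dCt_r)
  for (e in c(1.9, 2)) {
    expect_equal(pfaffl_cnv(e, e, 1.3, 0.4), e^(1.3 - 0.4), tolerance = 1e-12)
  }
  # strictly increasing in dCt_target, decreasing in dCt_reference
  grid <- seq(-2, 2, by = 0.5)
  expect_true(all(diff(pfaffl_cnv(2, 2, grid, 0)) > 0))
  expect_true(all(diff(pfaffl_cnv(2, 2, 0, grid)) < 0))
  expect_error(pfaffl_cnv(1, 2, 0, 0), "domain")
  expect_error(pfaffl_cnv(2, 2, NA, 0), "finite")
})

test_that("qPCR pipeline recovers exact copy numbers from a noise-free run", {
  cfg <- sim_config(n_individuals = 20, sd_tech = 0, sd_run = 0, seed = 5)
  cohort <- simulate_cohort(cfg)
  truth <- data.frame(specimen_id = cohort$specimen_id,
                      true_sex = cohort$true_sex)
  ct <- simulate_qpcr(cohort, cfg)
  res <- qpcr_pipeline(ct, ld_target_curve(), ld_reference_curve(),
                       known_sex = truth, seed = 9)
  expected <- ifelse(cohort$true_sex == "F", 2, 1)
  expect_equal(res$cnv[match(cohort$specimen_id, res$specimen_id)], expected,
               tolerance = 1e-9)
  # the calibrator is a male and self-relative at exactly 1
  cal <- unique(res$calibrator_id)
  expect_length(cal, 1)
  expect_identical(cohort$true_sex[cohort$specimen_id == cal], "M")
  expect_identical(res$cnv[res$specimen_id == cal], 1.0)
})

test_that("qPCR copy numbers are invariant to run offsets and DNA input", {
  base <- sim_config(n_individuals = 12, sd_tech = 0, sd_run = 0, seed = 21)
  cohort <- simulate_cohort(base)
  truth <- data.frame(specimen_id = cohort$specimen_id,
                      true_sex = cohort$true_sex)
  run_pipeline <- function(ct) {
    qpcr_pipeline(ct, ld_target_curve(), ld_reference_curve(),
                  known_sex = truth, seed = 2)$cnv
  }
  ct <- simulate_qpcr(cohort, base)
  ref <- run_pipeline(ct)
  # shifting every Ct of the run by a constant changes nothing
  shifted <- ct; shifted$ct <- shifted$ct + 3.7
  expect_equal(run_pipeline(shifted), ref, tolerance = 1e-9)
  # and the run-offset SD parameter has no effect at all
  noisy_run <- sim_config(n_individuals = 12, sd_tech = 0, sd_run = 5,
                          seed = 21)
  expect_equal(run_pipeline(simulate_qpcr(cohort, noisy_run)), ref,
               tolerance = 1e-9)
  # DNA input mass cancels in the calibrator-relative ratio
  for (ng in c(5, 20, 80)) {
    cfg_ng <- sim_config(n_individuals = 12, sd_tech = 0, sd_run = 0,
                         dna_input_ng = ng, seed = 21)
    expect_equal(run_pipeline(simulate_qpcr(cohort, cfg_ng)), ref,
                 tolerance = 1e-9)
  }
})

test_that("qPCR pipeline enforces the slope rule and reports broken input", {
  cfg <- sim_config(n_individuals = 6, sd_tech = 0, sd_run = 0, seed = 2)
  cohort <- simulate_cohort(cfg)
  ct <- simulate_qpcr(cohort, cfg)
  bad_ref <- cnvsex:::curve_from_params(-3.9, 36.5)
  expect_error(
    qpcr_pipeline(ct, ld_target_curve(), bad_ref, calibrator = cohort$specimen_id[1]),
    "slope-difference")
  expect_warning(
    qpcr_pipeline(ct, ld_target_curve(), bad_ref,
                  calibrator = cohort$specimen_id[1],
                  override_slope_check = TRUE),
    "override")
  # named calibrator absent from the run
  expect_error(
    qpcr_pipeline(ct, ld_target_curve(), ld_reference_curve(),
                  calibrator = "nope"),
    "no-calibrator")
  # a specimen missing one gene
  expect_error(
    qpcr_pipeline(ct[!(ct$specimen_id == cohort$specimen_id[2] &
                         ct$gene_role == "reference"), ],
                  ld_target_curve(), ld_reference_curve(),
                  calibrator = cohort$specimen_id[1]),
    "incomplete-specimen")
})
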