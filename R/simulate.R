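#' Simulation settings for synthetic qPCR / ddPCR cohorts
#'
#' Bundles the parameters of the forward model used to emulate two-gene
#' dosage measurements. Defaults describe a routine assay: standard curves
#' with near-perfect efficiencies (slopes -3.324 and -3.341, the fitted
#' target and reference curves of the shipped beetle assay), 20 ng DNA
#' input, technical triplicates, 0.15-cycle technical noise, 1-cycle run
#' offsets, and ~17,000 accepted droplets of 0.85 nL.
#'
#' @param n_individuals Cohort size.
#' @param female_fraction Probability an individual is female (default 0.5).
#' @param dna_input_ng DNA input per reaction (ng, default 20).
#' @param target_curve,reference_curve Length-2 vectors `(slope,
#'   y_intercept)` of the per-gene standard curves.
#' @param sd_tech SD of independent technical-replicate Ct noise (cycles).
#' @param sd_run SD of the additive run offset shared by all wells and both
#'   genes of one run (cycles).
#' @param n_runs Number of qPCR runs the cohort is split across.
#' @param n_tech_reps Technical replicates per specimen x gene (default 3).
#' @param n_bio_reps Biological replicates per specimen (default 1).
#' @param droplet_total Accepted droplets per ddPCR well (default 17,000).
#' @param droplet_volume_nl Droplet volume (default 0.85 nL).
#' @param copies_per_haploid ddPCR template concentration per haploid gene
#'   copy (copies/uL, default 300).
#' @param seed Integer seed; all generators are deterministic given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_individuals = 20, female_fraction = 0.5,
                       dna_input_ng = 20,
                       target_curve = c(slope = -3.324, y_intercept = 38.476),
                       reference_curve = c(slope = -3.341, y_intercept = 36.528),
                       sd_tech = 0.15, sd_run = 1.0, n_runs = 1,
                       n_tech_reps = 3, n_bio_reps = 1,
                       droplet_total = 17000, droplet_volume_nl = 0.85,
                       copies_per_haploid = 300, seed = 1) {
  stopifnot(n_individuals >= 1, female_fraction >= 0, female_fraction <= 1,
            dna_input_ng > 0, sd_tech >= 0, sd_run >= 0, n_runs >= 1,
            n_tech_reps >= 1, n_bio_reps >= 1, droplet_total >= 1,
            droplet_volume_nl > 0, copies_per_haploid > 0,
            target_curve[1] < 0, reference_curve[1] < 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a cohort of individuals with known sexes
#'
#' Sexes are drawn independently with `P(F) = female_fraction`; true gene
#' copy numbers follow the X0/XX dosage model (target: 2 in females, 1 in
#' males; reference: 2 in all). Individuals are assigned to `n_runs` runs in
#' contiguous blocks, mimicking plate layout.
#'
#' @param config A [sim_config()].
#' @return Data frame: `specimen_id`, `true_sex`, `copies_target`,
#'   `copies_reference`, `run_id`. Deterministic given `config$seed`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  sexes <- with_seed(config$seed, ifelse(
    runif(n) < config$female_fraction, "F", "M"))
  run_idx <- ceiling(seq_len(n) / ceiling(n / config$n_runs))
  data.frame(
    specimen_id = sprintf("S%04d", seq_len(n)),
    true_sex = sexes,
    copies_target = ifelse(sexes == "F", 2L, 1L),
    copies_reference = 2L,
    run_id = sprintf("run%02d", run_idx),
    stringsAsFactors = FALSE
  )
}

#' Simulate a qPCR Ct table for a cohort
#'
#' Forward model of calibrator-relative quantification:
#' `Ct = y_intercept + slope * log10(dna_input_ng * k / 2) + run_offset +
#' noise`, where `k` is the true copy number of the gene (so a single-copy
#' male's target amplifies `-slope * log10 2` (about 1) cycles later than a
#' female's), `run_offset ~ N(0, sd_run)` is shared by every well of a run,
#' and `noise ~ N(0, sd_tech)` is independent per technical replicate.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param config A [sim_config()].
#' @return Ct table: `specimen_id`, `gene_role`, `biological_replicate`,
#'   `technical_replicate`, `ct`, `run_id`. Deterministic given
#'   `config$seed`.
#' @export
simulate_qpcr <- function(cohort, config) {
  stopifnot(inherits(config, "sim_config"))
  grid <- expand.grid(
    technical_replicate = seq_len(config$n_tech_reps),
    biological_replicate = seq_len(config$n_bio_reps),
    gene_role = c("target", "reference"),
    specimen_id = cohort$specimen_id,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  idx <- match(grid$specimen_id, cohort$specimen_id)
  grid$run_id <- cohort$run_id[idx]
  k <- ifelse(grid$gene_role == "target",
              cohort$copies_target[idx], cohort$copies_reference[idx])
  slope <- ifelse(grid$gene_role == "target",
                  config$target_curve[1], config$reference_curve[1])
  intercept <- ifelse(grid$gene_role == "target",
                      config$target_curve[2], config$reference_curve[2])
  runs <- sort(unique(cohort$run_id))
  noise <- with_seed(config$seed + 1L, {
    offsets <- rnorm(length(runs), 0, config$sd_run)
    eps <- rnorm(nrow(grid), 0, config$sd_tech)
    list(offsets = offsets, eps = eps)
  })
  grid$ct <- intercept +
    slope * log10(config$dna_input_ng * k / 2) +
    noise$offsets[match(grid$run_id, runs)] +
    noise$eps
  grid[, c("specimen_id", "gene_role", "biological_replicate",
           "technical_replicate", "ct", "run_id")]
}

#' Simulate ddPCR droplet counts for a cohort
#'
#' For each specimen x gene, the true template concentration is
#' `copies_per_haploid * k` copies/uL; with droplet volume `v` the chance a
#' droplet holds no template is `exp(-c v)` (Poisson occupancy), and the
#' positive-droplet count is drawn binomially over `droplet_total` droplets.
#'
#' @inheritParams simulate_qpcr
#' @return Wells table: `specimen_id`, `gene_role`, `n_positive`,
#'   `n_negative`, `droplet_volume_nl`, `biological_replicate`.
#'   Deterministic given `config$seed`.
#' @export
simulate_ddpcr <- function(cohort, config) {
  stopifnot(inherits(config, "sim_config"))
  grid <- expand.grid(
    gene_role = c("target", "reference"),
    specimen_id = cohort$specimen_id,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  idx <- match(grid$specimen_id, cohort$specimen_id)
  k <- ifelse(grid$gene_role == "target",
              cohort$copies_target[idx], cohort$copies_reference[idx])
  conc <- config$copies_per_haploid * k
  lambda <- conc * config$droplet_volume_nl * 1e-3
  p_pos <- 1 - exp(-lambda)
  n_pos <- with_seed(config$seed + 2L,
                     rbinom(nrow(grid), config$droplet_total, p_pos))
  data.frame(
    specimen_id = grid$specimen_id,
    gene_role = grid$gene_role,
    n_positive = n_pos,
    n_negative = config$droplet_total - n_pos,
    droplet_volume_nl = config$droplet_volume_nl,
    biological_replicate = 1L,
    stringsAsFactors = FALSE
  )
}

# A standard_curve object from known (slope, y_intercept) parameters,
# bypassing the least-squares fit (r_squared = 1 by construction).
curve_from_params <- function(slope, y_intercept) {
  eff <- efficiency_from_slope(slope)
  structure(
    list(slope = unname(slope), y_intercept = unname(y_intercept),
         r_squared = 1.0,
         amplification_factor = eff$amplification_factor,
         efficiency_percent = eff$efficiency_percent),
    class = "standard_curve"
  )
}

#' Simulate-and-recover accuracy experiment
#'
#' Generates a cohort, runs the chosen quantification backend and the sex
#' caller, and compares calls with the simulated truth. Reports the fraction
#' of correct calls (ambiguous counts as incorrect), the phi association
#' coefficient, and CNV summaries per true sex. The qPCR branch selects a
#' random known male per run as calibrator, as in routine use.
#'
#' @param config A [sim_config()].
#' @param method `"qPCR"` or `"ddPCR"`.
#' @param threshold,band_halfwidth Passed to [call_cohort()].
#' @return List: `accuracy`, `phi`, `counts`, `summary` (per-true-sex mean /
#'   sd of estimated CNV), `results` (the `cnv_result` table), `cohort`.
#' @export
recovery_experiment <- function(config, method = c("qPCR", "ddPCR"),
                                threshold = 1.5, band_halfwidth = 0.5) {
  method <- match.arg(method)
  cohort <- simulate_cohort(config)
  truth <- data.frame(specimen_id = cohort$specimen_id,
                      true_sex = cohort$true_sex, stringsAsFactors = FALSE)
  if (method == "qPCR") {
    ct <- simulate_qpcr(cohort, config)
    results <- qpcr_pipeline(
      ct,
      curve_target = curve_from_params(config$target_curve[1],
                                       config$target_curve[2]),
      curve_reference = curve_from_params(config$reference_curve[1],
                                          config$reference_curve[2]),
      calibrator = "auto", known_sex = truth, seed = config$seed + 3L)
  } else {
    wells <- simulate_ddpcr(cohort, config)
    results <- ddpcr_pipeline(wells,
                              droplet_volume_nl = config$droplet_volume_nl,
                              min_droplets = 0)
  }
  cohort_calls <- call_cohort(results, threshold, band_halfwidth)
  calls <- cohort_calls$calls
  true_sex <- truth$true_sex[match(calls$specimen_id, truth$specimen_id)]
  accuracy <- mean(calls$predicted_sex == true_sex)
  a <- sum(true_sex == "F" & calls$predicted_sex == "F")
  b <- sum(true_sex == "F" & calls$predicted_sex == "M")
  cc <- sum(true_sex == "M" & calls$predicted_sex == "F")
  d <- sum(true_sex == "M" & calls$predicted_sex == "M")
  phi <- tryCatch(phi_coefficient(a, b, cc, d)$value, error = function(e) NA_real_)
  summary <- do.call(rbind, lapply(c("F", "M"), function(sx) {
    v <- results$cnv[truth$true_sex[match(results$specimen_id,
                                          truth$specimen_id)] == sx]
    if (length(v) < 2L) return(NULL)
    data.frame(true_sex = sx, n = length(v), mean = mean(v), sd = sd(v),
               stringsAsFactors = FALSE)
  }))
  list(accuracy = accuracy, phi = phi, counts = cohort_calls$counts,
       summary = summary, results = results, cohort = cohort)
}
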