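#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10 input DNA mass over a dilution
#' series. The slope of this line determines the amplification efficiency:
#' a perfectly doubling reaction has slope `-1/log10(2) = -3.3219` (one
#' extra cycle per halving of input).
#'
#' @param input_ng Input DNA masses of the dilution series (ng), all > 0.
#' @param ct Measured Ct values, same length.
#' @return Object of class `standard_curve` with fields `slope`,
#'   `y_intercept`, `r_squared`, `amplification_factor`
#'   (`10^(-1/slope)`, the per-cycle multiplication factor E) and
#'   `efficiency_percent` (`(E - 1) * 100`).
#' @export
#' @examples
#' m <- c(20, 10, 5, 2.5, 1.25)
#' fit_standard_curve(m, 38.476 - 3.324 * log10(m))  # E = 99.9%
fit_standard_curve <- function(input_ng, ct) {
  input_ng <- as.numeric(input_ng)
  ct <- as.numeric(ct)
  stopifnot(length(input_ng) == length(ct))
  if (any(input_ng <= 0)) {
    stop("domain error: input masses must be positive", call. = FALSE)
  }
  if (length(unique(input_ng)) < 2L) {
    stop("underdetermined-fit error: need >= 2 distinct input masses",
         call. = FALSE)
  }
  x <- log10(input_ng)
  fit <- stats::lm(ct ~ x)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    stop("fitted slope is non-negative; Ct must decrease with input",
         call. = FALSE)
  }
  # noise-free series are legitimate input; silence lm's perfect-fit notice
  r2 <- if (length(ct) == 2L) 1.0 else suppressWarnings(summary(fit)$r.squared)
  eff <- efficiency_from_slope(slope)
  structure(
    list(slope = slope, y_intercept = unname(coef(fit)[1]), r_squared = r2,
         amplification_factor = eff$amplification_factor,
         efficiency_percent = eff$efficiency_percent),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> slope %.3f, y-int %.3f, R2 %.3f, E = %.1f%% (factor %.4f)\n",
    x$slope, x$y_intercept, x$r_squared, x$efficiency_percent,
    x$amplification_factor))
  invisible(x)
}

#' Amplification efficiency from a standard-curve slope
#'
#' `E = 10^(-1/slope)` is the per-cycle template multiplication factor (2 for
#' a perfect reaction); the conventional percent efficiency is
#' `(E - 1) * 100`.
#'
#' @param slope Standard-curve slope (cycles per log10 input), must be < 0.
#' @return List with `amplification_factor` and `efficiency_percent`.
#' @export
#' @examples
#' efficiency_from_slope(-3.324)  # 99.9%
efficiency_from_slope <- function(slope) {
  if (!is.finite(slope) || slope >= 0) {
    stop("domain error: slope must be negative and finite", call. = FALSE)
  }
  af <- 10^(-1 / slope)
  list(amplification_factor = af, efficiency_percent = (af - 1) * 100)
}

#' Slope-difference (Larionov) rule for raw-Ct quantification
#'
#' Relative quantification from raw Ct values is admissible when the target
#' and reference standard-curve slopes differ by at most `tolerance` in
#' absolute value, i.e. the two amplification efficiencies are comparable.
#'
#' @param curve_target,curve_reference `standard_curve` objects (or bare
#'   numeric slopes).
#' @param tolerance Maximum admissible absolute slope difference (default
#'   0.1).
#' @return List with `difference` (absolute slope difference) and `pass`.
#' @export
validate_slope_difference <- function(curve_target, curve_reference,
                                      tolerance = 0.1) {
  s_t <- if (inherits(curve_target, "standard_curve")) curve_target$slope else curve_target
  s_r <- if (inherits(curve_reference, "standard_curve")) curve_reference$slope else curve_reference
  stopifnot(is.finite(s_t), is.finite(s_r))
  d <- abs(s_t - s_r)
  list(difference = d, pass = d <= tolerance)
}

#' Aggregate technical replicates of one specimen x gene
#'
#' Arithmetic mean of the non-missing Ct values. The result is flagged when
#' the replicate spread exceeds `sd_limit` cycles or when any replicate
#' failed to amplify (missing Ct): either situation warrants inspection,
#' though the mean of the remaining replicates is still used.
#'
#' @param ct Numeric vector of technical-replicate Ct values; `NA` = no
#'   amplification.
#' @param sd_limit Replicate standard deviation (cycles) above which the
#'   aggregate is flagged. Default 0.5.
#' @return List with `mean`, `sd`, `n_used`, `flagged`.
#' @export
#' @examples
#' mean_ct(c(21.0, 21.0, 24.0))  # mean 22, flagged (sd = sqrt(3))
mean_ct <- function(ct, sd_limit = 0.5) {
  ct <- as.numeric(ct)
  ok <- !is.na(ct)
  if (!any(ok)) {
    stop("no-amplification error: all technical replicates missing",
         call. = FALSE)
  }
  used <- ct[ok]
  s <- if (length(used) > 1L) sd(used) else 0
  list(mean = mean(used), sd = s, n_used = length(used),
       flagged = (s > sd_limit) || any(!ok))
}

#' Choose the run calibrator
#'
#' Calibrator-relative quantification needs one male per run: relative to a
#' single-copy male, the ratio computed by [pfaffl_cnv()] is directly the
#' target-gene copy number. When sexes are known, a male is drawn uniformly
#' at random (reproducible under `seed`). When they are not (larvae), the
#' putative male is the specimen maximising
#' `mean Ct(target) - mean Ct(reference)`: with one target copy instead of
#' two, the target amplifies about one cycle later.
#'
#' @param specimens Data frame with columns `specimen_id`,
#'   `mean_ct_target`, `mean_ct_reference`, and optionally `known_sex`
#'   (`"F"`/`"M"`/`NA`).
#' @param seed Integer seed for the random draw among known males.
#' @return The chosen calibrator `specimen_id` (character scalar).
#' @export
select_calibrator <- function(specimens, seed = NULL) {
  stopifnot(nrow(specimens) >= 1L)
  if (!is.null(specimens$known_sex) && any(!is.na(specimens$known_sex))) {
    males <- specimens$specimen_id[!is.na(specimens$known_sex) &
                                     specimens$known_sex == "M"]
    if (!length(males)) {
      stop("no-calibrator error: sexes known but no male in run",
           call. = FALSE)
    }
    if (length(males) == 1L) return(as.character(males))
    if (!is.null(seed)) {
      return(as.character(with_seed(seed, sample(males, 1L))))
    }
    return(as.character(sample(males, 1L)))
  }
  dct <- specimens$mean_ct_target - specimens$mean_ct_reference
  as.character(specimens$specimen_id[which.max(dct)])
}

#' Efficiency-corrected relative copy number (Pfaffl ratio)
#'
#' `CNV = E_target^dCt_target / E_reference^dCt_reference`, where each
#' `dCt = mean Ct(calibrator) - mean Ct(sample)` for that gene and `E` is the
#' gene's amplification factor (about 2). With a single-copy male calibrator
#' the ratio equals the absolute target-gene copy number: 1 in males, 2 in
#' females.
#'
#' @param e_target,e_reference Amplification factors (> 1), not percents.
#' @param delta_ct_target,delta_ct_reference Calibrator-minus-sample mean-Ct
#'   differences per gene (cycles); vectorised.
#' @return Numeric copy number value(s).
#' @export
#' @examples
#' pfaffl_cnv(2, 2, 1, 0)  # 2: target amplifies one cycle before calibrator
pfaffl_cnv <- function(e_target, e_reference, delta_ct_target,
                       delta_ct_reference) {
  if (any(e_target <= 1) || any(e_reference <= 1)) {
    stop("domain error: amplification factors must exceed 1", call. = FALSE)
  }
  if (any(!is.finite(delta_ct_target)) || any(!is.finite(delta_ct_reference))) {
    stop("delta Ct values must be finite", call. = FALSE)
  }
  e_target^delta_ct_target / e_reference^delta_ct_reference
}

#' qPCR pipeline: Ct table to per-specimen copy number values
#'
#' End-to-end calibrator-relative quantification. Per run and biological
#' replicate: technical replicates are aggregated with [mean_ct()], a
#' calibrator is chosen (explicitly, or by the [select_calibrator()] policy),
#' per-gene calibrator-minus-sample Ct differences are formed, and the copy
#' number follows from [pfaffl_cnv()]. Because the calibrator is measured on
#' the same run, any additive run offset common to both genes cancels.
#'
#' @param ct_table Data frame of technical-replicate rows with columns
#'   `specimen_id`, `gene_role`, `biological_replicate`,
#'   `technical_replicate`, `ct` (NA = no amplification), `run_id`.
#' @param curve_target,curve_reference `standard_curve` objects supplying
#'   the amplification factors.
#' @param calibrator `"auto"` (policy-based per run) or a specimen id.
#' @param known_sex Optional data frame `specimen_id`, `true_sex` used by
#'   the auto policy to draw a random male.
#' @param seed Integer seed for the random-male draw.
#' @param sd_limit Technical-replicate SD flag threshold, see [mean_ct()].
#' @param override_slope_check If `TRUE`, proceed even when the
#'   slope-difference rule fails (a warning is emitted).
#' @return Data frame of class `cnv_result`: `specimen_id`, `method`
#'   (`"qPCR"`), `biological_replicate`, `cnv`, `calibrator_id`, `run_id`,
#'   `flagged` (technical-replicate QC flag on either gene).
#' @export
qpcr_pipeline <- function(ct_table, curve_target, curve_reference,
                          calibrator = "auto", known_sex = NULL, seed = NULL,
                          sd_limit = 0.5, override_slope_check = FALSE) {
  required <- c("specimen_id", "gene_role", "biological_replicate",
                "technical_replicate", "ct", "run_id")
  missing_cols <- setdiff(required, names(ct_table))
  if (length(missing_cols)) {
    stop("ct table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(ct_table)) stop("ct table is empty", call. = FALSE)
  slope_check <- validate_slope_difference(curve_target, curve_reference)
  if (!slope_check$pass) {
    if (!override_slope_check) {
      stop(sprintf(
        "slope-difference rule failed (|difference| = %.3f > 0.1); raw-Ct quantification not admissible",
        slope_check$difference), call. = FALSE)
    }
    warning("slope-difference rule failed; proceeding on explicit override")
  }
  e_t <- curve_target$amplification_factor
  e_r <- curve_reference$amplification_factor

  runs <- sort(unique(ct_table$run_id))
  out <- list()
  for (i in seq_along(runs)) {
    run <- ct_table[ct_table$run_id == runs[i], , drop = FALSE]
    # per specimen x bio rep x gene technical-replicate aggregation
    key <- interaction(run$specimen_id, run$biological_replicate,
                       run$gene_role, drop = TRUE)
    agg <- lapply(split(run, key), function(grp) {
      m <- tryCatch(mean_ct(grp$ct, sd_limit = sd_limit), error = function(e) {
        stop(sprintf("specimen '%s', gene %s: %s", grp$specimen_id[1],
                     grp$gene_role[1], conditionMessage(e)), call. = FALSE)
      })
      data.frame(specimen_id = grp$specimen_id[1],
                 biological_replicate = grp$biological_replicate[1],
                 gene_role = grp$gene_role[1],
                 mean_ct = m$mean, flagged = m$flagged,
                 stringsAsFactors = FALSE)
    })
    agg <- do.call(rbind, agg)

    wide <- merge(
      agg[agg$gene_role == "target",
          c("specimen_id", "biological_replicate", "mean_ct", "flagged")],
      agg[agg$gene_role == "reference",
          c("specimen_id", "biological_replicate", "mean_ct", "flagged")],
      by = c("specimen_id", "biological_replicate"),
      suffixes = c("_target", "_reference"), all = TRUE
    )
    if (anyNA(wide$mean_ct_target) || anyNA(wide$mean_ct_reference)) {
      bad <- wide$specimen_id[is.na(wide$mean_ct_target) |
                                is.na(wide$mean_ct_reference)]
      stop(sprintf(
        "incomplete-specimen error in run '%s': missing one gene for %s",
        runs[i], paste(unique(bad), collapse = ", ")), call. = FALSE)
    }

    if (identical(calibrator, "auto")) {
      per_spec <- stats::aggregate(
        cbind(mean_ct_target, mean_ct_reference) ~ specimen_id,
        data = wide, FUN = mean)
      if (!is.null(known_sex)) {
        per_spec$known_sex <- known_sex$true_sex[
          match(per_spec$specimen_id, known_sex$specimen_id)]
      }
      run_seed <- if (is.null(seed)) NULL else seed + i
      cal_id <- select_calibrator(per_spec, seed = run_seed)
    } else {
      cal_id <- as.character(calibrator)
      if (!cal_id %in% wide$specimen_id) {
        stop(sprintf("no-calibrator error: '%s' not measured in run '%s'",
                     cal_id, runs[i]), call. = FALSE)
      }
    }

    for (rep_id in sort(unique(wide$biological_replicate))) {
      w <- wide[wide$biological_replicate == rep_id, , drop = FALSE]
      cal <- w[w$specimen_id == cal_id, , drop = FALSE]
      if (!nrow(cal)) {
        stop(sprintf(
          "no-calibrator error: calibrator '%s' missing from replicate %s of run '%s'",
          cal_id, rep_id, runs[i]), call. = FALSE)
      }
      cnv <- pfaffl_cnv(e_t, e_r,
                        cal$mean_ct_target - w$mean_ct_target,
                        cal$mean_ct_reference - w$mean_ct_reference)
      cnv[w$specimen_id == cal_id] <- 1.0  # self-relative by definition
      out[[length(out) + 1L]] <- data.frame(
        specimen_id = w$specimen_id, method = "qPCR",
        biological_replicate = rep_id, cnv = cnv,
        calibrator_id = cal_id, run_id = runs[i],
        flagged = w$flagged_target | w$flagged_reference,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$specimen_id, res$biological_replicate), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("cnv_result", class(res))
  res
}

# Evaluate an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
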