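#' Descriptive summary of a set of copy number values
#'
#' The summary reported per sex and collection: sample size, mean, sample
#' standard deviation, t-based 95% confidence half-width
#' (`t(0.975, n-1) * sd / sqrt(n)`), minimum, maximum, and coefficient of
#' variation (`sd / mean`).
#'
#' @param values Numeric vector, `n >= 2`.
#' @return One-row data frame: `n`, `mean`, `sd`, `ci95_halfwidth`, `min`,
#'   `max`, `cv`.
#' @export
descriptive_summary <- function(values) {
  values <- as.numeric(values[!is.na(values)])
  n <- length(values)
  if (n < 2L) stop("insufficient-data error: need n >= 2", call. = FALSE)
  m <- mean(values)
  s <- sd(values)
  data.frame(n = n, mean = m, sd = s,
             ci95_halfwidth = qt(0.975, n - 1) * s / sqrt(n),
             min = min(values), max = max(values), cv = s / m)
}

#' Bimodality amplitude of a copy number distribution
#'
#' A fixed-width histogram statistic quantifying the separation of two
#' modes: with `A_s` the count of the smaller of the two highest local
#' maxima and `A_v` the minimum bin count between those two peaks,
#' `BA = (A_s - A_v) / A_s`. BA is 1 when the valley between the modes is
#' empty and 0 when the histogram has fewer than two local maxima. For a
#' sexing assay the two modes are the male (CNV = 1) and female (CNV = 2)
#' clusters; BA > 0 is a qualitative prerequisite for threshold calling.
#'
#' @param values Numeric vector, `n >= 4`.
#' @param bin_width Histogram bin width (default 0.1 copy number units).
#' @param range Histogram range as `c(lo, hi)` (default `c(0, 3)`); values
#'   outside are clamped into the terminal bins.
#' @return List with `ba`, `peak_bins` (indices of the two peaks), and
#'   `counts` (the histogram).
#' @export
bimodality_amplitude <- function(values, bin_width = 0.1, range = c(0, 3)) {
  values <- as.numeric(values[!is.na(values)])
  if (length(values) < 4L) {
    stop("insufficient-data error: need n >= 4", call. = FALSE)
  }
  breaks <- seq(range[1], range[2], by = bin_width)
  if (breaks[length(breaks)] < range[2]) breaks <- c(breaks, range[2])
  clamped <- pmin(pmax(values, range[1]), range[2])
  counts <- graphics::hist(clamped, breaks = breaks, plot = FALSE,
                           include.lowest = TRUE, right = FALSE)$counts
  k <- length(counts)
  # local maxima: bins strictly above the previous differing neighbour and
  # at least as high as the next (plateaus count once, at their left edge)
  padded <- c(-Inf, counts, -Inf)
  is_peak <- vapply(seq_len(k), function(i) {
    padded[i] < padded[i + 1] && padded[i + 1] >= padded[i + 2]
  }, logical(1))
  peaks <- which(is_peak & counts > 0)
  if (length(peaks) < 2L) {
    return(list(ba = 0, peak_bins = peaks, counts = counts))
  }
  top2 <- peaks[order(counts[peaks], decreasing = TRUE)[1:2]]
  top2 <- sort(top2)
  a_s <- min(counts[top2])
  a_v <- min(counts[(top2[1] + 1):(top2[2] - 1)])
  list(ba = (a_s - a_v) / a_s, peak_bins = top2, counts = counts)
}

#' Paired t-test on biological replicates
#'
#' Tests whether the mean copy number differs between two biological
#' replicates of the same specimens (e.g. DNA extracted from different
#' tissues): `t = mean(d) / (sd(d) / sqrt(n))` on the per-specimen
#' differences `d = rep1 - rep2`, `df = n - 1`, two-sided p-value.
#' Delegates to [stats::t.test()].
#'
#' @param rep1,rep2 Equal-length numeric vectors, paired by specimen.
#' @return Data frame: `statistic_name` (`"t_paired"`), `value`, `df`,
#'   `p_value`.
#' @export
paired_t <- function(rep1, rep2) {
  stopifnot(length(rep1) == length(rep2), length(rep1) >= 2L)
  d <- rep1 - rep2
  if (sd(d) == 0) {
    stop("degenerate-test error: zero variance of replicate differences",
         call. = FALSE)
  }
  tt <- t.test(rep1, rep2, paired = TRUE)
  data.frame(statistic_name = "t_paired", value = unname(tt$statistic),
             df = unname(tt$parameter), p_value = tt$p.value,
             stringsAsFactors = FALSE)
}

#' Shapiro-Wilk normality test
#'
#' Normality of replicate differences is the prerequisite for the paired
#' t-test. Delegates to [stats::shapiro.test()] (Royston's AS R94
#' approximation).
#'
#' @param values Numeric vector, `3 <= n <= 5000`.
#' @return Data frame: `statistic_name` (`"W_shapiro"`), `value`, `p_value`.
#' @export
shapiro_wilk <- function(values) {
  values <- as.numeric(values[!is.na(values)])
  if (length(values) < 3L) {
    stop("insufficient-data error: Shapiro-Wilk needs n >= 3", call. = FALSE)
  }
  sw <- shapiro.test(values)
  data.frame(statistic_name = "W_shapiro", value = unname(sw$statistic),
             df = NA_real_, p_value = sw$p.value, stringsAsFactors = FALSE)
}

#' Phi association coefficient for a 2x2 confusion table
#'
#' `phi = (ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d))` for the table of true sex
#' against called sex; +1 is perfect association. The p-value derives from
#' `chi2 = n * phi^2` with one degree of freedom.
#'
#' @param a,b,c,d Counts: `a` = true F called F, `b` = true F called M,
#'   `c` = true M called F, `d` = true M called M.
#' @return Data frame: `statistic_name` (`"phi"`), `value`, `df`, `p_value`.
#' @export
#' @examples
#' phi_coefficient(234, 0, 0, 214)  # phi = 1
phi_coefficient <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    stop("undefined-association error: a table margin is zero", call. = FALSE)
  }
  phi <- (a * d - b * c) / sqrt(prod(margins))
  n <- sum(counts)
  chi2 <- n * phi^2
  data.frame(statistic_name = "phi", value = phi, df = 1,
             p_value = pchisq(chi2, df = 1, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Chi-square goodness of fit against a 1:1 sex ratio
#'
#' Pearson's uncorrected statistic `sum((obs - exp)^2 / exp)` with expected
#' counts `(n_f + n_m) / 2` each and one degree of freedom. Delegates to
#' [stats::chisq.test()] without continuity correction.
#'
#' @param n_f,n_m Observed female and male counts.
#' @return Data frame: `statistic_name` (`"chi2_gof"`), `value`, `df`,
#'   `p_value`.
#' @export
#' @examples
#' chi_square_1to1(30, 20)  # chi2 = 2
chi_square_1to1 <- function(n_f, n_m) {
  stopifnot(n_f >= 0, n_m >= 0, n_f + n_m >= 1)
  ct <- suppressWarnings(
    stats::chisq.test(c(n_f, n_m), p = c(0.5, 0.5), correct = FALSE))
  data.frame(statistic_name = "chi2_gof", value = unname(ct$statistic),
             df = unname(ct$parameter), p_value = ct$p.value,
             stringsAsFactors = FALSE)
}

#' Validation battery for a cohort of CNV results
#'
#' Convenience orchestrator producing, from a `cnv_result` table (and
#' optionally known sexes), the full set of assay-validation statistics:
#' bimodality amplitude of all values, a paired t-test and Shapiro-Wilk
#' normality of replicate differences (when two biological replicates are
#' present), the phi association with known sexes, a chi-square test of the
#' called sex ratio against 1:1, and descriptive summaries per called sex.
#'
#' @param results `cnv_result` data frame for one method.
#' @param truth Optional data frame `specimen_id`, `true_sex`.
#' @param threshold,band_halfwidth Passed to [call_cohort()].
#' @return List with `stats` (stacked StatResult rows), `summaries` (one
#'   [descriptive_summary()] row per called sex, over per-specimen mean
#'   CNVs), `calls`, and `counts`.
#' @export
validate_cohort <- function(results, truth = NULL, threshold = 1.5,
                            band_halfwidth = 0.5) {
  stats_rows <- list()
  ba <- bimodality_amplitude(results$cnv)
  stats_rows$ba <- data.frame(statistic_name = "BA", value = ba$ba,
                              df = NA_real_, p_value = NA_real_,
                              stringsAsFactors = FALSE)

  if (!is.null(results$biological_replicate) &&
      length(unique(results$biological_replicate)) == 2L) {
    reps <- sort(unique(results$biological_replicate))
    r1 <- results[results$biological_replicate == reps[1], ]
    r2 <- results[results$biological_replicate == reps[2], ]
    shared <- intersect(r1$specimen_id, r2$specimen_id)
    v1 <- r1$cnv[match(shared, r1$specimen_id)]
    v2 <- r2$cnv[match(shared, r2$specimen_id)]
    stats_rows$t <- paired_t(v1, v2)
    stats_rows$w <- shapiro_wilk(v1 - v2)
  }

  cohort <- call_cohort(results, threshold, band_halfwidth)
  calls <- cohort$calls

  if (!is.null(truth)) {
    truth_sex <- truth$true_sex[match(calls$specimen_id, truth$specimen_id)]
    a <- sum(truth_sex == "F" & calls$predicted_sex == "F", na.rm = TRUE)
    b <- sum(truth_sex == "F" & calls$predicted_sex == "M", na.rm = TRUE)
    cc <- sum(truth_sex == "M" & calls$predicted_sex == "F", na.rm = TRUE)
    d <- sum(truth_sex == "M" & calls$predicted_sex == "M", na.rm = TRUE)
    stats_rows$phi <- phi_coefficient(a, b, cc, d)
  }

  stats_rows$chi2 <- chi_square_1to1(cohort$counts["F"], cohort$counts["M"])

  summaries <- lapply(c(F = "F", M = "M"), function(sx) {
    vals <- calls$cnv[calls$predicted_sex == sx]
    if (length(vals) >= 2L) descriptive_summary(vals) else NULL
  })
  summaries <- do.call(rbind, Filter(Negate(is.null), summaries))
  if (!is.null(summaries)) {
    summaries <- cbind(sex = rownames(summaries), summaries)
    rownames(summaries) <- NULL
  }

  stats <- do.call(rbind, stats_rows)
  rownames(stats) <- NULL
  list(stats = stats, summaries = summaries, calls = calls,
       counts = cohort$counts)
}
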