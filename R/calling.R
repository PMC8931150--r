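#' Call sex from a copy number value
#'
#' For an X-linked target the expected copy number is 2 in females (XX) and
#' 1 in males (X0); the decision boundary defaults to the midpoint 1.5.
#' Values above the threshold are called female, below male, and exactly at
#' the threshold ambiguous. `in_band` records whether the value lies within
#' `band_halfwidth` of the expected copy number for the call; out-of-band
#' values keep their call but are flagged for inspection.
#'
#' @param cnv Copy number value(s), non-negative; vectorised.
#' @param threshold Decision boundary (default 1.5).
#' @param band_halfwidth Half-width of the expected band around 1 or 2
#'   (default 0.5).
#' @param method Optional method label carried into the output.
#' @return Data frame with `cnv`, `predicted_sex` (`"F"`/`"M"`/
#'   `"ambiguous"`), `in_band`, `method`.
#' @export
#' @examples
#' call_sex(c(1.973, 0.989, 0.320, 1.5))
call_sex <- function(cnv, threshold = 1.5, band_halfwidth = 0.5,
                     method = NA_character_) {
  cnv <- as.numeric(cnv)
  if (any(cnv < 0, na.rm = TRUE)) {
    stop("domain error: copy number values must be non-negative",
         call. = FALSE)
  }
  sex <- ifelse(cnv > threshold, "F", ifelse(cnv < threshold, "M",
                                             "ambiguous"))
  expected <- ifelse(sex == "F", 2, 1)
  in_band <- sex != "ambiguous" & abs(cnv - expected) <= band_halfwidth
  data.frame(cnv = cnv, predicted_sex = sex, in_band = in_band,
             method = method, stringsAsFactors = FALSE)
}

#' Call sexes for a cohort of CNV results
#'
#' One call per specimen (and method). Biological replicates must agree:
#' specimens whose replicates fall on opposite sides of the threshold are
#' called ambiguous with a conflict flag rather than resolved by vote —
#' the conservative choice for a diagnostic assay. The per-specimen `cnv`
#' reported is the mean over its replicates.
#'
#' @param results A `cnv_result` data frame (columns `specimen_id`, `cnv`,
#'   optionally `method`, `biological_replicate`).
#' @inheritParams call_sex
#' @return List with `calls` (one row per specimen x method: `specimen_id`,
#'   `method`, `cnv`, `predicted_sex`, `in_band`, `conflict`) and `counts`
#'   (named vector of F/M/ambiguous).
#' @export
call_cohort <- function(results, threshold = 1.5, band_halfwidth = 0.5) {
  stopifnot(nrow(results) >= 1L, !is.null(results$specimen_id),
            !is.null(results$cnv))
  method <- if (is.null(results$method)) rep(NA_character_, nrow(results)) else as.character(results$method)
  method_key <- ifelse(is.na(method), "", method)
  key <- interaction(results$specimen_id, method_key, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(results)), key), function(idx) {
    cnvs <- results$cnv[idx]
    reps <- call_sex(cnvs, threshold, band_halfwidth)
    conflict <- length(unique(reps$predicted_sex)) > 1L
    mean_cnv <- mean(cnvs)
    if (conflict) {
      call <- data.frame(cnv = mean_cnv, predicted_sex = "ambiguous",
                         in_band = FALSE, stringsAsFactors = FALSE)
    } else {
      call <- call_sex(mean_cnv, threshold, band_halfwidth)[
        , c("cnv", "predicted_sex", "in_band")]
    }
    data.frame(specimen_id = as.character(results$specimen_id[idx[1]]),
               method = method[idx[1]],
               call, conflict = conflict, stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  calls <- calls[order(calls$specimen_id), , drop = FALSE]
  rownames(calls) <- NULL
  counts <- c(F = sum(calls$predicted_sex == "F"),
              M = sum(calls$predicted_sex == "M"),
              ambiguous = sum(calls$predicted_sex == "ambiguous"))
  list(calls = calls, counts = counts)
}
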