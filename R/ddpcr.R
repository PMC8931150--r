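#' Template concentration from droplet counts by Poisson inversion
#'
#' In droplet digital PCR the reaction is partitioned into thousands of
#' droplets; template molecules distribute over droplets approximately as a
#' Poisson process, so the fraction of *negative* (empty) droplets estimates
#' `exp(-lambda)`, where `lambda` is the mean number of template copies per
#' droplet. Inverting gives `lambda = -ln(n_negative / n_total)` and the
#' concentration `lambda / droplet volume`.
#'
#' @param n_positive,n_negative Counts of positive and negative droplets
#'   (vectorised; equal lengths or length 1).
#' @param droplet_volume_nl Droplet volume in nanolitres. Default 0.85 nL, a
#'   common vendor partition volume; reported concentrations scale inversely
#'   with this constant.
#' @return A data frame with columns `lambda` (mean copies per droplet) and
#'   `copies_per_ul` (template copies per microlitre).
#' @export
#' @examples
#' poisson_concentration(8500, 8500)  # lambda = ln 2, ~815.5 copies/uL
poisson_concentration <- function(n_positive, n_negative,
                                  droplet_volume_nl = 0.85) {
  n_positive <- as.numeric(n_positive)
  n_negative <- as.numeric(n_negative)
  stopifnot(droplet_volume_nl > 0)
  if (any(n_positive < 0) || any(n_negative < 0)) {
    stop("droplet counts must be non-negative", call. = FALSE)
  }
  total <- n_positive + n_negative
  if (any(total == 0)) {
    stop("empty-well error: no accepted droplets", call. = FALSE)
  }
  if (any(n_negative == 0)) {
    stop("saturation error: no negative droplets, concentration not estimable",
         call. = FALSE)
  }
  lambda <- -log(n_negative / total)
  data.frame(lambda = lambda,
             copies_per_ul = lambda / (droplet_volume_nl * 1e-3))
}

#' Target-gene copy number from ddPCR concentrations
#'
#' The copy number of the X-linked target per diploid genome is twice the
#' ratio of target to reference concentration, because the autosomal
#' reference is present in two copies in every individual:
#' `CNV = 2 * c(target) / c(reference)`. Females (XX) are expected near 2,
#' males (X0) near 1.
#'
#' @param c_target,c_reference Template concentrations (copies per
#'   microlitre) of the target and reference gene; vectorised. Any common
#'   scale factor (droplet volume, dilution) cancels.
#' @param reference_name Gene name used in the error message when the
#'   reference concentration is zero.
#' @return Numeric copy number value(s).
#' @export
cnv_ddpcr <- function(c_target, c_reference, reference_name = "reference") {
  if (any(c_target < 0) || any(c_reference < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (any(c_reference <= 0)) {
    stop(sprintf(
      "division error: zero concentration for reference gene '%s'",
      reference_name), call. = FALSE)
  }
  2 * c_target / c_reference
}

#' ddPCR pipeline: wells to per-specimen copy number values
#'
#' Groups wells by specimen and biological replicate, applies the accepted-
#' droplet QC filter, converts counts to concentrations by
#' [poisson_concentration()], and computes the copy number by [cnv_ddpcr()].
#' When a specimen has several wells per gene (after QC) their estimated
#' concentrations are averaged.
#'
#' @param wells Data frame with columns `specimen_id`, `gene_role`
#'   (`"target"`/`"reference"`), `n_positive`, `n_negative`, and optionally
#'   `biological_replicate` (default 1) and `droplet_volume_nl`.
#' @param droplet_volume_nl Default droplet volume for wells that do not
#'   carry their own.
#' @param min_droplets Wells with fewer accepted droplets than this are
#'   excluded and listed in the `excluded_wells` attribute of the result.
#'   Default 10,000; routine runs accept ~15,000-20,000 droplets per well.
#' @return Data frame of class `cnv_result` with columns `specimen_id`,
#'   `method` (`"ddPCR"`), `biological_replicate`, `cnv`; attribute
#'   `excluded_wells` holds the QC-failed rows.
#' @export
ddpcr_pipeline <- function(wells, droplet_volume_nl = 0.85,
                           min_droplets = 10000) {
  required <- c("specimen_id", "gene_role", "n_positive", "n_negative")
  missing_cols <- setdiff(required, names(wells))
  if (length(missing_cols)) {
    stop("wells table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(wells)) stop("wells table is empty", call. = FALSE)
  if (is.null(wells$biological_replicate)) wells$biological_replicate <- 1L
  if (is.null(wells$droplet_volume_nl)) {
    wells$droplet_volume_nl <- droplet_volume_nl
  }
  total <- wells$n_positive + wells$n_negative
  keep <- total >= min_droplets
  excluded <- wells[!keep, , drop = FALSE]
  wells <- wells[keep, , drop = FALSE]
  if (!nrow(wells)) {
    stop("all wells failed the accepted-droplet QC threshold", call. = FALSE)
  }

  key <- interaction(wells$specimen_id, wells$biological_replicate,
                     drop = TRUE)
  pieces <- lapply(split(wells, key), function(grp) {
    for (role in c("target", "reference")) {
      if (!any(grp$gene_role == role)) {
        stop(sprintf(
          "incomplete-specimen error: specimen '%s' (replicate %s) has no %s well",
          grp$specimen_id[1], grp$biological_replicate[1], role),
          call. = FALSE)
      }
    }
    conc <- poisson_concentration(grp$n_positive, grp$n_negative,
                                  grp$droplet_volume_nl)
    c_t <- mean(conc$copies_per_ul[grp$gene_role == "target"])
    c_r <- mean(conc$copies_per_ul[grp$gene_role == "reference"])
    data.frame(
      specimen_id = grp$specimen_id[1],
      method = "ddPCR",
      biological_replicate = grp$biological_replicate[1],
      cnv = cnv_ddpcr(c_t, c_r),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$specimen_id, out$biological_replicate), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cnv_result", class(out))
  attr(out, "excluded_wells") <- excluded
  out
}
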