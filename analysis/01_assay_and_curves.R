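#!/usr/bin/env Rscript
# Step 1 — assay geometry and qPCR standard curves.
#
# Validates the shipped two-gene marker panel (X-linked LdVssc target,
# autosomal LdUBE3B reference), exports the primers as FASTA, refits the
# standard curves from the published dilution-series lines, and checks the
# slope-difference (Larionov) rule that licenses raw-Ct quantification.

library(cnvsex)
dir.create("results", showWarnings = FALSE)

assays <- ld_assays()
cat("Assay panel:\n")
for (a in assays) {
  print(a)
  v <- validate_assay(a)
  cat(if (length(v)) paste("  VIOLATIONS:", paste(v, collapse = "; "))
      else "  definition valid", "\n")
}
write_primer_fasta(assays, "results/primers.fasta")

geometry <- data.frame(
  gene = vapply(assays, `[[`, character(1), "gene_name"),
  role = vapply(assays, `[[`, character(1), "role"),
  amplicon_bp = vapply(assays, function(a)
    amplicon_length(a$forward_span[1], a$reverse_span[2]), integer(1))
)
cat("\nAmplicon sizes (bp):\n"); print(geometry, row.names = FALSE)

# Dilution series 20 .. 1.25 ng on the published fitted lines; the least-
# squares refit recovers slope, intercept and efficiency exactly.
masses <- c(20, 10, 5, 2.5, 1.25)
curve_t <- fit_standard_curve(masses, 38.476 - 3.324 * log10(masses))
curve_r <- fit_standard_curve(masses, 36.528 - 3.341 * log10(masses))
cat("\nStandard curves:\n  target:    "); print(curve_t)
cat("  reference: "); print(curve_r)

rule <- validate_slope_difference(curve_t, curve_r)
cat(sprintf("\nSlope difference %.3f -> raw-Ct quantification %s\n",
            rule$difference, if (rule$pass) "admissible" else "NOT admissible"))

curves <- data.frame(
  gene_role = c("target", "reference"),
  slope = c(curve_t$slope, curve_r$slope),
  y_intercept = c(curve_t$y_intercept, curve_r$y_intercept),
  r_squared = c(curve_t$r_squared, curve_r$r_squared),
  efficiency_percent = c(curve_t$efficiency_percent, curve_r$efficiency_percent),
  slope_difference = rule$difference,
  slope_rule_pass = rule$pass
)
write_results(curves, "results/standard_curves.tsv")
write_results(geometry, "results/assay_geometry.tsv")
cat("\nWrote results/assay_geometry.tsv, results/standard_curves.tsv, results/primers.fasta\n")
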