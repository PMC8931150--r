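# Shared fixtures: the published 20-adult optimisation cohort and small
# builders used across test files.

table3 <- collection_a_cnv()

table3_wide <- function(method) {
  df <- table3[table3$method == method, ]
  r1 <- df[df$biological_replicate == 1L, ]
  r2 <- df[df$biological_replicate == 2L, ]
  stopifnot(identical(r1$specimen_id, r2$specimen_id))
  data.frame(specimen_id = r1$specimen_id, true_sex = r1$true_sex,
             rep1 = r1$cnv, rep2 = r2$cnv, mean = (r1$cnv + r2$cnv) / 2,
             stringsAsFactors = FALSE)
}

ld_target_curve <- function() cnvsex:::curve_from_params(-3.324, 38.476)
ld_reference_curve <- function() cnvsex:::curve_from_params(-3.341, 36.528)

# one-well-per-gene ddPCR table with given counts
wells_df <- function(specimen_id, pos_t, neg_t, pos_r, neg_r) {
  data.frame(
    specimen_id = specimen_id,
    gene_role = c("target", "reference"),
    n_positive = c(pos_t, pos_r),
    n_negative = c(neg_t, neg_r),
    stringsAsFactors = FALSE
  )
}
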