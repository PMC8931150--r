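#' Read a qPCR Ct table
#'
#' Comma-separated UTF-8 with a mandatory header and one row per technical
#' replicate: `specimen_id,gene_role,biological_replicate,
#' technical_replicate,ct,run_id`. An empty `ct` field means no
#' amplification and is read as `NA`. Rows whose `ct` cannot be parsed as a
#' number are dropped and reported with their line numbers (fatal under
#' `strict = TRUE`).
#'
#' @param path CSV path.
#' @param strict If `TRUE`, malformed rows raise an error instead of a
#'   warning.
#' @return Data frame of Ct records; attribute `bad_rows` lists dropped
#'   line numbers, if any.
#' @export
read_ct_table <- function(path, strict = FALSE) {
  df <- read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  required <- c("specimen_id", "gene_role", "biological_replicate",
                "technical_replicate", "ct", "run_id")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ct_raw <- trimws(df$ct)
  ct <- suppressWarnings(as.numeric(ct_raw))
  bad <- which(is.na(ct) & nzchar(ct_raw))
  if (length(bad)) {
    msg <- sprintf("unparseable ct on data line(s): %s",
                   paste(bad, collapse = ", "))
    if (strict) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    df <- df[-bad, , drop = FALSE]
    ct <- ct[-bad]
  }
  out <- data.frame(
    specimen_id = df$specimen_id,
    gene_role = df$gene_role,
    biological_replicate = as.integer(df$biological_replicate),
    technical_replicate = as.integer(df$technical_replicate),
    ct = ct,
    run_id = df$run_id,
    stringsAsFactors = FALSE
  )
  attr(out, "bad_rows") <- bad
  out
}

#' Read a ddPCR wells table
#'
#' CSV with header `specimen_id,gene_role,n_positive,n_negative` and an
#' optional `droplet_volume_nl` column.
#'
#' @param path CSV path.
#' @return Data frame of wells.
#' @export
read_ddpcr_wells <- function(path) {
  df <- read.csv(path, fileEncoding = "UTF-8")
  required <- c("specimen_id", "gene_role", "n_positive", "n_negative")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$specimen_id <- as.character(df$specimen_id)
  df$gene_role <- as.character(df$gene_role)
  df
}

#' Read a standard-curve dilution table
#'
#' CSV with header `gene_role,input_ng,ct`; one row per dilution point.
#'
#' @param path CSV path.
#' @return Data frame with the three columns.
#' @export
read_standard_curves <- function(path) {
  df <- read.csv(path, fileEncoding = "UTF-8")
  required <- c("gene_role", "input_ng", "ct")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a truth table of known sexes
#'
#' CSV with header `specimen_id,true_sex` (`F`/`M`).
#'
#' @param path CSV path.
#' @return Data frame with the two columns.
#' @export
read_truth <- function(path) {
  df <- read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  missing_cols <- setdiff(c("specimen_id", "true_sex"), names(df))
  if (length(missing_cols)) {
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write a results table as TSV
#'
#' Tab-separated UTF-8 with header; numeric columns rendered at 3 decimal
#' places (the reporting precision of per-specimen copy numbers); rows
#' ordered by `specimen_id` then `biological_replicate` when those columns
#' exist, so reruns on identical input are byte-identical.
#'
#' @param results Non-empty data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (!nrow(results)) stop("results are empty", call. = FALSE)
  ord_cols <- intersect(c("specimen_id", "biological_replicate"),
                        names(results))
  if (length(ord_cols)) {
    results <- results[do.call(order, results[ord_cols]), , drop = FALSE]
  }
  is_num <- vapply(results, is.numeric, logical(1)) &
    !vapply(results, is.integer, logical(1))
  results[is_num] <- lapply(results[is_num], function(x) sprintf("%.3f", x))
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Published per-specimen copy number values of the optimisation cohort
#'
#' The 80 copy number values of the 20-adult optimisation collection
#' (10 females F1-F10, 10 males M1-M10), each measured by both ddPCR and
#' qPCR in two biological replicates, transcribed from the assay's
#' published validation. This table is the reference surface the validation
#' statistics are checked against.
#'
#' @return Data frame: `specimen_id`, `true_sex`, `method`,
#'   `biological_replicate`, `cnv` (80 rows).
#' @export
collection_a_cnv <- function() {
  path <- system.file("extdata", "collection_a_cnv.csv", package = "cnvsex")
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$biological_replicate <- as.integer(df$biological_replicate)
  df
}
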