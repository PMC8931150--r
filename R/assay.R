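#' Define a two-gene CNV sexing marker
#'
#' A `gene_assay` describes one primer pair of the dosage assay: either the
#' X-linked target gene (one copy in X0 males, two in XX females) or the
#' autosomal single-copy reference gene (two copies in both sexes). Genomic
#' coordinates are 1-based inclusive, so the amplicon spans from the first
#' base of the forward primer to the last base of the reverse primer.
#'
#' @param gene_name Gene symbol, e.g. `"LdVssc"`.
#' @param role `"target"` (X-linked) or `"reference"` (autosomal).
#' @param forward_primer_seq,reverse_primer_seq Primer sequences, 5'-3',
#'   unambiguous bases A/C/G/T only.
#' @param forward_span,reverse_span Length-2 integer vectors of 1-based
#'   inclusive genomic positions `(start, end)` of each primer binding site.
#' @param expected_amplicon_bp Declared amplicon length in base pairs.
#' @param scaffold_accession Accession of the scaffold the coordinates refer to.
#'
#' @return An object of class `gene_assay`.
#' @seealso [validate_assay()], [amplicon_length()], [read_assay_config()]
#' @export
#' @examples
#' a <- gene_assay("LdVssc", "target",
#'   forward_primer_seq = "AGAATCATGGATTGTCCGAAGGTT",
#'   reverse_primer_seq = "GAGGGTGGTAAGAGTGGCAAAAGT",
#'   forward_span = c(14058, 14081), reverse_span = c(14277, 14300),
#'   expected_amplicon_bp = 243)
#' validate_assay(a)  # character(0): valid
gene_assay <- function(gene_name, role = c("target", "reference"),
                       forward_primer_seq, reverse_primer_seq,
                       forward_span, reverse_span,
                       expected_amplicon_bp,
                       scaffold_accession = NA_character_) {
  role <- match.arg(role)
  structure(
    list(
      gene_name = as.character(gene_name),
      role = role,
      scaffold_accession = as.character(scaffold_accession),
      forward_primer_seq = toupper(as.character(forward_primer_seq)),
      reverse_primer_seq = toupper(as.character(reverse_primer_seq)),
      forward_span = as.integer(forward_span),
      reverse_span = as.integer(reverse_span),
      expected_amplicon_bp = as.integer(expected_amplicon_bp)
    ),
    class = "gene_assay"
  )
}

#' @export
print.gene_assay <- function(x, ...) {
  cat(sprintf("<gene_assay> %s (%s)\n", x$gene_name, x$role))
  cat(sprintf("  scaffold: %s\n", x$scaffold_accession))
  cat(sprintf("  F %d-%d  R %d-%d  amplicon %d bp\n",
              x$forward_span[1], x$forward_span[2],
              x$reverse_span[1], x$reverse_span[2],
              x$expected_amplicon_bp))
  invisible(x)
}

#' Amplicon length from primer coordinates
#'
#' Length in base pairs of the product spanning from the first base of the
#' forward primer to the last base of the reverse primer, both positions
#' 1-based inclusive. Vectorised.
#'
#' @param forward_start 1-based position of the forward primer's first base.
#' @param reverse_end 1-based position of the reverse primer's last base.
#' @return Integer amplicon length(s), `reverse_end - forward_start + 1`.
#' @export
#' @examples
#' amplicon_length(14058, 14300)  # 243
#' amplicon_length(72367, 72616)  # 250
amplicon_length <- function(forward_start, reverse_end) {
  forward_start <- as.integer(forward_start)
  reverse_end <- as.integer(reverse_end)
  if (any(reverse_end < forward_start)) {
    stop("coordinate order error: reverse_end must be >= forward_start",
         call. = FALSE)
  }
  reverse_end - forward_start + 1L
}

.valid_dna <- function(seq) {
  nzchar(seq) && grepl("^[ACGT]+$", seq)
}

#' Validate a gene_assay definition
#'
#' Checks the structural invariants of a marker definition and reports every
#' violation found. Violations are reported, not raised, so a whole assay
#' panel can be audited in one pass. The input is not modified.
#'
#' Checked: primer alphabet (A/C/G/T only; IUPAC ambiguity codes are
#' rejected), coordinate ordering
#' (`forward start <= forward end < reverse start <= reverse end`), and
#' agreement between the declared amplicon length and the one computed from
#' the coordinates.
#'
#' @param assay A [gene_assay()] object.
#' @return Character vector of violation messages; `character(0)` if valid.
#' @export
validate_assay <- function(assay) {
  stopifnot(inherits(assay, "gene_assay"))
  violations <- character(0)
  for (side in c("forward", "reverse")) {
    s <- assay[[paste0(side, "_primer_seq")]]
    if (!.valid_dna(s)) {
      violations <- c(violations, sprintf(
        "%s primer of %s contains characters outside A/C/G/T",
        side, assay$gene_name))
    }
  }
  fs <- assay$forward_span
  rs <- assay$reverse_span
  if (anyNA(c(fs, rs)) || length(fs) != 2L || length(rs) != 2L) {
    violations <- c(violations, sprintf(
      "%s: primer spans must be two finite positions each", assay$gene_name))
    return(violations)
  }
  if (!(fs[1] <= fs[2] && fs[2] < rs[1] && rs[1] <= rs[2])) {
    violations <- c(violations, sprintf(
      "%s: coordinates violate forward.start <= forward.end < reverse.start <= reverse.end",
      assay$gene_name))
  } else {
    computed <- amplicon_length(fs[1], rs[2])
    if (!is.na(assay$expected_amplicon_bp) &&
        computed != assay$expected_amplicon_bp) {
      violations <- c(violations, sprintf(
        "%s: declared amplicon %d bp but coordinates span %d bp",
        assay$gene_name, assay$expected_amplicon_bp, computed))
    }
  }
  violations
}

#' Read marker definitions from a YAML config file
#'
#' The file holds a top-level `assays:` list; each entry carries the fields
#' of [gene_assay()]. The assay panel shipped with the package (an X-linked
#' sodium-channel target and an autosomal ubiquitin-ligase reference for the
#' Colorado potato beetle) is in
#' `system.file("extdata", "assays.yaml", package = "cnvsex")`.
#'
#' @param path Path to the YAML file.
#' @return Named list of `gene_assay` objects (names = gene names).
#' @export
read_assay_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$assays)) {
    stop("assay config must contain a top-level 'assays' list", call. = FALSE)
  }
  out <- lapply(cfg$assays, function(a) {
    gene_assay(
      gene_name = a$gene_name, role = a$role,
      forward_primer_seq = a$forward_primer_seq,
      reverse_primer_seq = a$reverse_primer_seq,
      forward_span = unlist(a$forward_span),
      reverse_span = unlist(a$reverse_span),
      expected_amplicon_bp = a$expected_amplicon_bp,
      scaffold_accession = if (is.null(a$scaffold_accession)) NA else a$scaffold_accession
    )
  })
  names(out) <- vapply(out, `[[`, character(1), "gene_name")
  out
}

#' The beetle sexing assay panel shipped with the package
#'
#' @return Named list of two `gene_assay` objects: the X-linked `LdVssc`
#'   target and the autosomal `LdUBE3B` reference.
#' @export
ld_assays <- function() {
  read_assay_config(system.file("extdata", "assays.yaml", package = "cnvsex"))
}

#' Export primer sequences as FASTA
#'
#' One record per primer, headers `>gene|role|F` and `>gene|role|R`.
#'
#' @param assays List of [gene_assay()] objects.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_primer_fasta <- function(assays, path) {
  if (inherits(assays, "gene_assay")) assays <- list(assays)
  seqs <- unlist(unname(lapply(assays, function(a) {
    s <- c(a$forward_primer_seq, a$reverse_primer_seq)
    names(s) <- paste(a$gene_name, a$role, c("F", "R"), sep = "|")
    s
  })))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
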