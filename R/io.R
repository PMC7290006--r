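#' Read an annotated somatic variant table
#'
#' Reads the tab-separated variant table joining genomic and protein-level
#' annotation. Required columns: `chrom`, `pos`, `ref`, `alt`, `gene`,
#' `protein_id`, `protein_pos`, `aa_ref`, `aa_alt`, `tpm`. An optional
#' `variant_class` column (`substitution`/`indel`) defaults to
#' `"substitution"`. Rows violating the missense invariants (`aa_ref ==
#' aa_alt`, `protein_pos < 1`, `tpm < 0`, missing fields) are excluded and
#' reported, with their line numbers, in the `"rejected"` attribute of the
#' result.
#'
#' @param path Path to a UTF-8 TSV file with header; `.` encodes missing.
#' @return A data.frame of validated variants with a `variant_id` column
#'   (`gene_pPOSREF>ALT`), and attribute `rejected` (data.frame with `line`
#'   and `reason`).
#' @export
read_variant_table <- function(path) {
  req <- c("chrom", "pos", "ref", "alt", "gene", "protein_id",
           "protein_pos", "aa_ref", "aa_alt", "tpm")
  df <- read_tsv(path, required = req)
  validate_variants(df)
}

#' Validate an annotated variant data.frame
#'
#' Applies the missense-record invariants used by [read_variant_table()] to an
#' in-memory table.
#'
#' @param df Data.frame with the variant-table columns.
#' @return Validated data.frame with attribute `rejected`.
#' @export
validate_variants <- function(df) {
  if (is.null(df$variant_class)) {
    df$variant_class <- rep("substitution", nrow(df))
  }
  n <- nrow(df)
  reason <- character(n)
  bad <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    ifelse(cond & reason == "", why, reason)
  }
  if (n) {
    reason <- bad(is.na(df$aa_ref) | is.na(df$aa_alt) | is.na(df$protein_pos),
                  "missing protein annotation")
    reason <- bad(df$aa_ref == df$aa_alt, "non-missense (aa_ref == aa_alt)")
    reason <- bad(df$protein_pos < 1, "protein_pos < 1")
    reason <- bad(is.na(df$tpm) | df$tpm < 0, "tpm missing or negative")
  }
  keep <- reason == ""
  out <- df[keep, , drop = FALSE]
  if (nrow(out)) {
    out$variant_id <- sprintf("%s_p%d%s>%s", out$gene,
                              as.integer(out$protein_pos),
                              out$aa_ref, out$aa_alt)
  } else {
    out$variant_id <- character(0)
  }
  rownames(out) <- NULL
  attr(out, "rejected") <- data.frame(line = which(!keep) + 1L,
                                      reason = reason[!keep],
                                      stringsAsFactors = FALSE)
  out
}

#' Write an annotated variant table
#'
#' Inverse of [read_variant_table()]; valid rows round-trip field-identically.
#'
#' @param df Variant data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_variant_table <- function(df, path) {
  cols <- c("chrom", "pos", "ref", "alt", "gene", "protein_id",
            "protein_pos", "aa_ref", "aa_alt", "tpm", "variant_class")
  write_tsv(df[, intersect(cols, names(df)), drop = FALSE], path)
}

#' Read a minimal VCF into genomic variant records
#'
#' Parses a VCF 4.x file (via vcfR), keeping only the genomic fields.
#' Multi-allelic records are split into one record per ALT allele; symbolic
#' ALT alleles (e.g. `<DEL>`) are skipped with a warning. Protein-level
#' fields stay absent until joined with an annotation table on
#' `(chrom, pos, ref, alt)`.
#'
#' @param path Path to a VCF file.
#' @return Data.frame with `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `variant_class` (`substitution` if REF and ALT are single bases,
#'   `indel` otherwise).
#' @export
read_minimal_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), variant_class = character(),
                      stringsAsFactors = FALSE))
  }
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  out <- data.frame(chrom = rep(fix$CHROM, n_alt),
                    pos = rep(as.integer(fix$POS), n_alt),
                    ref = rep(fix$REF, n_alt),
                    alt = unlist(alts),
                    stringsAsFactors = FALSE)
  symbolic <- grepl("^<.*>$", out$alt) | out$alt == "*"
  if (any(symbolic)) {
    warning(sum(symbolic), " symbolic/structural ALT allele(s) skipped")
    out <- out[!symbolic, , drop = FALSE]
  }
  out$variant_class <- ifelse(nchar(out$ref) == 1L & nchar(out$alt) == 1L,
                              "substitution", "indel")
  rownames(out) <- NULL
  out
}

#' Read protein sequences from FASTA
#'
#' The first whitespace-delimited token of each header is the protein id.
#' Sequences are uppercased; duplicate ids are an error.
#'
#' @param path Path to a (plain-text) FASTA file.
#' @return Named character vector of uppercase amino-acid sequences.
#' @export
read_fasta_proteins <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aas), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate protein id(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(aas))
  names(seqs) <- ids
  seqs
}

#' Write protein sequences to FASTA
#'
#' @param seqs Named character vector of amino-acid sequences.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta_proteins <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path, width = 60L)
  invisible(path)
}

#' Read a peptide-allele percent-rank table
#'
#' Adapter for externally produced binding-predictor output, flattened to a
#' plain TSV with columns `peptide`, `allele`, `percent_rank` and optionally
#' `affinity_nM`. Percent ranks must lie in \[0, 100\]. Duplicate
#' `(peptide, allele)` rows are resolved by keeping the minimum rank, with a
#' warning.
#'
#' @param path Path to the TSV file.
#' @return Data.frame with one row per `(peptide, allele)`.
#' @export
read_rank_table <- function(path) {
  df <- read_tsv(path, required = c("peptide", "allele", "percent_rank"))
  df$percent_rank <- as.numeric(df$percent_rank)
  bad <- is.na(df$percent_rank) | df$percent_rank < 0 | df$percent_rank > 100
  if (any(bad)) {
    stop("percent_rank outside [0, 100] at data row(s): ",
         paste(utils::head(which(bad), 10), collapse = ", "))
  }
  key <- paste(df$peptide, df$allele, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)),
            " duplicate (peptide, allele) row(s); keeping minimum rank")
    df <- df[order(key, df$percent_rank), , drop = FALSE]
    df <- df[!duplicated(paste(df$peptide, df$allele, sep = "\r")), ,
             drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Write a peptide-allele percent-rank table
#'
#' @param df Data.frame with `peptide`, `allele`, `percent_rank` columns.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_rank_table <- function(df, path) write_tsv(df, path)

#' Read an ELISPOT plate table
#'
#' Long-format spot counts: one row per well, columns `patient`, `timepoint`,
#' `antigen`, `well`, `spots`, `effector_cells`. Unstimulated control wells
#' use antigen `"NONE"`.
#'
#' @param path Path to the TSV file.
#' @return Data.frame of well-level counts.
#' @export
read_elispot_table <- function(path) {
  df <- read_tsv(path, required = c("patient", "timepoint", "antigen",
                                    "well", "spots", "effector_cells"))
  if (any(df$spots < 0, na.rm = TRUE)) stop("negative spot count")
  df
}

#' Read a DTH reading table
#'
#' One row per reading: `patient`, `timepoint`, `hours` (1/24/48/72),
#' `lesion_type` (`macular`/`papular`), `diameter_cm`.
#'
#' @param path Path to the TSV file.
#' @return Data.frame of readings.
#' @export
read_dth_table <- function(path) {
  read_tsv(path, required = c("patient", "timepoint", "hours",
                              "lesion_type", "diameter_cm"))
}

#' Read a calcein-release fluorescence table
#'
#' One row per well: `stimulation`, `timepoint`, `et_ratio`, `well_type`
#' (`experimental`/`spontaneous`/`maximum`), `well`, `fluorescence`.
#'
#' @param path Path to the TSV file.
#' @return Data.frame of wells.
#' @export
read_lysis_table <- function(path) {
  read_tsv(path, required = c("stimulation", "timepoint", "et_ratio",
                              "well_type", "well", "fluorescence"))
}
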