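#' Enumerate wild-type/mutant peptide pairs for one missense variant
#'
#' Slides windows of each requested length over the protein and keeps every
#' window that covers the substituted residue and lies fully inside the
#' sequence. Each window yields the mutant peptide (with `aa_alt` substituted)
#' paired with the unmutated wild-type window.
#'
#' @param variant One-row data.frame (or list) with `variant_id`,
#'   `protein_id`, `protein_pos`, `aa_ref`, `aa_alt` and optionally `tpm`.
#' @param protein Amino-acid sequence of the protein (single string).
#' @param lengths Integer vector of peptide lengths, a subset of 8:15.
#' @return Data.frame with one row per window: `variant_id`, `length`,
#'   `start` (1-based in the protein), `mut_offset` (1-based position of the
#'   substitution within the peptide), `mut_peptide`, `wt_peptide`, `tpm`.
#'   Windows whose wild-type sequence contains a residue outside the
#'   20-letter alphabet (e.g. `X`) are dropped, with a count in the
#'   `"dropped_nonstandard"` attribute.
#' @export
enumerate_pairs <- function(variant, protein, lengths = 8:11) {
  lengths <- sort(unique(as.integer(lengths)))
  if (!all(lengths %in% 8:15)) stop("lengths must be within 8..15")
  p <- as.integer(variant$protein_pos)
  n <- nchar(protein)
  if (p < 1 || p > n) {
    stop("variant ", variant$variant_id, ": protein_pos ", p,
         " outside protein of length ", n)
  }
  if (substr(protein, p, p) != variant$aa_ref) {
    stop("variant ", variant$variant_id, ": residue at protein_pos is '",
         substr(protein, p, p), "', expected aa_ref '", variant$aa_ref, "'")
  }
  rows <- vector("list", length(lengths))
  for (i in seq_along(lengths)) {
    L <- lengths[i]
    starts <- seq.int(max(1L, p - L + 1L), min(p, n - L + 1L))
    starts <- starts[starts >= 1L & starts <= n - L + 1L]
    if (!length(starts)) next
    wt <- substring(protein, starts, starts + L - 1L)
    off <- p - starts + 1L
    mut <- wt
    substr(mut, off, off) <- rep(variant$aa_alt, length(mut))
    rows[[i]] <- data.frame(variant_id = variant$variant_id, length = L,
                            start = starts, mut_offset = off,
                            mut_peptide = mut, wt_peptide = wt,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(variant_id = character(), length = integer(),
                      start = integer(), mut_offset = integer(),
                      mut_peptide = character(), wt_peptide = character(),
                      stringsAsFactors = FALSE)
  }
  ok <- !grepl("[^ARNDCQEGHILKMFPSTWYV]", out$wt_peptide) &
    !grepl("[^ARNDCQEGHILKMFPSTWYV]", out$mut_peptide)
  dropped <- sum(!ok)
  out <- out[ok, , drop = FALSE]
  out$tpm <- if (is.null(variant$tpm)) NA_real_ else as.numeric(variant$tpm)
  rownames(out) <- NULL
  attr(out, "dropped_nonstandard") <- dropped
  out
}

#' Enumerate peptide pairs for a whole variant table
#'
#' @param variants Validated variant data.frame (see [read_variant_table()]).
#' @param proteins Named character vector of protein sequences, indexed by
#'   `protein_id`.
#' @param lengths Peptide lengths; default 8-11-mers.
#' @return Data.frame of pairs with a unique `pair_id`
#'   (`variant_id:length:start`). Variants whose `protein_id` is absent from
#'   `proteins` are dropped with a logged count (attribute `"unmatched"`).
#' @export
enumerate_all_pairs <- function(variants, proteins, lengths = 8:11) {
  have <- variants$protein_id %in% names(proteins)
  if (any(!have)) {
    message(sum(!have), " variant(s) without a protein sequence dropped")
  }
  variants <- variants[have, , drop = FALSE]
  pieces <- lapply(seq_len(nrow(variants)), function(i) {
    enumerate_pairs(variants[i, ], proteins[[variants$protein_id[i]]], lengths)
  })
  out <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  if (is.null(out) || !nrow(out)) {
    out <- enumerate_pairs(list(variant_id = "x", protein_id = "x",
                                protein_pos = 1, aa_ref = "A", aa_alt = "C"),
                           "A", integer(0))[0, ]
  }
  out$pair_id <- sprintf("%s:%d:%d", out$variant_id, out$length, out$start)
  attr(out, "unmatched") <- sum(!have)
  out
}

#' Filter peptide pairs by transcript expression
#'
#' Retains pairs whose source variant is expressed at or above the TPM
#' threshold. In `"annotate"` mode nothing is removed; a logical `retained`
#' column records the decision in both modes.
#'
#' @param pairs Pair data.frame with a `tpm` column.
#' @param tpm_threshold Non-negative expression cutoff
#'   (transcripts per million); default 0.1.
#' @param mode `"filter"` (drop failing pairs) or `"annotate"` (keep all).
#' @return The pair data.frame with a `retained` column (and failing rows
#'   removed when `mode = "filter"`).
#' @export
expression_filter <- function(pairs, tpm_threshold = 0.1,
                              mode = c("filter", "annotate")) {
  mode <- match.arg(mode)
  if (tpm_threshold < 0) stop("tpm_threshold must be >= 0")
  pairs$retained <- !is.na(pairs$tpm) & pairs$tpm >= tpm_threshold
  if (mode == "filter") {
    pairs <- pairs[pairs$retained, , drop = FALSE]
    rownames(pairs) <- NULL
  }
  pairs
}
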