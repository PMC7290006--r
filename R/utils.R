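#' Standard amino-acid alphabet
#'
#' The 20 proteinogenic residues in the conventional BLOSUM row order.
#'
#' @return Character vector of 20 single-letter codes.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Background amino-acid frequencies
#'
#' Robinson-Robinson style natural frequencies, normalized to sum to 1, in
#' [aa_alphabet()] order. Used by the mock binding predictor's background and
#' by the synthetic protein generator.
#'
#' @return Named numeric vector of length 20 summing to 1.
#' @export
aa_background_freqs <- function() {
  f <- c(A = 0.0787, R = 0.0512, N = 0.0448, D = 0.0536, C = 0.0193,
         Q = 0.0426, E = 0.0632, G = 0.0739, H = 0.0226, I = 0.0513,
         L = 0.0901, K = 0.0574, M = 0.0224, F = 0.0387, P = 0.0520,
         S = 0.0711, T = 0.0584, W = 0.0132, Y = 0.0321, V = 0.0644)
  f <- f[aa_alphabet()]
  f / sum(f)
}

#' Shifted BLOSUM62 substitution matrix
#'
#' BLOSUM62 restricted to the 20-letter alphabet with the global minimum
#' subtracted, so every entry is non-negative. The shift keeps the k-mer
#' kernel positive and its normalized similarity in \[0, 1\].
#'
#' @return A 20 x 20 non-negative numeric matrix with dimnames in
#'   [aa_alphabet()] order.
#' @export
blosum62_shifted <- function() {
  if (is.null(.neoprior_cache$blosum_shifted)) {
    e <- new.env(parent = emptyenv())
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    aa <- aa_alphabet()
    s <- e$BLOSUM62[aa, aa]
    .neoprior_cache$blosum_shifted <- s - min(s)
  }
  .neoprior_cache$blosum_shifted
}

# split a peptide into residue indices in the 20-letter alphabet; error on
# anything outside it (X / stop codons are dropped earlier, at enumeration)
aa_indices <- function(peptide) {
  idx <- match(strsplit(peptide, "", fixed = TRUE)[[1]], aa_alphabet())
  if (anyNA(idx)) {
    stop("peptide '", peptide, "' contains residues outside the 20-letter alphabet")
  }
  idx
}

# Derive a per-stream seed from one global seed so stages can be regenerated
# independently. Kept below 2^31 - 1.
derive_seed <- function(seed, stream) {
  offsets <- c(mutanome = 101L, ranks = 211L, elispot = 307L, dth = 401L,
               lysis = 503L, mock = 607L, antigens = 701L, noise = 809L)
  if (!stream %in% names(offsets)) stop("unknown seed stream: ", stream)
  as.integer((as.numeric(seed) * 1009 + offsets[[stream]]) %% 2147483647)
}

# deterministic TSV writer shared by all outputs ('.' encodes missing)
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

read_tsv <- function(path, required = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = ".", check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "))
  }
  df
}
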