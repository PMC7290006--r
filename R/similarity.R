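#' Alignment-free k-mer string kernel between two peptides
#'
#' Sums, over k = 1..`kmax`, the products of substitution scores between
#' every k-mer of `a` and every k-mer of `b`:
#' `K(a, b) = sum_k sum_i sum_j prod_m S(a[i+m], b[j+m])`,
#' where `S` is a non-negative (shifted) substitution matrix. With the
#' default shifted BLOSUM62 every term is non-negative, so the normalized
#' similarity lands in \[0, 1\]. Symmetric and deterministic.
#'
#' The inner sums are computed by cumulative diagonal products of the
#' residue-by-residue score matrix rather than explicit k-mer loops.
#'
#' @param a,b Peptide strings over the 20-letter alphabet.
#' @param kmax Maximum k-mer length (>= 1); default 3.
#' @param submat Non-negative symmetric substitution matrix with amino-acid
#'   dimnames; default [blosum62_shifted()].
#' @return The raw kernel value `K(a, b)`.
#' @export
kmer_kernel <- function(a, b, kmax = 3L, submat = blosum62_shifted()) {
  if (!nzchar(a) || !nzchar(b)) stop("peptides must be non-empty")
  if (kmax < 1L) stop("kmax must be >= 1")
  ai <- aa_indices(a)
  bi <- aa_indices(b)
  M <- submat[ai, bi, drop = FALSE]
  P <- M
  total <- sum(P)
  k <- 2L
  while (k <= kmax && nrow(P) > 1L && ncol(P) > 1L) {
    # P[i, j] after this step = product of S over the k-long diagonal run
    P <- P[-nrow(P), -ncol(P), drop = FALSE] *
      M[k:nrow(M), k:ncol(M), drop = FALSE]
    total <- total + sum(P)
    k <- k + 1L
  }
  total
}

#' Normalized kernel similarity and distance
#'
#' `similarity = K(a, b) / sqrt(K(a, a) * K(b, b))`, so identical peptides
#' have similarity exactly 1. Distance is `1 - similarity` by default, or the
#' kernel-metric form `sqrt(2 - 2 * similarity)`.
#'
#' @inheritParams kmer_kernel
#' @param metric Distance form: `"one_minus"` (default) or `"sqrt"`.
#' @return List with `kernel_raw`, `similarity`, `distance`.
#' @export
normalized_similarity <- function(a, b, kmax = 3L,
                                  submat = blosum62_shifted(),
                                  metric = c("one_minus", "sqrt")) {
  metric <- match.arg(metric)
  kaa <- kmer_kernel(a, a, kmax, submat)
  kbb <- kmer_kernel(b, b, kmax, submat)
  if (kaa <= 0 || kbb <= 0) stop("zero self-kernel: degenerate substitution matrix")
  kab <- kmer_kernel(a, b, kmax, submat)
  s <- kab / sqrt(kaa * kbb)
  d <- if (metric == "one_minus") 1 - s else sqrt(pmax(0, 2 - 2 * s))
  list(kernel_raw = kab, similarity = s, distance = d)
}

#' Kernel similarity for a table of wild-type/mutant pairs
#'
#' Computes the normalized kernel similarity between `wt_peptide` and
#' `mut_peptide` of every pair. Pairs of unequal length are rejected (they
#' cannot arise from [enumerate_pairs()]).
#'
#' @param pairs Pair data.frame with `mut_peptide`, `wt_peptide`.
#' @inheritParams normalized_similarity
#' @return `pairs` with `kernel_raw`, `similarity`, `distance` columns added.
#' @export
pair_similarity <- function(pairs, kmax = 3L, submat = blosum62_shifted(),
                            metric = c("one_minus", "sqrt")) {
  metric <- match.arg(metric)
  if (any(nchar(pairs$mut_peptide) != nchar(pairs$wt_peptide))) {
    stop("wt/mut peptides of unequal length")
  }
  res <- mapply(function(m, w) {
    r <- normalized_similarity(m, w, kmax, submat, metric)
    c(r$kernel_raw, r$similarity, r$distance)
  }, pairs$mut_peptide, pairs$wt_peptide, USE.NAMES = FALSE)
  pairs$kernel_raw <- res[1, ]
  pairs$similarity <- res[2, ]
  pairs$distance <- res[3, ]
  pairs
}
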