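#' Build a deterministic mock HLA binding model
#'
#' A stand-in for an external binding predictor, used for synthetic cohorts
#' and end-to-end tests. Each allele gets a 9 x 20 position-specific scoring
#' matrix (PSSM) drawn from a seed derived from the allele name, plus a
#' background of `n_background` random natural peptides whose sorted scores
#' define percent-rank semantics. Mock scores carry no biological meaning.
#'
#' Class I models score 9-mer windows of 9+-mer peptides; class II models
#' score the 9-mer binding core inside 15-mers the same way, so the core
#' position is available to downstream filters.
#'
#' @param allele Allele name (any string; same name + seed gives the same
#'   model).
#' @param seed Integer seed for the whole predictor; combined with the allele
#'   name to seed this model.
#' @param hla_class `"I"` or `"II"` (class II backgrounds are 15-mers).
#' @param n_background Number of background peptides (>= 1000).
#' @return A `mock_allele_model` list: `allele`, `hla_class`, `pssm`,
#'   `background` (sorted ascending scores).
#' @export
mock_allele_model <- function(allele, seed = 1L, hla_class = c("I", "II"),
                              n_background = 10000L) {
  hla_class <- match.arg(hla_class)
  if (n_background < 1000L) stop("n_background must be >= 1000")
  key <- paste(allele, seed, hla_class, n_background, sep = "|")
  hit <- .neoprior_cache$mock_models[[key]]
  if (!is.null(hit)) return(hit)
  allele_seed <- as.integer((derive_seed(seed, "mock") +
                               sum(utf8ToInt(allele)) * 131) %% 2147483647)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(allele_seed)
  pssm <- matrix(stats::rnorm(9L * 20L), nrow = 9L, ncol = 20L,
                 dimnames = list(NULL, aa_alphabet()))
  bg_len <- if (hla_class == "I") 9L else 15L
  bg <- random_peptides(n_background, bg_len)
  model <- structure(list(allele = allele, hla_class = hla_class, pssm = pssm,
                          background = numeric(0)),
                     class = "mock_allele_model")
  model$background <- sort(score_peptides(model, bg))
  if (is.null(.neoprior_cache$mock_models)) {
    .neoprior_cache$mock_models <- list()
  }
  .neoprior_cache$mock_models[[key]] <- model
  model
}

# save/restore .Random.seed so model construction does not disturb the
# caller's RNG stream (cache hits and misses must behave identically)
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Sample random peptides from the background frequency model
#'
#' @param n Number of peptides.
#' @param length Peptide length.
#' @param freqs Amino-acid frequencies; default [aa_background_freqs()].
#' @return Character vector of `n` peptides.
#' @export
random_peptides <- function(n, length = 9L, freqs = aa_background_freqs()) {
  m <- matrix(sample(aa_alphabet(), n * length, replace = TRUE, prob = freqs),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# vectorized raw scoring of equal treatment for mixed lengths: every peptide
# is scored as the max PSSM sum over its contiguous 9-mer windows
score_peptides <- function(model, peptides) {
  lens <- nchar(peptides)
  if (any(lens < 9L)) stop("peptides shorter than 9 cannot be scored")
  out <- numeric(length(peptides))
  core <- integer(length(peptides))
  for (L in unique(lens)) {
    sel <- which(lens == L)
    chars <- matrix(match(unlist(strsplit(peptides[sel], "", fixed = TRUE),
                                 use.names = FALSE), aa_alphabet()),
                    nrow = length(sel), byrow = TRUE)
    if (anyNA(chars)) stop("peptide contains residues outside the 20-letter alphabet")
    n_win <- L - 9L + 1L
    best <- rep(-Inf, length(sel))
    best_w <- rep(1L, length(sel))
    for (w in seq_len(n_win)) {
      sc <- numeric(length(sel))
      for (j in 1:9) sc <- sc + model$pssm[j, ][chars[, w + j - 1L]]
      upd <- sc > best
      best[upd] <- sc[upd]
      best_w[upd] <- w
    }
    out[sel] <- best
    core[sel] <- best_w
  }
  attr(out, "core_start") <- core
  out
}

#' Score a peptide with a mock allele model
#'
#' The raw score of a 9-mer is the sum of its per-position PSSM entries;
#' longer peptides score as the maximum over their contiguous 9-mer windows.
#' Higher means better predicted binding. Deterministic.
#'
#' @param model A [mock_allele_model()].
#' @param peptide Peptide string, length >= 9.
#' @return Raw numeric score, with attribute `core_start` (1-based start of
#'   the best-scoring 9-mer window, the binding core).
#' @export
score_peptide <- function(model, peptide) {
  s <- score_peptides(model, peptide)
  structure(as.numeric(s), core_start = attr(s, "core_start"))
}

#' Percent rank of peptides against a model background
#'
#' `rank = 100 * (fraction of background scores strictly greater than the
#' peptide's raw score)`: 0 means the peptide outscores the whole background.
#' Ties with background scores are not counted as greater (optimistic rank).
#'
#' @param model A [mock_allele_model()].
#' @param peptides Character vector of peptides (length >= 9 each).
#' @return Numeric vector of percent ranks in \[0, 100\].
#' @export
percent_rank <- function(model, peptides) {
  sc <- score_peptides(model, peptides)
  n <- length(model$background)
  # background sorted ascending: #(bg <= s) via findInterval, rest are > s
  100 * (n - findInterval(sc, model$background)) / n
}

#' Predict percent ranks for every peptide-allele combination
#'
#' Builds the complete rank matrix over the mutant and wild-type peptides of
#' a pair table and a set of alleles, either from the built-in mock predictor
#' or from a precomputed rank table.
#'
#' @param pairs Pair data.frame with `mut_peptide` and `wt_peptide`.
#' @param alleles Character vector of allele names.
#' @param source `"mock"` (deterministic built-in predictor) or `"table"`.
#' @param rank_table For `source = "table"`, a data.frame from
#'   [read_rank_table()].
#' @param seed Seed for the mock predictor.
#' @param hla_class Class of the alleles (`"I"` or `"II"`).
#' @param strict For `source = "table"`: error on missing `(peptide, allele)`
#'   combinations (default) instead of returning `NA` ranks.
#' @return Data.frame `peptide`, `allele`, `percent_rank` covering every
#'   combination.
#' @export
predict_ranks <- function(pairs, alleles, source = c("mock", "table"),
                          rank_table = NULL, seed = 1L,
                          hla_class = "I", strict = TRUE) {
  source <- match.arg(source)
  peptides <- unique(c(pairs$mut_peptide, pairs$wt_peptide))
  grid <- expand.grid(peptide = peptides, allele = alleles,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (source == "mock") {
    ranks <- lapply(alleles, function(a) {
      m <- mock_allele_model(a, seed = seed, hla_class = hla_class)
      percent_rank(m, peptides)
    })
    grid$percent_rank <- unlist(ranks, use.names = FALSE)
  } else {
    if (is.null(rank_table)) stop("source = 'table' requires rank_table")
    key <- paste(grid$peptide, grid$allele, sep = "\r")
    tkey <- paste(rank_table$peptide, rank_table$allele, sep = "\r")
    idx <- match(key, tkey)
    if (strict && anyNA(idx)) {
      miss <- grid[is.na(idx), , drop = FALSE]
      stop("rank table is missing ", nrow(miss), " (peptide, allele) pair(s), e.g. ",
           paste(utils::head(sprintf("(%s, %s)", miss$peptide, miss$allele), 5),
                 collapse = ", "))
    }
    grid$percent_rank <- rank_table$percent_rank[idx]
  }
  grid
}

#' Binding-core start positions of 15-mers under a class II mock model
#'
#' @param model A class II [mock_allele_model()].
#' @param peptides Character vector of 15-mers.
#' @return Integer vector of 1-based core starts in \[1, 7\].
#' @export
core_starts <- function(model, peptides) {
  s <- score_peptides(model, peptides)
  as.integer(attr(s, "core_start"))
}
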