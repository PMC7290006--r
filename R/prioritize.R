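#' Thresholds for neoepitope classification
#'
#' Strong/weak percent-rank cutoffs and the low-similarity cutoff that define
#' the three candidate groups, plus the class II promiscuity and binding-core
#' containment parameters.
#'
#' `"<"` and `">"` are strict throughout: a candidate with a rank exactly at
#' `strong_rank` or `weak_rank` satisfies neither side and falls to
#' `UNCLASSIFIED`.
#'
#' @param strong_rank Percent rank below which a peptide is a strong binder
#'   (default 2).
#' @param weak_rank Percent rank above which binding counts as poor
#'   (default 5).
#' @param low_similarity Normalized similarity below which a wt/mut pair
#'   counts as dissimilar (default 0.95; on the \[0, 1\] kernel scale any
#'   visible substitution effect).
#' @param classII_min_alleles Minimum number of qualifying class II alleles
#'   for a promiscuous binder (default 2).
#' @param classII_core_overlap Minimum number of neoepitope residues inside
#'   the 9-mer class II binding core (default 7).
#' @return A `neo_thresholds` list.
#' @export
neo_thresholds <- function(strong_rank = 2, weak_rank = 5,
                           low_similarity = 0.95, classII_min_alleles = 2L,
                           classII_core_overlap = 7L) {
  if (strong_rank >= weak_rank) stop("strong_rank must be < weak_rank")
  structure(list(strong_rank = strong_rank, weak_rank = weak_rank,
                 low_similarity = low_similarity,
                 classII_min_alleles = as.integer(classII_min_alleles),
                 classII_core_overlap = as.integer(classII_core_overlap)),
            class = "neo_thresholds")
}

#' Classify candidates into groups A, B, NEGATIVE or UNCLASSIFIED
#'
#' Group A: the mutant peptide binds strongly (`best_mut_rank < strong_rank`)
#' while the wild type binds poorly (`best_wt_rank > weak_rank`). Group B:
#' both bind strongly and the wt/mut similarity is low
#' (`similarity < low_similarity`). NEGATIVE (control): the mutant binds
#' poorly (`best_mut_rank > weak_rank`) while the wild type binds strongly.
#' Rules are evaluated in that order; anything else is UNCLASSIFIED.
#'
#' @param best_mut_rank,best_wt_rank Numeric vectors of best (minimum over
#'   the patient's class I alleles) percent ranks.
#' @param similarity Numeric vector of normalized wt/mut similarities.
#' @param thresholds A [neo_thresholds()] object.
#' @return Character vector in `{"A", "B", "NEGATIVE", "UNCLASSIFIED"}`.
#' @export
assign_group <- function(best_mut_rank, best_wt_rank, similarity,
                         thresholds = neo_thresholds()) {
  th <- thresholds
  out <- rep("UNCLASSIFIED", length(best_mut_rank))
  is_a <- best_mut_rank < th$strong_rank & best_wt_rank > th$weak_rank
  is_b <- !is_a & best_mut_rank < th$strong_rank &
    best_wt_rank < th$strong_rank & similarity < th$low_similarity
  is_n <- !is_a & !is_b & best_mut_rank > th$weak_rank &
    best_wt_rank < th$strong_rank
  out[is_n] <- "NEGATIVE"
  out[is_b] <- "B"
  out[is_a] <- "A"
  out
}

#' Build the candidate table from pairs and a rank table
#'
#' Aggregates per-allele percent ranks to the best (minimum) rank over the
#' patient's class I alleles for each mutant and wild-type peptide, joins the
#' wt/mut similarity, and assigns the group label.
#'
#' @param pairs Pair data.frame with `pair_id`, `mut_peptide`, `wt_peptide`
#'   and a `similarity` column (see [pair_similarity()]).
#' @param ranks Data.frame `peptide`, `allele`, `percent_rank` covering both
#'   peptides of every pair for every allele in `alleles`.
#' @param alleles Patient class I alleles to aggregate over.
#' @param thresholds A [neo_thresholds()] object.
#' @param aggregate `"best"` (minimum rank over alleles, default) or
#'   `"per_allele"` (one candidate row per pair x allele, each judged on its
#'   own ranks).
#' @return Data.frame of candidates with `best_mut_rank`, `best_wt_rank`,
#'   `similarity`, `group`.
#' @export
candidate_table <- function(pairs, ranks, alleles,
                            thresholds = neo_thresholds(),
                            aggregate = c("best", "per_allele")) {
  aggregate <- match.arg(aggregate)
  ranks <- ranks[ranks$allele %in% alleles, , drop = FALSE]
  if (aggregate == "best") {
    best <- tapply(ranks$percent_rank, ranks$peptide, min)
    mut_r <- as.numeric(best[pairs$mut_peptide])
    wt_r <- as.numeric(best[pairs$wt_peptide])
    if (anyNA(mut_r) || anyNA(wt_r)) {
      stop("rank table does not cover every peptide of every pair")
    }
    out <- pairs
    out$best_mut_rank <- mut_r
    out$best_wt_rank <- wt_r
  } else {
    key <- paste(ranks$peptide, ranks$allele, sep = "\r")
    out <- do.call(rbind, lapply(alleles, function(a) {
      x <- pairs
      x$allele <- a
      x$best_mut_rank <- ranks$percent_rank[match(paste(x$mut_peptide, a, sep = "\r"), key)]
      x$best_wt_rank <- ranks$percent_rank[match(paste(x$wt_peptide, a, sep = "\r"), key)]
      x
    }))
    if (anyNA(out$best_mut_rank) || anyNA(out$best_wt_rank)) {
      stop("rank table does not cover every peptide of every pair")
    }
  }
  out$group <- assign_group(out$best_mut_rank, out$best_wt_rank,
                            out$similarity, thresholds)
  rownames(out) <- NULL
  out
}

#' Sort candidates within their groups
#'
#' Within each group candidates are ordered by ascending best mutant rank,
#' then wild-type rank — descending in group A (poorer wild-type binding
#' first, the group's defining trait), ascending elsewhere — then ascending
#' similarity. Ties preserve input order (stable sort). Groups are ordered
#' A, B, NEGATIVE, UNCLASSIFIED.
#'
#' @param candidates Candidate data.frame from [candidate_table()].
#' @return The sorted data.frame with a `rank_in_group` column.
#' @export
sort_candidates <- function(candidates) {
  grp <- factor(candidates$group,
                levels = c("A", "B", "NEGATIVE", "UNCLASSIFIED"))
  wt_key <- ifelse(candidates$group == "A",
                   -candidates$best_wt_rank, candidates$best_wt_rank)
  o <- order(grp, candidates$best_mut_rank, wt_key, candidates$similarity)
  out <- candidates[o, , drop = FALSE]
  out$rank_in_group <- stats::ave(seq_len(nrow(out)), out$group,
                                  FUN = seq_along)
  rownames(out) <- NULL
  out
}

#' Split an ordered peptide list into screening pools
#'
#' Contiguous chunks in sorted order whose sizes differ by at most one
#' (larger pools first); every peptide lands in exactly one pool.
#'
#' @param peptides Character vector, already sorted.
#' @param n_pools Number of pools; alternatively give `pool_size`.
#' @param pool_size Target pool size; `n_pools` is then
#'   `ceiling(length(peptides) / pool_size)`.
#' @param prefix Pool label prefix (e.g. `"A"` gives pools `A1`, `A2`, ...).
#' @return Data.frame `pool_id`, `peptide` (one row per peptide).
#' @export
make_pools <- function(peptides, n_pools = NULL, pool_size = NULL,
                       prefix = "P") {
  n <- length(peptides)
  if (is.null(n_pools)) {
    if (is.null(pool_size) || pool_size < 1) stop("give n_pools or pool_size >= 1")
    n_pools <- ceiling(n / pool_size)
  }
  if (n_pools < 1 || n_pools > max(n, 1)) stop("invalid number of pools")
  base <- n %/% n_pools
  extra <- n %% n_pools
  sizes <- rep(base, n_pools) + c(rep(1L, extra), rep(0L, n_pools - extra))
  data.frame(pool_id = paste0(prefix, rep(seq_len(n_pools), sizes)),
             peptide = peptides, stringsAsFactors = FALSE)
}

#' All 15-mer windows of a protein containing a neoepitope
#'
#' @param neoepitope Peptide (<= 15 residues) to embed; must occur in the
#'   protein (first occurrence is used, with a warning if there are several).
#' @param protein Source protein sequence.
#' @return Data.frame `fifteen_mer`, `start` (1-based in the protein), with
#'   attribute `ne_start` (1-based start of the neoepitope in the protein).
#' @export
fifteen_mer_windows <- function(neoepitope, protein) {
  ne_len <- nchar(neoepitope)
  if (ne_len > 15L) stop("neoepitope longer than 15 residues")
  hits <- gregexpr(neoepitope, protein, fixed = TRUE)[[1]]
  if (hits[1] < 0) stop("neoepitope not found in protein")
  if (length(hits) > 1) warning("neoepitope occurs ", length(hits),
                                " times; using the first occurrence")
  ne_start <- as.integer(hits[1])
  n <- nchar(protein)
  starts <- seq.int(max(1L, ne_start - (15L - ne_len)),
                    min(ne_start, n - 15L + 1L))
  starts <- starts[starts >= 1L]
  structure(data.frame(fifteen_mer = substring(protein, starts, starts + 14L),
                       start = starts, stringsAsFactors = FALSE),
            ne_start = ne_start)
}

#' Select class II 15-mers containing a tested neoepitope
#'
#' From all 15-mer windows of the source protein that contain the entire
#' neoepitope, keeps those that are promiscuous strong class II binders with
#' the neoepitope anchored in the binding core: an allele qualifies when its
#' percent rank is below `strong_rank` and at least `classII_core_overlap`
#' neoepitope residues lie inside its 9-mer binding core; a window is kept
#' when at least `classII_min_alleles` alleles qualify.
#'
#' @param neoepitope The tested class I neoepitope (8-11-mer) to embed.
#' @param protein Source protein sequence containing the neoepitope.
#' @param classII_ranks Data.frame `fifteen_mer`, `allele`, `percent_rank`,
#'   `core_start` (1-based start of the 9-mer core within the 15-mer) covering
#'   every window x allele.
#' @param thresholds A [neo_thresholds()] object.
#' @return Data.frame of selected windows: `fifteen_mer`, `start` (1-based in
#'   the protein), `n_strong_alleles` (alleles with rank < strong_rank),
#'   `n_qualifying_alleles` (strong alleles that also satisfy core
#'   containment), `core_start` (core of the best qualifying allele).
#' @export
select_class_ii <- function(neoepitope, protein, classII_ranks,
                            thresholds = neo_thresholds()) {
  th <- thresholds
  ne_len <- nchar(neoepitope)
  win <- fifteen_mer_windows(neoepitope, protein)
  starts <- win$start
  windows <- win$fifteen_mer
  ne_start <- attr(win, "ne_start")
  key <- paste(classII_ranks$fifteen_mer, classII_ranks$allele, sep = "\r")
  alleles <- unique(classII_ranks$allele)
  keep <- logical(length(windows))
  n_strong <- integer(length(windows))
  n_qual <- integer(length(windows))
  best_core <- rep(NA_integer_, length(windows))
  for (i in seq_along(windows)) {
    idx <- match(paste(windows[i], alleles, sep = "\r"), key)
    if (anyNA(idx)) stop("classII_ranks does not cover window ", windows[i])
    pr <- classII_ranks$percent_rank[idx]
    cs <- classII_ranks$core_start[idx]
    # neoepitope occupies positions (ne_start - start + 1) .. within the 15-mer
    ne_off <- ne_start - starts[i] + 1L
    overlap <- pmin(cs + 8L, ne_off + ne_len - 1L) - pmax(cs, ne_off) + 1L
    strong <- pr < th$strong_rank
    qual <- strong & overlap >= th$classII_core_overlap
    n_strong[i] <- sum(strong)
    n_qual[i] <- sum(qual)
    keep[i] <- n_qual[i] >= th$classII_min_alleles
    if (any(qual)) best_core[i] <- cs[qual][which.min(pr[qual])]
  }
  out <- data.frame(fifteen_mer = windows, start = starts,
                    n_strong_alleles = n_strong,
                    n_qualifying_alleles = n_qual,
                    core_start = best_core, stringsAsFactors = FALSE)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
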