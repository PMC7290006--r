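#' Mock class II percent-rank table for a set of 15-mers
#'
#' Scores each 15-mer against class II mock allele models and reports the
#' percent rank plus the 9-mer binding-core start, in the layout
#' [select_class_ii()] consumes.
#'
#' @param fifteen_mers Character vector of 15-mers.
#' @param alleles Class II allele names.
#' @param seed Predictor seed.
#' @return Data.frame `fifteen_mer`, `allele`, `percent_rank`, `core_start`.
#' @export
mock_class_ii_ranks <- function(fifteen_mers, alleles, seed = 1L) {
  rows <- lapply(alleles, function(a) {
    m <- mock_allele_model(a, seed = seed, hla_class = "II")
    data.frame(fifteen_mer = fifteen_mers, allele = a,
               percent_rank = percent_rank(m, fifteen_mers),
               core_start = core_starts(m, fifteen_mers),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full synthetic-cohort pipeline
#'
#' Simulates a cohort, prioritizes the index patient's neoepitope candidates
#' (expression filter, wt/mut kernel similarity, group assignment, in-group
#' sorting, screening pools, class II window selection), scores the
#' immunomonitoring readouts (ELISPOT scores and heat-map bins, DTH scores,
#' DTH-ELISPOT Pearson correlation, specific lysis, TMB), and writes every
#' table as TSV under `outdir`. Fully deterministic under a fixed seed: two
#' runs with the same seed produce byte-identical outputs.
#'
#' @param seed Global seed.
#' @param outdir Output directory (created; existing files overwritten).
#' @param config Optional [cohort_config()] (defaults to
#'   `cohort_config(seed = seed)`).
#' @param tpm_threshold Expression filter cutoff (TPM).
#' @param thresholds A [neo_thresholds()] object.
#' @return Invisible list with all intermediate and final tables.
#' @export
run_pipeline <- function(seed = 1L, outdir = NULL, config = NULL,
                         tpm_threshold = 0.1,
                         thresholds = neo_thresholds()) {
  if (is.null(config)) config <- cohort_config(seed = seed)
  sim <- simulate_cohort(config)

  pairs <- expression_filter(sim$pairs, tpm_threshold, mode = "filter")
  pairs <- pair_similarity(pairs)
  cands <- candidate_table(pairs, sim$ranks, config$class_i_alleles,
                           thresholds)
  cands <- sort_candidates(cands)

  a_pep <- cands$mut_peptide[cands$group == "A"]
  b_pep <- cands$mut_peptide[cands$group == "B"]
  pools <- rbind(
    if (length(a_pep)) make_pools(a_pep, pool_size = 9, prefix = "A"),
    if (length(b_pep)) make_pools(b_pep, pool_size = 6, prefix = "B"))

  # class II check for the top planted-immunogenic neoepitope
  imm_pairs <- sim$truth$pair_id[sim$truth$immunogenic]
  classii <- NULL
  if (length(imm_pairs)) {
    top <- cands[cands$pair_id %in% imm_pairs, , drop = FALSE][1, ]
    vi <- match(top$variant_id, sim$variants$variant_id)
    mut_prot <- mutate_protein(sim$proteins[[sim$variants$protein_id[vi]]],
                               sim$variants[vi, ])
    win <- fifteen_mer_windows(top$mut_peptide, mut_prot)
    cii_ranks <- mock_class_ii_ranks(win$fifteen_mer,
                                     config$class_ii_alleles, seed = seed)
    classii <- select_class_ii(top$mut_peptide, mut_prot, cii_ranks,
                               thresholds)
  }

  heat <- normalize_spots(sim$elispot, censor_limit = config$censor_limit)
  heat$positive <- call_positive(heat$norm_raw, heat$background)
  heat$bin <- heatmap_bin(heat$value, heat$positive)
  dth_scores <- score_dth(sim$dth)
  corr <- correlate_scores(dth_scores, sim$elispot_scores)
  lysis_scores <- score_lysis(sim$lysis)
  burden <- tmb(config$n_substitutions, config$n_indels, config$exome_mb)

  res <- list(config = config, sim = sim, pairs = pairs, candidates = cands,
              pools = pools, classii = classii, heatmap = heat,
              elispot_scores = sim$elispot_scores, dth_scores = dth_scores,
              correlation = corr, lysis_scores = lysis_scores, tmb = burden)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_cohort(sim, file.path(outdir, "sim"))
    write_tsv(cands, file.path(outdir, "candidates.tsv"))
    if (!is.null(pools)) write_tsv(pools, file.path(outdir, "pools.tsv"))
    if (!is.null(classii)) write_tsv(classii, file.path(outdir, "classii.tsv"))
    write_tsv(heat, file.path(outdir, "heatmap.tsv"))
    write_tsv(sim$elispot_scores, file.path(outdir, "elispot_scores.tsv"))
    write_tsv(dth_scores, file.path(outdir, "dth_scores.tsv"))
    write_tsv(data.frame(r = corr$r, p_value = corr$p_value, n = corr$n,
                         tmb = burden),
              file.path(outdir, "summary.tsv"))
    write_tsv(lysis_scores, file.path(outdir, "lysis_scores.tsv"))
  }
  invisible(res)
}

# apply a missense variant to its protein sequence (the mutant proteome is
# the substrate in which class II windows around the neoepitope live)
mutate_protein <- function(protein, variant) {
  p <- as.integer(variant$protein_pos)
  if (substr(protein, p, p) != variant$aa_ref) {
    stop("aa_ref mismatch applying variant ", variant$variant_id)
  }
  substr(protein, p, p) <- variant$aa_alt
  protein
}
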