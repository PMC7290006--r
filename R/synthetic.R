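#' Synthetic cohort configuration
#'
#' All planted parameters of the synthetic vaccine-trial cohort. Defaults
#' mirror the study conditions the pipeline is built for: 13 patients sampled
#' at 4 timepoints (PRE, P1, P2, P3), ~10 tumor-associated antigens tested
#' per patient, one index patient carrying a sequenced tumor mutanome with
#' planted candidate groups of 49 A, 24 B and 9 NEGATIVE peptides (9 of
#' group A immunogenic), a latent DTH-ELISPOT correlation of 0.7, ELISPOT
#' counts right-censored at 350 spots/well, and a mutation load of 400
#' substitutions plus 44 indels over a 30 Mb exome (TMB 14.8).
#'
#' @param seed Global integer seed; expanded into independent per-stream
#'   seeds (mutanome, ranks, elispot, dth, lysis) so stages can be
#'   regenerated in isolation.
#' @param n_patients Number of patients.
#' @param timepoints Sampling timepoints, in chronological order.
#' @param n_antigens Antigens tested per patient in ELISPOT.
#' @param immunogenic_fraction Fraction of tested antigens with a planted
#'   vaccine-induced response.
#' @param n_variants Missense variants in the index patient's mutanome.
#' @param protein_length_range Range (min, max) of synthetic protein lengths.
#' @param peptide_lengths Peptide lengths enumerated per variant.
#' @param planted Named counts `c(A = , B = , NEGATIVE = )` of planted
#'   candidate groups among the index patient's variants.
#' @param n_immunogenic Planted immunogenic group A candidates.
#' @param tpm_meanlog,tpm_sdlog Log-normal TPM distribution parameters.
#' @param tpm_zero_fraction Fraction of filler variants with zero expression
#'   (exercise the expression filter).
#' @param background_rate Mean unstimulated spots/well.
#' @param effect_size Added mean spots/well at the final timepoint for an
#'   immunogenic antigen (response ramps linearly PRE -> P3).
#' @param nb_dispersion Negative-binomial size parameter of spot counts
#'   (smaller = more overdispersed).
#' @param effector_cells Effector cells seeded per well.
#' @param censor_limit Maximum quantification limit, spots/well.
#' @param n_replicates ELISPOT replicate wells per condition.
#' @param rho Latent DTH-ELISPOT correlation.
#' @param class_i_alleles,class_ii_alleles Patient HLA allele names.
#' @param lysis_lmax,lysis_k Saturating lysis dose-response: maximal percent
#'   lysis and the E:T ratio of half saturation (default gives exactly 50%
#'   at 10:1).
#' @param lysis_timepoint_scale Named per-timepoint scaling of the lysis
#'   curve (vaccine responses mature over the protocol).
#' @param lysis_stim_scale Named per-stimulation scaling.
#' @param lysis_spont,lysis_max Spontaneous and maximum (detergent) release
#'   fluorescence means.
#' @param lysis_noise_sd Fluorescence noise SD (0 = noiseless).
#' @param et_ratios Effector:target ratios assayed.
#' @param n_substitutions,n_indels,exome_mb Somatic mutation totals and
#'   exome size for the TMB computation.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(seed = 1L,
                          n_patients = 13L,
                          timepoints = c("PRE", "P1", "P2", "P3"),
                          n_antigens = 10L,
                          immunogenic_fraction = 0.5,
                          n_variants = 150L,
                          protein_length_range = c(120L, 400L),
                          peptide_lengths = 8:11,
                          planted = c(A = 49L, B = 24L, NEGATIVE = 9L),
                          n_immunogenic = 9L,
                          tpm_meanlog = 2, tpm_sdlog = 1.5,
                          tpm_zero_fraction = 0.15,
                          background_rate = 10,
                          effect_size = 110,
                          nb_dispersion = 8,
                          effector_cells = 4e4,
                          censor_limit = 350L,
                          n_replicates = 3L,
                          rho = 0.7,
                          class_i_alleles = c("HLA-A*11:01", "HLA-A*02:01",
                                              "HLA-B*07:02", "HLA-B*40:01",
                                              "HLA-C*03:04", "HLA-C*07:01"),
                          class_ii_alleles = c("DRB1*04:01", "DRB1*07:01",
                                               "DQB1*03:02", "DPB1*04:01"),
                          lysis_lmax = 60, lysis_k = 2,
                          lysis_timepoint_scale = c(PRE = 0.1, P1 = 0.5,
                                                    P2 = 0.9, P3 = 1.0),
                          lysis_stim_scale = c(vaccine_lysate = 1.0,
                                               tumor_lysate = 0.95,
                                               neoag_pool = 0.3),
                          lysis_spont = 100, lysis_max = 600,
                          lysis_noise_sd = 0,
                          et_ratios = c(50, 25, 10, 5, 1),
                          n_substitutions = 400L, n_indels = 44L,
                          exome_mb = 30) {
  cfg <- as.list(environment())
  stopifnot(all(cfg$planted >= 0), abs(cfg$rho) <= 1, cfg$censor_limit > 0,
            cfg$n_variants >= sum(cfg$planted))
  class(cfg) <- "cohort_config"
  cfg
}

#' Simulate the index patient's mutanome
#'
#' Generates one synthetic protein per missense variant (residues drawn from
#' the background frequency model) and the matching annotated variant table.
#' Variant roles are pre-assigned in planting order (A, B, NEGATIVE, filler);
#' group B variants receive the most dissimilar substitution (lowest BLOSUM62
#' score against the reference residue) so their wt/mut kernel similarity is
#' forced low, the others a random different residue. Planted variants are
#' always expressed above the filter threshold; a fraction of filler
#' variants gets zero TPM.
#'
#' @param config A [cohort_config()].
#' @return List `proteins` (named character vector), `variants` (annotated
#'   variant data.frame), `roles` (data.frame `variant_id`, `role`).
#' @export
simulate_mutanome <- function(config) {
  set.seed(derive_seed(config$seed, "mutanome"))
  n <- config$n_variants
  aa <- aa_alphabet()
  freqs <- aa_background_freqs()
  e <- new.env(parent = emptyenv())
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  blosum <- e$BLOSUM62[aa, aa]
  lens <- sample(seq(config$protein_length_range[1],
                     config$protein_length_range[2]), n, replace = TRUE)
  roles <- rep("filler", n)
  k <- 0L
  for (g in names(config$planted)) {
    cnt <- config$planted[[g]]
    if (cnt > 0) roles[(k + 1L):(k + cnt)] <- g
    k <- k + cnt
  }
  if (n == 0L) {
    variants <- validate_variants(
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), gene = character(),
                 protein_id = character(), protein_pos = integer(),
                 aa_ref = character(), aa_alt = character(), tpm = numeric(),
                 variant_class = character(), stringsAsFactors = FALSE))
    return(list(proteins = stats::setNames(character(0), character(0)),
                variants = variants,
                roles = data.frame(variant_id = character(),
                                   role = character(),
                                   stringsAsFactors = FALSE)))
  }
  proteins <- character(n)
  rows <- vector("list", n)
  margin <- max(config$peptide_lengths) + 6L
  for (i in seq_len(n)) {
    seq_i <- paste(sample(aa, lens[i], replace = TRUE, prob = freqs),
                   collapse = "")
    pos <- sample(seq(margin, lens[i] - margin), 1L)
    ref <- substr(seq_i, pos, pos)
    alt <- if (roles[i] == "B") {
      aa[which.min(blosum[ref, ] + 1000 * (aa == ref))]
    } else {
      sample(setdiff(aa, ref), 1L)
    }
    tpm_i <- if (roles[i] == "filler" && stats::runif(1) < config$tpm_zero_fraction) {
      0
    } else {
      max(0.2, stats::rlnorm(1, config$tpm_meanlog, config$tpm_sdlog))
    }
    pid <- sprintf("PROT%04d", i)
    proteins[i] <- seq_i
    rows[[i]] <- data.frame(chrom = sprintf("chr%d", 1L + (i %% 22L)),
                            pos = 1000L * i, ref = "A", alt = "T",
                            gene = sprintf("GENE%04d", i), protein_id = pid,
                            protein_pos = pos, aa_ref = ref, aa_alt = alt,
                            tpm = tpm_i, variant_class = "substitution",
                            stringsAsFactors = FALSE)
  }
  names(proteins) <- sprintf("PROT%04d", seq_len(n))
  variants <- validate_variants(do.call(rbind, rows))
  list(proteins = proteins, variants = variants,
       roles = data.frame(variant_id = variants$variant_id, role = roles,
                          stringsAsFactors = FALSE))
}

#' Plant percent ranks realizing the candidate-group structure
#'
#' Chooses one candidate pair per variant (the most central 9-mer window) and
#' draws per-allele percent ranks so the candidate's best mutant/wild-type
#' ranks satisfy its planted group rule: group A mutant < 2 with wild type
#' > 5, group B both < 2, NEGATIVE mutant > 5 with wild type < 2. All other
#' peptides draw ranks inside the unclassifiable zone (2.5-4.5), so in the
#' noiseless regime classification recovers the planted labels exactly.
#'
#' @param config A [cohort_config()].
#' @param pairs Enumerated pair data.frame (see [enumerate_all_pairs()]).
#' @param roles Role sidecar from [simulate_mutanome()].
#' @return List `ranks` (data.frame `peptide`, `allele`, `percent_rank`) and
#'   `truth` (data.frame `pair_id`, `planted_group`, `immunogenic`; one row
#'   per pair, filler pairs labelled `UNCLASSIFIED`).
#' @export
plant_ranks <- function(config, pairs, roles) {
  set.seed(derive_seed(config$seed, "ranks"))
  alleles <- config$class_i_alleles
  n_all <- length(alleles)
  role_of <- stats::setNames(roles$role, roles$variant_id)
  # candidate pair per planted variant: 9-mer with the mutation most central
  planted_ids <- roles$variant_id[roles$role != "filler"]
  cand_pair <- character(0)
  for (vid in planted_ids) {
    sub <- pairs[pairs$variant_id == vid & pairs$length == 9L, , drop = FALSE]
    if (!nrow(sub)) stop("no 9-mer pair available to plant for ", vid)
    cand_pair[vid] <- sub$pair_id[which.min(abs(sub$mut_offset - 5L))]
  }
  if (anyDuplicated(c(pairs$mut_peptide, pairs$wt_peptide)) >
      0.01 * nrow(pairs)) {
    warning("unusually many duplicate peptides across pairs")
  }
  peptides <- unique(c(pairs$mut_peptide, pairs$wt_peptide))
  # default: every peptide sits in the unclassifiable rank zone
  rank_mat <- matrix(stats::runif(length(peptides) * n_all, 2.5, 4.5),
                     nrow = length(peptides),
                     dimnames = list(peptides, alleles))
  draw_strong <- function(k) stats::runif(k, 0.05, 1.95)
  draw_weak <- function(k) stats::runif(k, 5.5, 60)
  set_best <- function(mat, pep, kind) {
    best_allele <- sample(n_all, length(pep), replace = TRUE)
    strong <- kind == "strong"
    # non-best alleles sit well above the weak cutoff either way
    mat[pep, ] <- stats::runif(length(pep) * n_all, 6, 80)
    mat[cbind(match(pep, rownames(mat)), best_allele)] <-
      if (strong) draw_strong(length(pep)) else draw_weak(length(pep))
    mat
  }
  idx <- match(cand_pair, pairs$pair_id)
  grp <- role_of[pairs$variant_id[idx]]
  mut_p <- pairs$mut_peptide[idx]
  wt_p <- pairs$wt_peptide[idx]
  rank_mat <- set_best(rank_mat, mut_p[grp == "A"], "strong")
  rank_mat <- set_best(rank_mat, wt_p[grp == "A"], "weak")
  rank_mat <- set_best(rank_mat, mut_p[grp == "B"], "strong")
  rank_mat <- set_best(rank_mat, wt_p[grp == "B"], "strong")
  rank_mat <- set_best(rank_mat, mut_p[grp == "NEGATIVE"], "weak")
  rank_mat <- set_best(rank_mat, wt_p[grp == "NEGATIVE"], "strong")
  ranks <- data.frame(peptide = rep(peptides, n_all),
                      allele = rep(alleles, each = length(peptides)),
                      percent_rank = as.numeric(rank_mat),
                      stringsAsFactors = FALSE)
  truth <- data.frame(pair_id = pairs$pair_id,
                      planted_group = "UNCLASSIFIED",
                      immunogenic = FALSE, stringsAsFactors = FALSE)
  truth$planted_group[idx] <- unname(grp)
  a_pairs <- cand_pair[names(cand_pair) %in%
                         roles$variant_id[roles$role == "A"]]
  imm <- utils::head(a_pairs, config$n_immunogenic)
  truth$immunogenic[truth$pair_id %in% imm] <- TRUE
  list(ranks = ranks, truth = truth)
}

#' Add Gaussian noise to a percent-rank table
#'
#' @param ranks Rank data.frame (`percent_rank` column).
#' @param sigma Noise SD in percent-rank units.
#' @param seed Seed for the noise stream.
#' @return The rank table with perturbed ranks, clamped to \[0, 100\].
#' @export
perturb_ranks <- function(ranks, sigma, seed = 1L) {
  set.seed(derive_seed(seed, "noise"))
  ranks$percent_rank <- pmin(100, pmax(0, ranks$percent_rank +
                                         stats::rnorm(nrow(ranks), 0, sigma)))
  ranks
}

#' Simulate ELISPOT plates for the whole cohort
#'
#' Triplicate negative-binomial spot counts per (patient, timepoint,
#' antigen). Immunogenic antigens ramp linearly from the background mean at
#' PRE to background + `effect_size` at the final timepoint;
#' non-immunogenic antigens stay at background. Counts are right-censored at
#' the quantification limit. Unstimulated control wells (antigen `"NONE"`)
#' are emitted per patient-timepoint.
#'
#' @param config A [cohort_config()].
#' @return List `plate` (well-level data.frame) and `antigen_truth`
#'   (data.frame `patient`, `antigen`, `immunogenic`).
#' @export
simulate_elispot <- function(config) {
  set.seed(derive_seed(config$seed, "elispot"))
  tps <- config$timepoints
  n_tp <- length(tps)
  patients <- sprintf("PT%03d", seq_len(config$n_patients))
  antigens <- sprintf("AG%02d", seq_len(config$n_antigens))
  n_imm <- round(config$immunogenic_fraction * config$n_antigens)
  truth <- do.call(rbind, lapply(patients, function(p) {
    data.frame(patient = p, antigen = antigens,
               immunogenic = seq_along(antigens) %in%
                 sample(seq_along(antigens), n_imm),
               stringsAsFactors = FALSE)
  }))
  ramp <- (seq_len(n_tp) - 1) / (n_tp - 1)
  grid <- expand.grid(patient = patients, timepoint = tps,
                      antigen = c(antigens, "NONE"),
                      well = seq_len(config$n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$patient, grid$timepoint, grid$antigen, grid$well), ]
  imm <- truth$immunogenic[match(paste(grid$patient, grid$antigen),
                                 paste(truth$patient, truth$antigen))]
  imm[grid$antigen == "NONE"] <- FALSE
  mu <- config$background_rate +
    ifelse(imm, config$effect_size * ramp[match(grid$timepoint, tps)], 0)
  grid$spots <- pmin(stats::rnbinom(nrow(grid), mu = mu,
                                    size = config$nb_dispersion),
                     config$censor_limit)
  grid$effector_cells <- config$effector_cells
  rownames(grid) <- NULL
  list(plate = grid, antigen_truth = truth)
}

#' Simulate DTH readings latently correlated with ELISPOT scores
#'
#' For each (patient, timepoint) the standardized ELISPOT score is combined
#' with independent Gaussian noise into a latent reactivity
#' `z = rho * z_elispot + sqrt(1 - rho^2) * eps` — a linear construction, so
#' the latent's Pearson correlation with the ELISPOT score is `rho`
#' regardless of the score's marginal distribution. The latent maps affinely
#' to a target DTH score (centered at 8, slope 3, clamped to 0..16), which is
#' decomposed into four timed readings whose grades sum to it.
#'
#' @param config A [cohort_config()].
#' @param elispot_scores Data.frame `patient`, `timepoint`, `score` (see
#'   [score_elispot()]).
#' @param seed Optional seed override (defaults to the config's dth stream).
#' @return Reading-level data.frame `patient`, `timepoint`, `hours`,
#'   `lesion_type`, `diameter_cm`.
#' @export
simulate_dth <- function(config, elispot_scores, seed = NULL) {
  set.seed(if (is.null(seed)) derive_seed(config$seed, "dth")
           else derive_seed(seed, "dth"))
  s <- elispot_scores$score
  z_e <- if (stats::sd(s) > 0) (s - mean(s)) / stats::sd(s) else rep(0, length(s))
  rho <- config$rho
  z <- rho * z_e + sqrt(1 - rho^2) * stats::rnorm(length(s))
  target <- as.integer(round(pmin(16, pmax(0, 8 + 3 * z))))
  # representative readings per grade; dth_grade() recovers the grade exactly
  grade_reading <- function(g) {
    switch(as.character(g),
           "0" = c("macular", "0.3"), "1" = c("macular", "0.8"),
           "2" = c("macular", "1.5"), "3" = c("macular", "2.6"),
           "4" = c("papular", "2.6"))
  }
  hours <- c(1L, 24L, 48L, 72L)
  rows <- lapply(seq_along(target), function(i) {
    g <- rep(target[i] %/% 4L, 4L)
    rem <- target[i] %% 4L
    if (rem > 0) g[seq_len(rem)] <- g[seq_len(rem)] + 1L
    rd <- vapply(g, grade_reading, character(2))
    data.frame(patient = elispot_scores$patient[i],
               timepoint = elispot_scores$timepoint[i], hours = hours,
               lesion_type = rd[1, ], diameter_cm = as.numeric(rd[2, ]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate calcein-release fluorescence wells
#'
#' Quadruplicate experimental wells per (stimulation, timepoint, E:T ratio)
#' whose implied specific lysis follows a saturating dose-response
#' `lmax * r / (r + k)` scaled per timepoint and stimulation, plus shared
#' spontaneous and maximum control wells. Maximum release always exceeds
#' spontaneous release.
#'
#' @param config A [cohort_config()].
#' @return Well-level data.frame `stimulation`, `timepoint`, `et_ratio`,
#'   `well_type`, `well`, `fluorescence`.
#' @export
simulate_lysis <- function(config) {
  set.seed(derive_seed(config$seed, "lysis"))
  stims <- names(config$lysis_stim_scale)
  tps <- config$timepoints
  rows <- list()
  for (st in stims) {
    for (tp in tps) {
      sp <- config$lysis_spont
      mx <- config$lysis_max
      rows[[length(rows) + 1L]] <- data.frame(
        stimulation = st, timepoint = tp, et_ratio = NA_real_,
        well_type = rep(c("spontaneous", "maximum"), each = 4L),
        well = rep(1:4, 2L),
        fluorescence = c(sp + stats::rnorm(4, 0, config$lysis_noise_sd),
                         mx + stats::rnorm(4, 0, config$lysis_noise_sd)),
        stringsAsFactors = FALSE)
      for (r in config$et_ratios) {
        frac <- config$lysis_lmax * r / (r + config$lysis_k) / 100 *
          config$lysis_timepoint_scale[[tp]] * config$lysis_stim_scale[[st]]
        expm <- sp + frac * (mx - sp)
        rows[[length(rows) + 1L]] <- data.frame(
          stimulation = st, timepoint = tp, et_ratio = r,
          well_type = "experimental", well = 1:4,
          fluorescence = expm + stats::rnorm(4, 0, config$lysis_noise_sd),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a complete synthetic cohort
#'
#' Runs every generator off one global seed: index-patient mutanome, peptide
#' enumeration, planted percent ranks, cohort ELISPOT plates, correlated DTH
#' readings and lysis wells.
#'
#' @param config A [cohort_config()].
#' @return List `config`, `proteins`, `variants`, `roles`, `pairs`, `ranks`,
#'   `truth`, `elispot`, `antigen_truth`, `elispot_scores`, `dth`, `lysis`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  mut <- simulate_mutanome(config)
  pairs <- enumerate_all_pairs(mut$variants, mut$proteins,
                               config$peptide_lengths)
  planted <- plant_ranks(config, pairs, mut$roles)
  eli <- simulate_elispot(config)
  scores <- score_elispot(eli$plate, censor_limit = config$censor_limit)
  dth <- simulate_dth(config, scores)
  lys <- simulate_lysis(config)
  list(config = config, proteins = mut$proteins, variants = mut$variants,
       roles = mut$roles, pairs = pairs, ranks = planted$ranks,
       truth = planted$truth, elispot = eli$plate,
       antigen_truth = eli$antigen_truth, elispot_scores = scores,
       dth = dth, lysis = lys)
}

#' Write a simulated cohort to a directory of plain-text files
#'
#' @param sim Result of [simulate_cohort()].
#' @param outdir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_fasta_proteins(sim$proteins, file.path(outdir, "proteins.fasta"))
  write_variant_table(sim$variants, file.path(outdir, "variants.tsv"))
  write_tsv(sim$pairs, file.path(outdir, "pairs.tsv"))
  write_rank_table(sim$ranks, file.path(outdir, "ranks.tsv"))
  write_tsv(sim$truth, file.path(outdir, "truth.tsv"))
  write_tsv(sim$elispot, file.path(outdir, "elispot.tsv"))
  write_tsv(sim$dth, file.path(outdir, "dth.tsv"))
  write_tsv(sim$lysis, file.path(outdir, "lysis.tsv"))
  invisible(outdir)
}
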