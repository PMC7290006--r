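# small cohort for unit tests; the full study-scale cohort is exercised in
# the acceptance suite
small_config <- function(seed = 7, planted = c(A = 5L, B = 3L, NEGATIVE = 2L),
                         n_immunogenic = 2L, ...) {
  cohort_config(seed = seed, n_patients = 4, n_antigens = 6,
                n_variants = 20, planted = planted,
                n_immunogenic = n_immunogenic, ...)
}

test_that("mutanome generation is reproducible and internally consistent", {
  cfg <- small_config()
  m1 <- simulate_mutanome(cfg)
  m2 <- simulate_mutanome(cfg)
  expect_identical(m1, m2)
  expect_equal(nrow(m1$variants), 20L)
  expect_equal(nrow(attr(m1$variants, "rejected")), 0L)
  # residue at protein_pos equals aa_ref for every variant
  for (i in seq_len(nrow(m1$variants))) {
    v <- m1$variants[i, ]
    expect_equal(substr(m1$proteins[[v$protein_id]], v$protein_pos,
                        v$protein_pos), v$aa_ref)
    expect_false(v$aa_ref == v$aa_alt)
  }
  m0 <- simulate_mutanome(cohort_config(seed = 7, n_variants = 0,
                                        planted = c(A = 0L, B = 0L,
                                                    NEGATIVE = 0L)))
  expect_equal(nrow(m0$variants), 0L)
})

test_that("planted ranks are recovered exactly in the noiseless regime", {
  cfg <- small_config()
  mut <- simulate_mutanome(cfg)
  pairs <- enumerate_all_pairs(mut$variants, mut$proteins, cfg$peptide_lengths)
  planted <- plant_ranks(cfg, pairs, mut$roles)
  pairs <- pair_similarity(pairs)
  cands <- candidate_table(pairs, planted$ranks, cfg$class_i_alleles)
  m <- merge(cands[, c("pair_id", "group")], planted$truth, by = "pair_id")
  expect_identical(m$group, m$planted_group)
  expect_equal(sum(m$group == "A"), 5L)
  expect_equal(sum(m$group == "B"), 3L)
  expect_equal(sum(m$group == "NEGATIVE"), 2L)
  expect_equal(sum(planted$truth$immunogenic), 2L)

  # plant nothing -> everything unclassified
  cfg0 <- small_config(planted = c(A = 0L, B = 0L, NEGATIVE = 0L),
                       n_immunogenic = 0L)
  mut0 <- simulate_mutanome(cfg0)
  pairs0 <- enumerate_all_pairs(mut0$variants, mut0$proteins,
                                cfg0$peptide_lengths)
  pl0 <- plant_ranks(cfg0, pairs0, mut0$roles)
  pairs0 <- pair_similarity(pairs0)
  c0 <- candidate_table(pairs0, pl0$ranks, cfg0$class_i_alleles)
  expect_true(all(c0$group == "UNCLASSIFIED"))
})

test_that("simulated ELISPOT counts ramp for immunogenic antigens and censor", {
  cfg <- small_config(nb_dispersion = 50)
  sim <- simulate_elispot(cfg)
  expect_true(all(sim$plate$spots <= cfg$censor_limit))
  norm <- normalize_spots(sim$plate, cfg$censor_limit)
  key <- paste(norm$patient, norm$antigen)
  tkey <- paste(sim$antigen_truth$patient, sim$antigen_truth$antigen)
  norm$immunogenic <- sim$antigen_truth$immunogenic[match(key, tkey)]
  avg <- tapply(norm$value, list(norm$timepoint, norm$immunogenic), mean)
  # immunogenic responses grow PRE -> P3; background antigens stay flat
  expect_gt(avg["P3", "TRUE"], avg["PRE", "TRUE"] + 50)
  expect_lt(avg["P3", "FALSE"], 30)

  # means far above the limit censor every replicate
  cfg_hi <- small_config(background_rate = 5000)
  sim_hi <- simulate_elispot(cfg_hi)
  stim <- sim_hi$plate$antigen != "NONE"
  expect_true(mean(sim_hi$plate$spots[stim] == 350) > 0.99)
})

test_that("DTH readings are valid records whose scores track the latent", {
  cfg <- small_config()
  sim <- simulate_elispot(cfg)
  scores <- score_elispot(sim$plate)
  dth <- simulate_dth(cfg, scores)
  expect_equal(nrow(dth), nrow(scores) * 4L)
  expect_true(all(dth$hours %in% c(1, 24, 48, 72)))
  expect_true(all(dth$lesion_type %in% c("macular", "papular")))
  ds <- score_dth(dth)
  expect_true(all(ds$dth_score >= 0 & ds$dth_score <= 16))
  # rho = 1 with the latent construction gives a strong positive sample r
  cfg1 <- small_config(rho = 1)
  d1 <- simulate_dth(cfg1, scores)
  r1 <- correlate_scores(score_dth(d1), scores)
  expect_gt(r1$r, 0.8)
})

test_that("simulated lysis wells invert to the configured dose-response", {
  cfg <- small_config(lysis_noise_sd = 0)
  lys <- simulate_lysis(cfg)
  sc <- score_lysis(lys)
  # noiseless: vaccine-lysate P3 at 10:1 is exactly the curve value, 50%
  got <- sc$specific_lysis_percent[sc$stimulation == "vaccine_lysate" &
                                     sc$timepoint == "P3" & sc$et_ratio == 10]
  expect_equal(got, 50)
  # saturating in E:T ratio
  v3 <- sc[sc$stimulation == "vaccine_lysate" & sc$timepoint == "P3", ]
  v3 <- v3[order(v3$et_ratio), ]
  expect_true(all(diff(v3$specific_lysis_percent) >= 0))
  # spontaneous always below maximum
  sp <- tapply(lys$fluorescence[lys$well_type == "spontaneous"],
               paste(lys$stimulation, lys$timepoint)[lys$well_type == "spontaneous"], mean)
  mx <- tapply(lys$fluorescence[lys$well_type == "maximum"],
               paste(lys$stimulation, lys$timepoint)[lys$well_type == "maximum"], mean)
  expect_true(all(mx > sp))
})

test_that("the whole cohort is deterministic under a fixed seed", {
  s1 <- simulate_cohort(small_config())
  s2 <- simulate_cohort(small_config())
  expect_identical(s1, s2)
  s3 <- simulate_cohort(small_config(seed = 8))
  expect_false(identical(s1$ranks, s3$ranks))
})

test_that("cohort files round-trip through the documented readers", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(small_config())
  write_cohort(sim, dir)
  v <- read_variant_table(file.path(dir, "variants.tsv"))
  expect_equal(nrow(v), nrow(sim$variants))
  p <- read_fasta_proteins(file.path(dir, "proteins.fasta"))
  expect_identical(p, sim$proteins)
  r <- read_rank_table(file.path(dir, "ranks.tsv"))
  expect_equal(nrow(r), nrow(sim$ranks))
  e <- read_elispot_table(file.path(dir, "elispot.tsv"))
  expect_equal(sum(e$spots), sum(sim$elispot$spots))
  d <- read_dth_table(file.path(dir, "dth.tsv"))
  expect_equal(nrow(d), nrow(sim$dth))
  l <- read_lysis_table(file.path(dir, "lysis.tsv"))
  expect_equal(nrow(l), nrow(sim$lysis))
})
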