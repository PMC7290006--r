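test_that("group assignment follows the three published rules", {
  th <- neo_thresholds()
  expect_equal(assign_group(0.5, 8.0, 0.9, th), "A")
  expect_equal(assign_group(1.0, 1.5, 0.5, th), "B")
  expect_equal(assign_group(7.0, 0.8, 0.9, th), "NEGATIVE")
  expect_equal(assign_group(3.0, 3.0, 0.5, th), "UNCLASSIFIED")
  # strict boundaries: rank exactly at a cutoff satisfies neither side
  expect_equal(assign_group(2.0, 8.0, 0.5, th), "UNCLASSIFIED")
  expect_equal(assign_group(0.5, 5.0, 0.5, th), "UNCLASSIFIED")
  # B needs low similarity
  expect_equal(assign_group(1.0, 1.5, 0.99, th), "UNCLASSIFIED")
  expect_error(neo_thresholds(strong_rank = 5, weak_rank = 5), "strong_rank")
})

test_that("sorting is by mutant rank, then group-specific wt rank, then similarity", {
  cands <- data.frame(
    pair_id = c("p1", "p2", "p3", "p4", "p5", "p6"),
    best_mut_rank = c(0.8, 0.2, 0.5, 0.5, 1.0, 1.0),
    best_wt_rank = c(9, 7, 6, 9, 1.5, 1.5),
    similarity = c(0.9, 0.9, 0.9, 0.9, 0.4, 0.2),
    group = c("A", "A", "A", "A", "B", "B"),
    stringsAsFactors = FALSE)
  s <- sort_candidates(cands)
  # group A first, ascending mut rank; ties broken by poorer (higher) wt rank
  expect_equal(s$pair_id[1:4], c("p2", "p4", "p3", "p1"))
  # group B ties broken by ascending similarity
  expect_equal(s$pair_id[5:6], c("p6", "p5"))
  expect_equal(s$rank_in_group[s$group == "A"], 1:4)

  # full tie preserves input order (stable)
  tie <- data.frame(pair_id = c("x", "y"), best_mut_rank = 1,
                    best_wt_rank = 8, similarity = 0.5, group = "A",
                    stringsAsFactors = FALSE)
  expect_equal(sort_candidates(tie)$pair_id, c("x", "y"))
})

test_that("pools are contiguous, near-equal and conserve the peptide count", {
  p49 <- sprintf("PEP%02d", 1:49)
  pools <- make_pools(p49, n_pools = 6, prefix = "A")
  sizes <- as.integer(table(factor(pools$pool_id, levels = unique(pools$pool_id))))
  expect_equal(sizes, c(9L, 8L, 8L, 8L, 8L, 8L))
  expect_equal(pools$peptide, p49)  # contiguous, in sorted order
  p24 <- sprintf("PEP%02d", 1:24)
  pools4 <- make_pools(p24, n_pools = 4, prefix = "B")
  expect_equal(as.integer(table(pools4$pool_id)), rep(6L, 4))
  expect_equal(nrow(make_pools("only", n_pools = 1)), 1L)
  # pool_size interface used by the pipeline
  expect_equal(length(unique(make_pools(p49, pool_size = 9)$pool_id)), 6L)
})

test_that("candidate table aggregates best-over-alleles ranks", {
  pairs <- data.frame(pair_id = "pr1", mut_peptide = "AAAAAAAAA",
                      wt_peptide = "AAAAAAAAL", similarity = 0.8,
                      stringsAsFactors = FALSE)
  ranks <- expand.grid(peptide = c("AAAAAAAAA", "AAAAAAAAL"),
                       allele = c("a1", "a2"), KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  ranks$percent_rank <- c(0.5, 9, 4, 8)  # mut: 0.5/4 -> best 0.5; wt: 9/8 -> 8
  ct <- candidate_table(pairs, ranks, c("a1", "a2"))
  expect_equal(ct$best_mut_rank, 0.5)
  expect_equal(ct$best_wt_rank, 8)
  expect_equal(ct$group, "A")
  # per-allele mode judges each allele separately
  pa <- candidate_table(pairs, ranks, c("a1", "a2"), aggregate = "per_allele")
  expect_equal(nrow(pa), 2L)
  expect_equal(sort(pa$group), c("A", "UNCLASSIFIED"))
  expect_error(candidate_table(pairs, ranks[c(1, 3), ], c("a1", "a2")),
               "cover")
})

test_that("class II selection applies containment, promiscuity and core rules", {
  # neoepitope of 9 residues centered in a 40-mer protein
  set.seed(31)
  prot <- rand_pep(40)
  ne <- substr(prot, 16, 24)
  win <- fifteen_mer_windows(ne, prot)
  expect_equal(nrow(win), 7L)  # 15 - 9 + 1 placements
  expect_true(all(vapply(win$fifteen_mer, function(w) grepl(ne, w, fixed = TRUE),
                         logical(1))))

  alleles <- c("d1", "d2", "d3")
  grid <- expand.grid(fifteen_mer = win$fifteen_mer, allele = alleles,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # strong everywhere, core fully over the neoepitope
  ne_off <- 16L - win$start + 1L  # neoepitope offset inside each window
  grid$percent_rank <- 0.5
  grid$core_start <- rep(pmin(pmax(ne_off, 1L), 7L), length(alleles))
  sel <- select_class_ii(ne, prot, grid)
  expect_equal(nrow(sel), 7L)
  expect_true(all(sel$n_strong_alleles == 3L))

  # strong binding for exactly 1 allele -> rejected
  g1 <- grid
  g1$percent_rank <- ifelse(g1$allele == "d1", 0.5, 50)
  expect_equal(nrow(select_class_ii(ne, prot, g1)), 0L)

  # every core shifted so exactly 6 neoepitope residues are covered -> all
  # windows rejected (both 9-mers overlap in |9 - shift| residues; shift 3)
  g2 <- grid
  g2$core_start <- rep(ifelse(ne_off <= 4L, ne_off + 3L, ne_off - 3L),
                       length(alleles))
  expect_equal(nrow(select_class_ii(ne, prot, g2)), 0L)

  expect_error(select_class_ii("WWWWWWWWW", prot, grid), "not found")
})
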