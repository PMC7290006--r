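make_variant <- function(protein, pos, alt, tpm = 5) {
  list(variant_id = "V1", protein_id = "P1", protein_pos = pos,
       aa_ref = substr(protein, pos, pos), aa_alt = alt, tpm = tpm)
}

test_that("window enumeration matches placement counts at interior and termini", {
  set.seed(11)
  prot <- rand_pep(60)
  v <- make_variant(prot, 30, "W")
  expect_equal(nrow(enumerate_pairs(v, prot, lengths = 9)), 9L)
  expect_equal(nrow(enumerate_pairs(v, prot, lengths = 8:11)), 38L)
  v1 <- make_variant(prot, 1, "W")
  expect_equal(nrow(enumerate_pairs(v1, prot, lengths = 9)), 1L)
  vend <- make_variant(prot, 60, "W")
  expect_equal(nrow(enumerate_pairs(vend, prot, lengths = 9)), 1L)
})

test_that("every enumerated pair differs exactly at the mutation offset", {
  set.seed(12)
  prot <- rand_pep(80)
  v <- make_variant(prot, 40, "W")
  pairs <- enumerate_pairs(v, prot, lengths = 8:11)
  expect_true(all(nchar(pairs$mut_peptide) == pairs$length))
  expect_true(all(nchar(pairs$wt_peptide) == pairs$length))
  for (i in seq_len(nrow(pairs))) {
    diffs <- which(strsplit(pairs$mut_peptide[i], "")[[1]] !=
                     strsplit(pairs$wt_peptide[i], "")[[1]])
    expect_equal(diffs, pairs$mut_offset[i])
    expect_equal(substr(pairs$mut_peptide[i], pairs$mut_offset[i],
                        pairs$mut_offset[i]), "W")
  }
})

test_that("enumeration agrees with the brute-force sliding-window oracle", {
  set.seed(13)
  for (rep in 1:40) {
    N <- sample(12:120, 1)
    p <- sample(N, 1)
    prot <- rand_pep(N)
    ref <- substr(prot, p, p)
    alt <- sample(setdiff(aa_alphabet(), ref), 1)
    lengths <- sample(8:11, sample(1:4, 1))
    v <- list(variant_id = "V", protein_id = "P", protein_pos = p,
              aa_ref = ref, aa_alt = alt, tpm = 1)
    got <- enumerate_pairs(v, prot, lengths = lengths)
    want <- unlist(lapply(sort(lengths),
                          function(L) enumerate_bruteforce(prot, p, alt, L)))
    expect_equal(got$mut_peptide, want)
    expect_equal(nrow(got) + attr(got, "dropped_nonstandard"),
                 window_count_closed_form(N, p, sort(lengths)))
  }
})

test_that("aa_ref mismatch and out-of-range positions are errors", {
  prot <- "ACDEFGHIKLMNPQRSTVWY"
  v <- list(variant_id = "V", protein_id = "P", protein_pos = 3,
            aa_ref = "E", aa_alt = "W", tpm = 1)
  expect_error(enumerate_pairs(v, prot), "aa_ref")
  v$protein_pos <- 99
  expect_error(enumerate_pairs(v, prot), "outside")
})

test_that("windows containing nonstandard residues are dropped with a count", {
  prot <- paste0(strrep("A", 20), "X", strrep("L", 20))
  v <- list(variant_id = "V", protein_id = "P", protein_pos = 18,
            aa_ref = "A", aa_alt = "W", tpm = 1)
  got <- enumerate_pairs(v, prot, lengths = 9)
  expect_true(all(!grepl("X", got$wt_peptide)))
  expect_equal(nrow(got) + attr(got, "dropped_nonstandard"), 9L)
  expect_gt(attr(got, "dropped_nonstandard"), 0L)
})

test_that("expression filter retains by TPM threshold and records decisions", {
  pairs <- data.frame(pair_id = c("a", "b", "c"),
                      tpm = c(5.0, 0.0, 0.1), stringsAsFactors = FALSE)
  kept <- expression_filter(pairs, 0.1)
  expect_equal(kept$pair_id, c("a", "c"))
  ann <- expression_filter(pairs, 0.1, mode = "annotate")
  expect_equal(ann$retained, c(TRUE, FALSE, TRUE))
  expect_equal(nrow(expression_filter(pairs, 0)), 3L)
  expect_error(expression_filter(pairs, -1), ">= 0")
})
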