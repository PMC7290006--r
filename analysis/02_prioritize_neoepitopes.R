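#!/usr/bin/env Rscript

# Step 2 — prioritize the index patient's neoepitope candidates.
#
# Reads the simulated mutanome and percent-rank table from step 1, applies
# the expression filter, computes the wt/mut kernel similarity, classifies
# candidates into groups A / B / NEGATIVE, sorts within groups, and builds
# the ELISPOT screening pools (group A in pools of up to 9 peptides, group B
# in pools of up to 6, mirroring the screening design the scores in step 3
# assume).

suppressMessages(library(neoprior))

simdir <- file.path("results", "sim")
cfg <- cohort_config(seed = 1L)

variants <- read_variant_table(file.path(simdir, "variants.tsv"))
proteins <- read_fasta_proteins(file.path(simdir, "proteins.fasta"))
ranks <- read_rank_table(file.path(simdir, "ranks.tsv"))

pairs <- enumerate_all_pairs(variants, proteins, cfg$peptide_lengths)
pairs <- expression_filter(pairs, tpm_threshold = 0.1)
pairs <- pair_similarity(pairs)
cands <- sort_candidates(candidate_table(pairs, ranks, cfg$class_i_alleles))

message("candidates by group:")
print(table(cands$group))

a_pep <- cands$mut_peptide[cands$group == "A"]
b_pep <- cands$mut_peptide[cands$group == "B"]
pools <- rbind(make_pools(a_pep, pool_size = 9, prefix = "A"),
               make_pools(b_pep, pool_size = 6, prefix = "B"))
message("screening pools: ", length(unique(pools$pool_id)),
        " (sizes ", paste(range(table(pools$pool_id)), collapse = "-"), ")")

write.table(cands, file.path("results", "candidates.tsv"), sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
write.table(pools, file.path("results", "pools.tsv"), sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
message("wrote results/candidates.tsv and results/pools.tsv")
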