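#!/usr/bin/env Rscript

# Step 1 — generate the synthetic vaccine-trial cohort.
#
# 13 patients sampled at PRE/P1/P2/P3, each tested against ~10 antigens by
# IFNg ELISPOT; one index patient carries a sequenced tumor mutanome with a
# planted candidate structure (49 group A, 24 group B, 9 negative-control
# peptides, 9 of group A immunogenic), DTH readings latently correlated with
# the ELISPOT response (rho = 0.7), and calcein-release lysis assays.
# All downstream steps read the plain-text tables written here.

suppressMessages(library(neoprior))

seed <- 1L
outdir <- file.path("results", "sim")

cfg <- cohort_config(seed = seed)
sim <- simulate_cohort(cfg)
write_cohort(sim, outdir)

message("cohort written to ", outdir)
message("  variants (index patient): ", nrow(sim$variants))
message("  enumerated wt/mut pairs:  ", nrow(sim$pairs))
message("  planted groups:           ",
        paste(names(cfg$planted), cfg$planted, collapse = ", "))
message("  ELISPOT wells:            ", nrow(sim$elispot),
        " (censored at ", cfg$censor_limit, " spots/well)")
message("  DTH readings:             ", nrow(sim$dth))
message("  lysis wells:              ", nrow(sim$lysis))
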