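#!/usr/bin/env Rscript

# Step 3 — score the immunomonitoring readouts.
#
# ELISPOT plates are normalized to spots per 1e5 effector cells with
# per-timepoint background subtraction, responses are called with the
# excess rule (>= background + 10 and >= 2x background), and each
# patient-timepoint gets the response score (magnitude + diversity) plus
# display heat-map bins. DTH readings are graded on the erythema scale and
# summed, lysis wells are converted to specific lysis, and the index
# patient's TMB is computed from the simulated mutation load.

suppressMessages(library(neoprior))

simdir <- file.path("results", "sim")
cfg <- cohort_config(seed = 1L)

plate <- read_elispot_table(file.path(simdir, "elispot.tsv"))
scores <- score_elispot(plate, censor_limit = cfg$censor_limit)
heat <- normalize_spots(plate, censor_limit = cfg$censor_limit)
heat$positive <- call_positive(heat$norm_raw, heat$background)
heat$bin <- heatmap_bin(heat$value, heat$positive)

dth <- read_dth_table(file.path(simdir, "dth.tsv"))
dth_scores <- score_dth(dth)

lysis <- read_lysis_table(file.path(simdir, "lysis.tsv"))
lysis_scores <- score_lysis(lysis)

burden <- tmb(cfg$n_substitutions, cfg$n_indels, cfg$exome_mb)

message("mean ELISPOT score by timepoint:")
print(round(tapply(scores$score, scores$timepoint, mean), 1))
message("mean DTH score by timepoint:")
print(round(tapply(dth_scores$dth_score, dth_scores$timepoint, mean), 1))
v10 <- lysis_scores[lysis_scores$stimulation == "vaccine_lysate" &
                      lysis_scores$et_ratio == 10, ]
message("vaccine-lysate specific lysis at 10:1, PRE->P3: ",
        paste(round(v10$specific_lysis_percent[match(cfg$timepoints,
                                                     v10$timepoint)], 1),
              collapse = " / "), " %")
message("index patient TMB: ", round(burden, 1), " mutations/Mb")

write.table(scores, file.path("results", "elispot_scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
write.table(heat, file.path("results", "heatmap.tsv"), sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
write.table(dth_scores, file.path("results", "dth_scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
write.table(lysis_scores, file.path("results", "lysis_scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
message("wrote results/{elispot_scores,heatmap,dth_scores,lysis_scores}.tsv")
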