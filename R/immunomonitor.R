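#' Normalize ELISPOT plates to spots per 1e5 effector cells
#'
#' Aggregates replicate wells per (patient, timepoint, antigen): the
#' replicate mean is scaled to 1e5 effector cells, and the timepoint
#' background — the average of the unstimulated control wells (antigen
#' `"NONE"`), scaled the same way — is subtracted, flooring at 0. Any
#' replicate at or above the quantification limit flags the value as
#' censored (a lower bound, reported as ">=").
#'
#' @param plate Well-level data.frame (see [read_elispot_table()]).
#' @param censor_limit Maximum quantification limit in spots/well
#'   (default 350).
#' @return Data.frame per (patient, timepoint, antigen): `mean_spots`,
#'   `sd_spots` (raw well scale), `norm_raw` (spots/1e5, before background),
#'   `background` (spots/1e5), `value` (background-subtracted, floored at 0),
#'   `censored`.
#' @export
normalize_spots <- function(plate, censor_limit = 350) {
  stim <- plate[plate$antigen != "NONE", , drop = FALSE]
  ctrl <- plate[plate$antigen == "NONE", , drop = FALSE]
  if (!nrow(stim)) stop("no stimulated wells")
  bg_key <- paste(ctrl$patient, ctrl$timepoint, sep = "\r")
  bg_norm <- tapply(ctrl$spots * 1e5 / ctrl$effector_cells, bg_key, mean)
  key <- paste(stim$patient, stim$timepoint, stim$antigen, sep = "\r")
  agg <- function(x, f) as.numeric(tapply(x, key, f))
  # tapply returns groups in sorted-key order; build the frame the same way
  skey <- sort(unique(key))
  parts <- do.call(rbind, strsplit(skey, "\r", fixed = TRUE))
  out <- data.frame(patient = parts[, 1], timepoint = parts[, 2],
                    antigen = parts[, 3], stringsAsFactors = FALSE)
  out$mean_spots <- agg(stim$spots, mean)
  out$sd_spots <- agg(stim$spots, function(x) if (length(x) > 1) stats::sd(x) else 0)
  out$norm_raw <- as.numeric(tapply(stim$spots * 1e5 / stim$effector_cells,
                                    key, mean))
  bg <- bg_norm[paste(out$patient, out$timepoint, sep = "\r")]
  if (anyNA(bg)) {
    miss <- unique(paste(out$patient, out$timepoint)[is.na(bg)])
    stop("missing unstimulated control for: ", paste(miss, collapse = ", "))
  }
  out$background <- as.numeric(bg)
  out$value <- pmax(0, out$norm_raw - out$background)
  out$censored <- as.logical(tapply(stim$spots >= censor_limit, key, any))
  rownames(out) <- NULL
  out
}

#' Call an antigen response positive
#'
#' The response rule is an explicit parameter because positivity criteria
#' vary between laboratories. The default `"excess"` rule calls positive when
#' the normalized stimulated value (before background subtraction) is at
#' least `margin` spots/1e5 above background and at least `fold` times the
#' background. The `"fold"` rule uses only the fold criterion.
#'
#' @param norm_raw Normalized stimulated spots/1e5 (before background
#'   subtraction).
#' @param background Timepoint background, spots/1e5.
#' @param rule `"excess"` or `"fold"`.
#' @param margin Additive margin in spots/1e5 (excess rule; default 10).
#' @param fold Fold threshold over background (default 2).
#' @param strict If `TRUE`, boundary equality is not positive.
#' @return Logical vector.
#' @export
call_positive <- function(norm_raw, background, rule = c("excess", "fold"),
                          margin = 10, fold = 2, strict = FALSE) {
  rule <- match.arg(rule)
  cmp <- if (strict) `>` else `>=`
  if (rule == "excess") {
    cmp(norm_raw, background + margin) & cmp(norm_raw, fold * background)
  } else {
    cmp(norm_raw, fold * background)
  }
}

#' IFNg ELISPOT response score
#'
#' `score = magnitude + diversity`, where magnitude is the mean normalized
#' spots/1e5 over the positive antigens (the sum over positive antigens
#' divided by their number) and diversity is the fraction of tested antigens
#' called positive. With no positives the score is 0.
#'
#' @param values Background-subtracted normalized spot values (one per
#'   antigen tested at this patient-timepoint).
#' @param positive Logical vector of positivity calls, same length.
#' @return List `magnitude`, `diversity`, `score`, `n_positive`, `n_tested`.
#' @export
elispot_score <- function(values, positive) {
  n_tested <- length(values)
  if (n_tested == 0) stop("no antigens tested")
  if (length(positive) != n_tested) stop("values/positive length mismatch")
  n_pos <- sum(positive)
  magnitude <- if (n_pos) mean(values[positive]) else 0
  diversity <- n_pos / n_tested
  list(magnitude = magnitude, diversity = diversity,
       score = magnitude + diversity, n_positive = n_pos,
       n_tested = n_tested)
}

#' Score every patient-timepoint of an ELISPOT table
#'
#' Normalizes the plate ([normalize_spots()]), applies the positivity rule
#' ([call_positive()]) and computes the response score ([elispot_score()])
#' for each (patient, timepoint).
#'
#' @inheritParams normalize_spots
#' @param ... Passed to [call_positive()] (rule, margin, fold, strict).
#' @return Data.frame per (patient, timepoint): `magnitude`, `diversity`,
#'   `score`, `n_positive`, `n_tested`, `any_censored`.
#' @export
score_elispot <- function(plate, censor_limit = 350, ...) {
  norm <- normalize_spots(plate, censor_limit = censor_limit)
  norm$positive <- call_positive(norm$norm_raw, norm$background, ...)
  key <- paste(norm$patient, norm$timepoint, sep = "\r")
  skey <- sort(unique(key))
  rows <- lapply(skey, function(k) {
    x <- norm[key == k, , drop = FALSE]
    s <- elispot_score(x$value, x$positive)
    data.frame(patient = x$patient[1], timepoint = x$timepoint[1],
               magnitude = s$magnitude, diversity = s$diversity,
               score = s$score, n_positive = s$n_positive,
               n_tested = s$n_tested, any_censored = any(x$censored),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Heat-map intensity bin for a normalized spot value
#'
#' Bins the mean spots/1e5 of a positive response into the display scale
#' 0-4: 0 for non-positive responses, then half-open bins `(0, 175]`,
#' `(175, 350]`, `(350, 525]` and `> 525` (values above 700 also map to 4).
#' Half-open closure resolves the 175/176 boundary deterministically.
#'
#' @param value Normalized spot values (spots/1e5), >= 0.
#' @param positive Logical positivity calls (default all positive).
#' @return Integer vector of bins in 0..4.
#' @export
heatmap_bin <- function(value, positive = TRUE) {
  if (any(value < 0)) stop("negative spot value")
  bin <- findInterval(value, c(175, 350, 525), left.open = TRUE) + 1L
  bin <- pmin(bin, 4L)
  bin[value <= 0] <- 0L
  bin[!positive] <- 0L
  as.integer(bin)
}

#' Grade a DTH skin reading
#'
#' Erythema grading scale: macular lesions grade 0 (< 0.5 cm), 1
#' (0.5-1.0 cm), 2 (> 1.0 to 2.0 cm), 3 (> 2.0 cm); papular lesions > 2.0 cm
#' grade 4. The printed scale leaves papular lesions <= 2.0 cm and the
#' 1.0/1.1 cm boundary open; here papular lesions <= 2.0 cm take the macular
#' grade for that diameter plus one (capped at 4) and are flagged, and the
#' 1.0 cm boundary closes grade 1 (`grade 2 = (1.0, 2.0]`).
#'
#' @param lesion_type `"macular"` or `"papular"` (vectorized).
#' @param diameter_cm Lesion diameter in cm, >= 0.
#' @return Integer vector of grades 0-4 with attribute `flagged` marking
#'   papular readings <= 2.0 cm (graded by extension of the printed scale).
#' @export
dth_grade <- function(lesion_type, diameter_cm) {
  if (any(diameter_cm < 0)) stop("negative diameter")
  if (!all(lesion_type %in% c("macular", "papular"))) {
    stop("lesion_type must be 'macular' or 'papular'")
  }
  mac <- findInterval(diameter_cm, c(0.5, 1.0, 2.0), left.open = TRUE)
  # findInterval with left.open: 0.5 -> 1 (>=0.5), 1.0 -> 1, 1.1 -> 2, 2.0 -> 2, 2.1 -> 3
  mac[diameter_cm >= 0.5 & diameter_cm <= 1.0] <- 1L
  g <- mac
  pap <- lesion_type == "papular"
  g[pap & diameter_cm > 2.0] <- 4L
  flagged <- pap & diameter_cm <= 2.0
  g[flagged] <- pmin(mac[flagged] + 1L, 4L)
  structure(as.integer(g), flagged = flagged)
}

#' DTH score: sum of the four timed reading grades
#'
#' Readings are taken 1, 24, 48 and 72 h after intradermal challenge; the
#' score is the sum of their grades, in 0..16.
#'
#' @param lesion_type,diameter_cm Vectors of length 4 (one reading each), or
#'   a single record's readings in time order.
#' @return Integer score in 0..16.
#' @export
dth_score <- function(lesion_type, diameter_cm) {
  if (length(lesion_type) != 4L) stop("a DTH record has exactly 4 readings")
  sum(dth_grade(lesion_type, diameter_cm))
}

#' Score every patient-timepoint of a DTH reading table
#'
#' @param dth Reading-level data.frame (see [read_dth_table()]).
#' @return Data.frame per (patient, timepoint) with `dth_score`.
#' @export
score_dth <- function(dth) {
  key <- paste(dth$patient, dth$timepoint, sep = "\r")
  skey <- sort(unique(key))
  rows <- lapply(skey, function(k) {
    x <- dth[key == k, , drop = FALSE]
    x <- x[order(x$hours), , drop = FALSE]
    data.frame(patient = x$patient[1], timepoint = x$timepoint[1],
               dth_score = dth_score(x$lesion_type, x$diameter_cm),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation between paired DTH and ELISPOT scores
#'
#' Pairs the two score tables on (patient, timepoint), pooling all patients
#' and timepoints, and reports the Pearson coefficient with its two-sided
#' t-based p value.
#'
#' @param dth_scores Data.frame with `patient`, `timepoint`, `dth_score`.
#' @param elispot_scores Data.frame with `patient`, `timepoint`, `score`.
#' @return List `r`, `p_value`, `n`.
#' @export
correlate_scores <- function(dth_scores, elispot_scores) {
  key_d <- paste(dth_scores$patient, dth_scores$timepoint, sep = "\r")
  key_e <- paste(elispot_scores$patient, elispot_scores$timepoint, sep = "\r")
  idx <- match(key_d, key_e)
  x <- dth_scores$dth_score[!is.na(idx)]
  y <- elispot_scores$score[idx[!is.na(idx)]]
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in a score vector")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Specific lysis from calcein release fluorescence
#'
#' `(experimental - spontaneous) / (maximum - spontaneous) * 100`.
#' Values below 0 or above 100 are reported as-is and flagged.
#'
#' @param experimental,spontaneous,maximum Replicate-mean fluorescence
#'   readings (vectorized; `maximum > spontaneous` required).
#' @return Numeric percent lysis with attribute `flagged` marking values
#'   outside \[0, 100\].
#' @export
specific_lysis <- function(experimental, spontaneous, maximum) {
  if (any(maximum <= spontaneous)) {
    stop("maximum release must exceed spontaneous release")
  }
  pct <- (experimental - spontaneous) / (maximum - spontaneous) * 100
  structure(pct, flagged = pct < 0 | pct > 100)
}

#' Score a calcein-release well table
#'
#' Averages replicate wells per (stimulation, timepoint, E:T ratio) and
#' computes specific lysis against the matching spontaneous and maximum
#' control wells (shared per stimulation x timepoint).
#'
#' @param lysis Well-level data.frame (see [read_lysis_table()]).
#' @return Data.frame per (stimulation, timepoint, et_ratio) with
#'   `specific_lysis_percent`.
#' @export
score_lysis <- function(lysis) {
  ctrl_key <- paste(lysis$stimulation, lysis$timepoint, sep = "\r")
  spont <- tapply(lysis$fluorescence[lysis$well_type == "spontaneous"],
                  ctrl_key[lysis$well_type == "spontaneous"], mean)
  maxr <- tapply(lysis$fluorescence[lysis$well_type == "maximum"],
                 ctrl_key[lysis$well_type == "maximum"], mean)
  ex <- lysis[lysis$well_type == "experimental", , drop = FALSE]
  key <- paste(ex$stimulation, ex$timepoint, ex$et_ratio, sep = "\r")
  skey <- sort(unique(key))
  parts <- do.call(rbind, strsplit(skey, "\r", fixed = TRUE))
  out <- data.frame(stimulation = parts[, 1], timepoint = parts[, 2],
                    et_ratio = as.numeric(parts[, 3]),
                    stringsAsFactors = FALSE)
  expm <- as.numeric(tapply(ex$fluorescence, key, mean))
  ck <- paste(out$stimulation, out$timepoint, sep = "\r")
  out$specific_lysis_percent <- as.numeric(
    specific_lysis(expm, as.numeric(spont[ck]), as.numeric(maxr[ck])))
  rownames(out) <- NULL
  out
}

#' Tumor mutational burden
#'
#' Somatic base substitutions plus indels per megabase of exome examined.
#'
#' @param n_substitutions,n_indels Non-negative mutation counts.
#' @param exome_mb Megabases of exome examined (> 0).
#' @return Mutations per megabase.
#' @export
tmb <- function(n_substitutions, n_indels, exome_mb) {
  if (any(exome_mb <= 0)) stop("exome_mb must be > 0")
  (n_substitutions + n_indels) / exome_mb
}
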