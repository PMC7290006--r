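# Independent oracles, deliberately naive, against which the optimized
# implementations are checked.

# triple-loop k-mer kernel: explicit enumeration of every k-mer pair
kernel_bruteforce <- function(a, b, kmax, submat = blosum62_shifted()) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  total <- 0
  for (k in seq_len(kmax)) {
    if (k > length(av) || k > length(bv)) next
    for (i in seq_len(length(av) - k + 1)) {
      for (j in seq_len(length(bv) - k + 1)) {
        p <- 1
        for (m in seq_len(k)) p <- p * submat[av[i + m - 1], bv[j + m - 1]]
        total <- total + p
      }
    }
  }
  total
}

# literal rule-by-rule transcription of the three group definitions
group_truthtable <- function(mut, wt, sim, strong = 2, weak = 5,
                             low_sim = 0.95) {
  mapply(function(m, w, s) {
    if (m < strong && w > weak) return("A")
    if (m < strong && w < strong && s < low_sim) return("B")
    if (m > weak && w < strong) return("NEGATIVE")
    "UNCLASSIFIED"
  }, mut, wt, sim, USE.NAMES = FALSE)
}

# closed-form window count for a mutation at residue p of an N-residue
# protein: sum over lengths of the number of admissible window starts
window_count_closed_form <- function(N, p, lengths) {
  sum(vapply(lengths, function(L) {
    max(0L, min(p, N - L + 1L) - max(1L, p - L + 1L) + 1L)
  }, integer(1)))
}

# brute-force sliding-window enumeration (independent of enumerate_pairs)
enumerate_bruteforce <- function(protein, p, alt, L) {
  n <- nchar(protein)
  out <- character(0)
  for (s in seq_len(max(0, n - L + 1))) {
    if (s <= p && p <= s + L - 1) {
      w <- substr(protein, s, s + L - 1)
      substr(w, p - s + 1, p - s + 1) <- alt
      out <- c(out, w)
    }
  }
  out
}

# from-scratch Pearson r and two-sided t-based p value
pearson_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r <- sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# random peptide over the standard alphabet
rand_pep <- function(n) paste(sample(aa_alphabet(), n, TRUE), collapse = "")

# well-level ELISPOT plate for one patient/timepoint from per-antigen
# replicate vectors plus control replicates
make_plate <- function(reps_by_antigen, control, patient = "PT001",
                       timepoint = "P1", effector_cells = 4e4) {
  rows <- lapply(names(reps_by_antigen), function(a) {
    data.frame(patient = patient, timepoint = timepoint, antigen = a,
               well = seq_along(reps_by_antigen[[a]]),
               spots = reps_by_antigen[[a]], effector_cells = effector_cells,
               stringsAsFactors = FALSE)
  })
  ctrl <- data.frame(patient = patient, timepoint = timepoint,
                     antigen = "NONE", well = seq_along(control),
                     spots = control, effector_cells = effector_cells,
                     stringsAsFactors = FALSE)
  do.call(rbind, c(rows, list(ctrl)))
}
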