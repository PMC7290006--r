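---
title: "Neoepitope prioritization and vaccine immunomonitoring: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neoepitope prioritization and vaccine immunomonitoring: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoprior)
```

## What the package computes

`neoprior` implements a candidate-selection procedure for tumor neoantigens
(neoAgs) from somatic missense variants, together with the bespoke statistics
used to monitor the immune response in a therapeutic cancer-vaccine trial.
The pipeline has two halves:

1. **Prioritization.** From each annotated missense SNV, every 8–11-mer
   peptide window covering the substituted residue is enumerated as a
   mutant/wild-type (wt) pair. Pairs from unexpressed transcripts are
   filtered out, each peptide receives an HLA class I binding percent rank
   per patient allele, each pair receives an alignment-free kernel
   similarity, and candidates are classified into three groups (below),
   sorted, and packed into ELISPOT screening pools. A class II filter then
   looks for promiscuous strong-binding 15-mers containing a tested
   neoepitope with the mutation anchored in the binding core.

2. **Immunomonitoring.** IFN&gamma;-ELISPOT plates are normalized and
   converted to a response score, DTH (delayed-type hypersensitivity) skin
   readings are graded and summed, the two scores are correlated, the
   calcein-release assay yields percent specific lysis, and tumor mutational
   burden (TMB) is mutations per megabase of exome.

A synthetic-cohort generator makes every stage testable without patient
data: it is first-class, tested code, not a fixture.

## The candidate groups

With `best_mut_rank` / `best_wt_rank` the minimum percent rank of the mutant
/ wt peptide over the patient's class I alleles, and `sim` the normalized
wt/mut kernel similarity:

* **A** — `best_mut_rank < 2` and `best_wt_rank > 5`: the mutation creates
  binding the wt peptide lacks;
* **B** — `best_mut_rank < 2`, `best_wt_rank < 2`, and `sim < 0.95`: both
  bind, but the mutant looks different enough to the TCR;
* **NEGATIVE** (control) — `best_mut_rank > 5` and `best_wt_rank < 2`: the
  mutation destroys binding;
* everything else is **UNCLASSIFIED**.

The `<` and `>` are strict: ranks exactly 2 or exactly 5 satisfy neither
side and fall to UNCLASSIFIED. This is the literal reading of the rules;
both cutoffs are configurable via `neo_thresholds()`. Rules are evaluated
A &rarr; B &rarr; NEGATIVE; with the default thresholds they are mutually
exclusive, so precedence only matters for deliberately inconsistent
configurations.

Within a group, candidates sort by ascending mutant rank, then wt rank —
**descending** in group A, since poorer wt binding is the trait that defines
the group, ascending elsewhere — then ascending similarity; ties keep input
order. The direction of the wt key in group A is a design decision, not a
published fact: the source procedure lists the three sort keys without
directions.

Aggregating ranks as the minimum over the patient's alleles ("best over
alleles") is the default; a per-allele mode, in which each (pair, allele)
combination is judged on its own ranks, is available in
`candidate_table(aggregate = "per_allele")`.

## The kernel similarity

The similarity between wt and mutant peptides uses an alignment-free k-mer
string kernel. For peptides $a, b$ and a non-negative substitution matrix
$S$:

$$K(a,b) = \sum_{k=1}^{k_{\max}} \sum_{i} \sum_{j} \prod_{m=1}^{k}
S(a_{i+m-1}, b_{j+m-1}),$$

normalized as $\mathrm{sim}(a,b) = K(a,b) / \sqrt{K(a,a)\,K(b,b)}$, so
$\mathrm{sim}(a,a) = 1$; distance is $1 - \mathrm{sim}$ (a metric form
$\sqrt{2 - 2\,\mathrm{sim}}$ is available by flag). Defaults:
$k_{\max} = 3$ and BLOSUM62 shifted by its global minimum (+4) so all
entries are non-negative, keeping $K$ positive and the similarity in
$[0, 1]$. This is the established alignment-free peptide kernel of the HLA
prediction literature; the exact constants the original analysis used are
not published, so they are exposed in the API and documented here as this
package's defaults.

Two numerical facts shaped the defaults:

* Under shifted BLOSUM62 with $k_{\max}=3$, a single substitution in a
  9-mer yields similarities of roughly 0.52–0.98 (median ≈ 0.82). The
  `low_similarity` default of 0.95 therefore means "any pair whose
  substitution visibly changes the kernel"; it is deliberately permissive
  and should be tuned per study.
* The normalized similarity is **not** exactly monotone in the substitution
  score $S(\text{ref}, \text{alt})$ — the self-kernel $K(b,b)$ in the
  denominator also moves with the substituted residue, and about 5% of
  substitution pairs invert the order. The test suite therefore checks a
  strong positive rank correlation rather than strict monotonicity.

The optimized kernel (cumulative diagonal products of the residue score
matrix) is verified against a naive triple-loop enumeration to 1e-9.

## The mock binding predictor

Real percent ranks come from external predictors and enter through
`read_rank_table()`. For synthetic cohorts and end-to-end tests,
`mock_allele_model()` provides a deterministic stand-in: a 9×20 PSSM drawn
per allele from a seed derived from the allele name, scored as the sum of
per-position entries (longer peptides: max over 9-mer windows, which for
class II 15-mers also yields the binding-core position). The percent rank
of a peptide is the fraction of a 10,000-peptide background — drawn from
Robinson–Robinson amino-acid frequencies — scoring strictly higher; ties
are not counted (optimistic rank). Ranks of random peptides are uniform on
(0, 100) up to the 1/10,000 background granularity, mirroring the
"%rank among random natural peptides" semantics of real predictors. Mock
scores carry no biological meaning.

## Class II selection

Given a tested neoepitope, all 15-mer windows of the (mutated) source
protein containing it are evaluated. An allele *qualifies* for a window
when its percent rank is `< 2` **and** at least 7 neoepitope residues lie
inside that allele's 9-mer binding core; a window is selected when at least
2 alleles qualify. Tying the core-containment requirement to the same
alleles that bind strongly is a design decision — the published criterion
lists promiscuity, strong binding and core containment without saying
whether they must coincide per allele; requiring coincidence is the
conservative reading.

## Immunomonitoring statistics

**ELISPOT.** Replicate wells are averaged, scaled to spots per $10^5$
effector cells, and the per-timepoint background (mean of unstimulated
control wells, scaled identically) is subtracted, flooring at 0. Counts at
the quantification limit (350 spots/well) flag the value as censored — a
lower bound. The response score is

$$\text{score} = \underbrace{\frac{\sum_{\text{positive Ags}} \text{mean
spots}/10^5}{\#\text{positive Ags}}}_{\text{magnitude}} +
\underbrace{\frac{\#\text{positive}}{\#\text{tested}}}_{\text{diversity}},$$

implemented literally as printed, including the addition of a magnitude in
spots/$10^5$ to a unitless fraction. The positivity rule is not part of the
published score definition, so it is an explicit parameter; the default
"excess" rule calls positive at $\ge$ background + 10 spots/$10^5$ and
$\ge 2\times$ background. Heat-map display bins use half-open intervals
$(0,175], (175,350], (350,525], >525$ — the published legend has a gap
between 175 and 176, which half-open closure resolves deterministically.

The censored-score lower-bound property (enlarging a censored replicate
never decreases the score) holds through the magnitude channel
unconditionally and through the positivity channel whenever a censored
antigen is already positive — true under any realistic background, since a
well at the 350-spot limit towers over background rates of tens of spots.
An adversarial background larger than the censoring limit could flip a
newly positive low-value antigen and lower the magnitude mean; the test
suite exercises the property under 1,000 realistic randomized plates.

**DTH.** Four readings (1, 24, 48, 72 h) are graded 0–4: macular erythema
< 0.5 cm &rarr; 0, 0.5–1.0 &rarr; 1, (1.0, 2.0] &rarr; 2, > 2.0 &rarr; 3,
papular > 2.0 &rarr; 4; the score is the sum (0–16). The published scale is
silent on papular lesions ≤ 2.0 cm and on the 1.0/1.1 cm boundary; a total
function is required, so papular ≤ 2.0 cm takes the macular grade + 1
(capped at 4, flagged), and grade 1 closes at 1.0 cm.

**Correlation.** DTH and ELISPOT scores are paired on (patient, timepoint)
and pooled across the cohort — as in the source analysis — and Pearson's
$r$ with a two-sided t-based $p$ is reported via `stats::cor.test`. Pooling
repeated measures per patient inflates the nominal sample size; this caveat
is inherited from the design being reproduced, documented, and not
"corrected".

**Lysis, TMB.** Specific lysis is
$(E - S)/(M - S) \times 100$ with experimental $E$, spontaneous $S$ and
maximum (detergent) $M$ release; values outside $[0, 100]$ are reported and
flagged. TMB is (substitutions + indels) / exome megabases.

## The synthetic cohort

`cohort_config()` fixes the study conditions the generator emulates:

* 13 patients × 4 timepoints (PRE, P1, P2, P3), ~10 antigens each;
* one index patient with 150 missense variants in synthetic proteins
  (residues from background frequencies, lengths 120–400), planted
  candidate groups of **49 A, 24 B, 9 NEGATIVE** with 9 group A candidates
  immunogenic, and a mutation load of 400 substitutions + 44 indels over a
  30 Mb exome (TMB 14.8);
* triplicate negative-binomial spot counts (size 8 — overdispersion is the
  norm for ELISPOT replicates), background 10 spots/well at 4×10⁴
  effectors, immunogenic antigens ramping linearly to +110 spots/well by
  P3, right-censored at 350;
* DTH readings driven by a latent
  $z = \rho\, z_{\text{ELISPOT}} + \sqrt{1-\rho^2}\,\varepsilon$ with
  $\rho = 0.7$, mapped affinely to a target score ($8 + 3z$, clamped to
  0–16) and decomposed into four readings whose grades sum to it. The
  linear construction keeps the latent's Pearson correlation with the
  observed ELISPOT score at exactly $\rho$ regardless of the score's skewed
  marginal; only the 17-level discretization and rare clamping attenuate
  the sample $r$ (empirically ≈ 0.70 at $n = 52$);
* quadruplicate lysis wells following a saturating dose-response
  $L_{\max} r/(r + k)$ with $L_{\max} = 60$, $k = 2$ — exactly 50% at a
  10:1 effector:target ratio for the fully matured response — scaled per
  timepoint and stimulation (vaccine lysate 1.0, tumor lysate 0.95, neoAg
  pool 0.3).

Rank planting draws the candidate's decisive allele uniformly inside its
rule region (strong: 0.05–1.95; weak: 5.5–60; all other peptides 2.5–4.5),
so noiseless classification recovers the planted labels exactly, and
Gaussian rank noise degrades recovery smoothly — the margins around the
2 and 5 cutoffs are uniformly populated, so misclassification grows
monotonically with the noise SD. Group B variants receive the most
dissimilar substitution (argmin BLOSUM62 against the reference residue),
which keeps their kernel similarity below the 0.95 cutoff (empirical
maximum ≈ 0.93).

One global seed expands into independent per-stream seeds (mutanome, ranks,
ELISPOT, DTH, lysis, mock models, noise), so stages can be regenerated in
isolation and the whole pipeline is byte-identical across runs with the
same seed.

What the generator does **not** emulate: linkage between variants, real HLA
binding motifs (mock PSSMs are random), antigen-processing effects, shared
peptides between patients, plate-position or batch effects, and dropout of
patient samples. Passing tests therefore demonstrate the correctness of the
computations and the recoverability of planted structure — not predictive
accuracy on real tumors.

## Problem sizes and numerical choices

The test and verification runs use: 10,000 random rank triples (with the
boundary ranks 2 and 5 planted) for the grouping truth table; 100 random
pairs of lengths 8–11 at $k_{\max} \le 3$ for kernel-oracle equivalence
(tolerance 1e-9); 200 random instances for the enumeration closed form;
3 seeds × noise SD ∈ {0.5, 1, 2} for planted-recovery degradation; 1,000
randomized plates for the censoring bound; 500 Monte-Carlo replicates at
$n = 52$ pairs for correlation recovery (mean $r$ inside the Fisher-z 95%
band around 0.7; empirical type-I error at $\rho = 0$ within 0.05 ± 0.02);
and 2,000 peptides for the Kolmogorov–Smirnov uniformity check of mock
ranks at $\alpha = 0.01$. These sizes give stable verdicts for all the
checks while keeping a full run in a couple of minutes.

Degenerate inputs are rejected loudly rather than patched: an `aa_ref`
mismatch between variant and protein is an error, as are ranks outside
[0, 100], maximum release not exceeding spontaneous release, zero-variance
score vectors in the correlation, and DTH records without exactly four
readings.

## Known limitations

* The kernel constants ($k_{\max}$, matrix, shift) are this package's
  documented defaults, not recovered from the original analysis; absolute
  similarity values should not be compared across parameterizations.
* The ELISPOT positivity rule is an assumption (explicitly parameterized);
  published positive/negative calls cannot be reproduced without knowing
  the original rule.
* `UNCLASSIFIED` is deliberately large under the default thresholds:
  most real pairs have intermediate ranks and high similarity.
* The pooled DTH–ELISPOT correlation ignores within-patient dependence, by
  design (see above).
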