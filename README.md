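# neoprior

Neoantigen candidate prioritization and vaccine immunomonitoring statistics,
as an R package plus a small analysis workflow.

## The problem

Therapeutic cancer vaccines aim to raise T-cell responses against tumor
antigens. When a patient's tumor is sequenced, somatic missense variants
define candidate *neoepitopes* — mutant peptides that may be presented by
the patient's HLA molecules and recognized as foreign. Only a small
fraction of predicted candidates is immunogenic, so candidates must be
ranked and grouped before expensive wet-lab screening, and the resulting
immune responses must be quantified with assay-specific scores. `neoprior`
is for computational immunologists and trial analysts who need both halves
reproducible: the candidate selection and the immunomonitoring arithmetic.

## The method

**Prioritization.** For each missense SNV, every 8–11-mer window covering
the substituted residue yields a mutant/wild-type (wt) peptide pair.
Pairs from unexpressed transcripts (TPM < 0.1 by default) are removed.
Each peptide gets an HLA class I binding percent rank per patient allele
(lower = stronger; from a precomputed predictor table, or a deterministic
built-in mock predictor for synthetic data), aggregated as the best
(minimum) rank over alleles. Each pair gets an alignment-free k-mer kernel
similarity

    K(a,b) = Σ_{k≤3} Σ_i Σ_j Π_m S(a[i+m], b[j+m]),   sim = K(a,b)/√(K(a,a)K(b,b))

with shifted BLOSUM62, so sim ∈ [0,1] and sim(a,a) = 1. Candidates are
classified:

| group | mutant rank | wt rank | similarity |
|---|---|---|---|
| A | < 2 | > 5 | — |
| B | < 2 | < 2 | < 0.95 |
| NEGATIVE (control) | > 5 | < 2 | — |

sorted within groups (mutant rank, then wt rank — descending in A —, then
similarity) and packed into near-equal screening pools. A class II filter
selects 15-mers containing a tested neoepitope that bind ≥ 2 alleles at
rank < 2 with ≥ 7 neoepitope residues inside the 9-mer binding core.

**Immunomonitoring.** ELISPOT wells are normalized to spots per 1e5
effector cells minus the per-timepoint unstimulated background (censored at
350 spots/well); the response score is *magnitude* (mean spots/1e5 over
positive antigens) + *diversity* (fraction of antigens positive). DTH skin
readings at 1/24/48/72 h are graded 0–4 on the erythema scale and summed
(0–16). The two scores, paired on (patient, timepoint), give a pooled
Pearson correlation. Calcein-release wells give specific lysis
`(E − S)/(M − S) × 100`, and TMB is (substitutions + indels)/Mb.

A synthetic-cohort generator (`simulate_cohort()`) plants all of this
structure — candidate groups, immunogenic antigens with censored
overdispersed counts, a latent DTH–ELISPOT correlation ρ = 0.7, saturating
lysis dose-response, TMB 14.8 — so the full pipeline runs and is tested
without any patient data. See the methods vignette
(`vignettes/neoepitope-prioritization.Rmd`) for model details and design
decisions.

## Worked example

The `analysis/` scripts run the whole workflow on the synthetic cohort and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_prioritize_neoepitopes.R
Rscript analysis/03_score_immunomonitoring.R
Rscript analysis/04_correlate_dth_elispot.R
```

Output (seed 1):

```
candidates by group:
           A            B     NEGATIVE UNCLASSIFIED
          49           24            9         5200
screening pools: 10 (sizes 6-9)
mean ELISPOT score by timepoint:
   P1    P2    P3   PRE
 90.7 178.2 276.8   1.2
mean DTH score by timepoint:
  P1   P2   P3  PRE
 7.7  8.9 10.2  4.5
vaccine-lysate specific lysis at 10:1, PRE->P3: 5 / 25 / 45 / 50 %
index patient TMB: 14.8 mutations/Mb
pooled Pearson r = 0.68 (p = 3.5e-08, n = 52)
mean r over 500 replicates = 0.699 (Fisher-z band 0.528..0.817)
```

Reading: the planted candidate groups (49/24/9) are recovered exactly from
the planted ranks; the ELISPOT score climbs from ~0 at baseline to ~277 at
the 25-month timepoint as planted responses mature; DTH scores climb in
step, and their pooled correlation with the ELISPOT score recovers the
planted latent ρ = 0.7; lysis of target cells by vaccine-boosted effector
cells reaches 50% at a 10:1 effector:target ratio by the final timepoint.

Or in R, end to end:

```r
library(neoprior)
res <- run_pipeline(seed = 1, outdir = "results/full")
table(res$candidates$group)
res$correlation$r   # 0.677
res$tmb             # 14.8
```

## Input formats

Plain UTF-8 TSV with documented headers (`.` = missing): `variants.tsv`
(chrom, pos, ref, alt, gene, protein_id, protein_pos, aa_ref, aa_alt, tpm),
`ranks.tsv` (peptide, allele, percent_rank[, affinity_nM]), `elispot.tsv`
(patient, timepoint, antigen, well, spots, effector_cells; antigen `NONE`
marks unstimulated controls), `dth.tsv` (patient, timepoint, hours,
lesion_type, diameter_cm), `lysis.tsv` (stimulation, timepoint, et_ratio,
well_type, well, fluorescence). Also VCF 4.x (genomic fields only) and
protein FASTA.
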