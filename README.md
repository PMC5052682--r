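# sigimmune

Somatic mutational signatures leave more than a trinucleotide fingerprint:
the substitutions they generate have systematically different protein-level
consequences. APOBEC-type mutagenesis deaminates cytidines in a TCN context,
and by the structure of the genetic code those events are uniquely efficient
at converting the two negatively charged residues — Glu→Lys via C>T, Asp→His
via C>G — into positively charged ones. `sigimmune` is an R package for
testing whether such signature-specific consequences track immune phenotypes
in a tumour cohort: lymphocytic infiltrate, immune and proliferation
gene-expression scores, and survival. It is aimed at cancer-genomics
analysts who have per-sample substitution tables, a signature catalog, and
bulk expression/clinical data, and who want the full chain — attribution,
consequence scoring, phenotype association — as reusable, tested functions.
Because real cohorts of this kind are controlled-access, the package
includes a synthetic-cohort generator with planted effects that makes every
stage runnable and testable offline.

## What it computes

- **96-class context classification** `X[R>A]Y` with strand normalization
  (purine references reverse-complemented).
- **Exposure refitting** against a fixed signature catalog `C` by
  non-negative least squares, `min_{w≥0} ||m − Cw||`, and **per-mutation
  attribution** by maximum posterior `P(s|c,j) ∝ w_j(s) C(c,s)`.
- **Consequence annotation** (standard genetic code), **17-mer mutant
  peptide windows**, enumeration of all mutant-containing 9-mers, and the
  strong-binder rule (any peptide × allele EC50 < 50 nM) behind a pluggable
  MHC predictor interface.
- **Charge and Kyte–Doolittle hydrophobicity deltas** per substitution,
  aggregated per signature and per sample.
- **Gene-set scores** (mean expression), top-quartile and three-group
  TIL/MCC stratification, missingness/variance preprocessing, and
  sample-correlation clustering with uncentred-correlation distance.
- **Statistics**: Mann–Whitney U, Kruskal–Wallis, Cuzick's trend test
  (implemented from its rank-sum formulas, `T = Σ l_i R_i`, tie-corrected
  variance), chi-square/Fisher with the low-expected-count rule,
  Kaplan–Meier with logrank and logrank-trend, Cox proportional hazards.
- **Synthetic cohorts**: coding sequences, toy signature profiles
  (APOBEC C>T/C>G at TCN, age-like C>T at NCG, flat, broad), Dirichlet
  exposures, signature-driven mutations with ground-truth labels, planted
  TIL/MCC expression modules, and clinical tables with planted hazard and
  infiltrate effects.

## Worked example

Simulate a 60-sample cohort, attribute its mutations, and test whether
charge-increasing substitutions of the APOBEC C>G-like signature track the
ordinal lymphocytic infiltrate:

```r
library(sigimmune)

cfg <- cohort_config(n_samples = 60, n_genes = 60, mutations_per_sample = 300,
                     n_transcripts = 150, seed = 11)
co  <- simulate_cohort(cfg)

sp  <- build_spectrum(co$mutations, per_sample = TRUE)
fit <- fit_exposures_all(sp, co$catalog)
att <- attribute_mutations(co$mutations, co$catalog, fit$proportions)
mean(att$assigned_signature == att$true_signature)
#> [1] 0.912

ann <- annotate_coding_consequence(att, co$cds)
pc  <- count_property_changes(ann, per_sample = TRUE)
infl <- setNames(factor(co$clinical$infiltrate, levels = 0:2, ordered = TRUE),
                 co$clinical$sample_id)
charge_increase_trend(pc, infl, "apobec_CtoG")
#> Cuzick trend: statistic = 4254, p = 7.392e-08 (n = 20/20/20)
charge_increase_trend(pc, infl, "ALL", exclude = "apobec_CtoG")
#> Cuzick trend: statistic = 3348, p = 0.00461 (n = 20/20/20)
```

The planted infiltrate effect is recovered (the trend on the attributed
APOBEC C>G charge-increasing counts is strongly significant), and the pooled
trend survives excluding that signature because the C>T APOBEC profile also
generates Glu→Lys charge gains — the mechanism the charge oracle in the test
suite verifies exhaustively.

The expression/survival layer stratifies samples by their TIL and MCC
gene-set scores and contrasts outcomes:

```r
til <- geneset_score(co$expression, co$gene_sets$TIL, "TIL")$score
mcc <- geneset_score(co$expression, co$gene_sets$MCC, "MCC")$score
grp <- til_mcc_groups(til, mcc)
table(grp)
#> grp
#>     high_TIL intermediate     high_MCC
#>           13           34           13

cl <- co$clinical[match(names(til), co$clinical$sample_id), ]
km_logrank(cl$time_months, cl$event, grp, trend = TRUE)
#> logrank trend: statistic = 13.26, p = 0.0002718 (n = 13/34/13)
cox_ph(data.frame(high_TIL = as.integer(quartile_group(til) == "TOP_QUARTILE"),
                  high_MCC = as.integer(quartile_group(mcc) == "TOP_QUARTILE")),
       cl$time_months, cl$event)
#>       term        hr     ci_lo     ci_hi     p_value
#> 1 high_TIL 0.2997403 0.1246779 0.7206109 0.007100927
#> 2 high_MCC 2.1084986 1.0963759 4.0549656 0.025369976
```

High TIL-score samples have a hazard ratio below 1 and high MCC-score
samples above 1, matching the planted effects (−0.7 and +0.7 log-hazard per
score s.d.). `run_pipeline()` composes all of these stages from a single
YAML/list configuration and writes each stage's table plus a checksum
manifest; reruns with the same seed are byte-identical.

## Layout

- `R/` — implementation (contexts, catalog, synthetic generator,
  attribution, consequences, properties, expression, statistics, pipeline).
- `tests/testthat/` — unit, property and acceptance tests; all fixtures are
  generated in code.
- `vignettes/sigimmune-methods.Rmd` — the full methods account: models,
  conventions, parameter defaults and their rationale, generator scope and
  limitations.
- `inst/extdata/aa_properties.tsv` — the bundled amino-acid constants
  (Kyte–Doolittle scale, charge assignment), the single source of both.
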