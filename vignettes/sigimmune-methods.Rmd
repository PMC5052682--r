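---
title: "Methods: from mutational signatures to immune phenotype associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from mutational signatures to immune phenotype associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`sigimmune` links three layers of tumour data: (i) somatic substitutions
attributed to mutational signatures, (ii) the protein-level consequences of
those substitutions (amino-acid charge and hydrophobicity changes, candidate
neo-epitope peptide windows), and (iii) transcriptome-derived phenotypes
(mitotic-cell-cycle and tumour-infiltrating-lymphocyte gene-set scores,
ordinal lymphocytic infiltrate, survival). The cohorts such analyses were
designed for sit behind controlled access, so the package ships a
synthetic-cohort generator that reproduces the statistical structure every
stage assumes; all tests and the acceptance script run on generated data
alone.

# Substitution classes and exposure refitting

Every substitution is mapped to one of the 96 strand-normalized trinucleotide
classes `X[R>A]Y`: the mutated base with its 5' and 3' neighbours, reverse
complemented when the reference base is a purine so that the mutated base is
always reported as a pyrimidine. Class labels are ordered alphabetically
(C locale); that ordering is the canonical row order of every spectrum and
catalog.

Given a fixed catalog \(C \in \mathbb{R}^{96 \times S}\) of signature
profiles (columns sum to 1), per-sample exposures are refit by non-negative
least squares on the raw 96-count spectrum \(m\):

\[\hat w = \arg\min_{w \ge 0} \lVert m - Cw \rVert_2 .\]

NNLS on counts is the standard refitting choice when the de novo extraction
that produced the catalog is out of scope; the fitted weights live on the
count scale (they sum approximately to the number of mutations) and are also
reported normalized. For small problems the optimum is verified in the test
suite against an exhaustive grid search over the exposure simplex.

Each mutation of class \(c\) in sample \(j\) is then attributed to a
signature by maximum posterior,
\(P(s \mid c, j) \propto \hat w_j(s)\, C_{c,s}\).
Hard argmax assignment is used because the downstream analyses count whole
substitutions per signature; the posterior and the runner-up margin are kept
for sensitivity analyses. Exact ties break towards the lowest catalog column
index and are flagged; classes with zero probability under all exposed
signatures receive a uniform posterior over exposed signatures and an
`unresolved` flag.

Sample groupings follow the conventions of signature-phenotype cohort
studies: a "dominant signature" contrast compares samples with at least 50%
of their substitutions attributed to one signature against samples with less
than 20%, and is considered valid only when both groups hold at least 15
cases; a "mutational burden" contrast takes the top and bottom 20% of the
cohort ranked on total substitution count, pooled across strata such as ER
status rather than within them.

# Consequence annotation and neo-epitope windows

Substitutions on synthetic CDS are annotated with the standard genetic code:
codon index \(\lceil p/3 \rceil\), wild-type and mutant residue, and a
consequence class (silent, missense, nonsense, stop_loss, start_loss). Only
missense changes — the "non-silent, non-terminating" set — proceed to
peptide windowing and property scoring.

For each missense change the mutant protein window takes 8 residues on each
side of the mutated position (a 17-mer with the mutant centred), clamped at
the protein ends. A window is kept when at least 9 residues long; proteins
shorter than 9 residues are rejected with a logged reason. All contiguous
9-mers containing the mutant position are enumerated — exactly 9 for a full
17-mer, `len - 8` or fewer for clamped windows. The clamp-and-keep-if-≥9
rule is this package's decision for boundary cases; the keep threshold is
the shortest peptide the class-I binding question makes sense for.

MHC binding itself is external software, so the package defines a predictor
interface `(peptides, allele) -> EC50 (nM)` with three bundled
implementations: a constant stub, a lookup over a (peptide, allele, EC50)
table, and a deterministic arithmetic-hash pseudo-predictor for tests that
need peptide-dependent but reproducible output. The decision rule is fixed:
a substitution harbours a potential neo-epitope when *any* peptide-allele
prediction is strictly below 50 nM (an EC50 of exactly 50 nM is not a strong
binder). The default panel is the ten HLA-A2 alleles most prevalent in
European-ancestry populations, giving at most 9 × 10 = 90 (practically
≤ 80 for typical genes) predictions per substitution.

# Amino-acid property deltas

Charge uses the integer assignment Asp = Glu = −1, Lys = Arg = His = +1, all
other residues 0; histidine is treated as fully positive, ignoring
physiological pKa nuance. The charge delta is charge(mutant) −
charge(wild-type); a positive delta is an "increase". Double steps (Glu→Lys,
delta +2) are classed like single steps with the magnitude retained.

Hydrophobicity uses the Kyte–Doolittle hydropathy scale, bundled as a TSV
(`inst/extdata/aa_properties.tsv`) that is the single source of both scales.
The difference is computed literally as KD(wild-type) − KD(mutant) with a
positive difference labelled "increase". That direction reads
counter-intuitively (a positive value means the *mutant* is less
hydrophobic) but is implemented as stated in the originating analysis
convention; `label_convention = "mutant_minus_wt"` swaps both the sign and
the label for users who prefer the other reading.

A built-in consequence of the genetic code, checked exhaustively over all
576 single-nucleotide codon changes in the test suite: Glu→Lys arises only
from G>A at codon position 1 — on the pyrimidine strand a C>T in a TCN
context — and Asp→His only from G>C at codon position 1, a C>G in a TCN
context. This is exactly why APOBEC-type mutagenesis, which deaminates
cytidines in TCN, is uniquely efficient at generating positively charged
substitutions from the two negatively charged residues.

# Expression scores and stratification

Preprocessing mirrors standard cohort practice: transcripts missing in more
than 20% of samples are dropped, the 5,000 most variable of the remainder
are kept (variance over non-missing entries; zero-variance rows rank last,
ties break by input order), and rows are median-centred. Sample structure is
summarized by the Pearson correlation matrix over pairwise-complete
observations, hierarchically clustered with uncentred-correlation distance
\(1 - \sum x_i y_i / \sqrt{\sum x_i^2 \sum y_i^2}\) (the Cluster 3.0
metric). Average linkage is used; the metric is named by the convention this
follows but the linkage is not, so average linkage is this package's
documented choice.

A gene-set score is the per-sample mean of the member genes present in the
matrix (missing entries excluded per sample). The "top quartile" is defined
by rank — the `ceiling(n/4)` highest-scoring *cases*, not an interpolated
percentile — with boundary ties broken by stable sample order and flagged.
The combined TIL/MCC stratification has three groups: TIL-top-only
(`high_TIL`), MCC-top-only (`high_MCC`), and everyone else including
double-top and double-rest samples (`intermediate`); the levels are ordered
`high_TIL < intermediate < high_MCC` so the label feeds the logrank trend
test directly with integer scores.

# The statistical layer

Two-group comparisons use the Mann–Whitney U test (exact for small samples
without ties, normal approximation with tie correction otherwise); more than
two groups use Kruskal–Wallis. Contingency tables use Pearson's chi-square
without continuity correction, switching to Fisher's exact test as the
primary p-value when any expected cell is below 5; both p-values and the
choice are recorded.

Cuzick's test for trend across ordered groups — the adjunct to
Kruskal–Wallis used for the infiltrate analyses — is implemented from its
formulas. With pooled mid-ranks, group rank-sums \(R_i\), scores \(l_i\) and
sizes \(n_i\):

\[T = \sum_i l_i R_i, \qquad E(T) = \tfrac{N+1}{2} \sum_i n_i l_i,\]
\[\mathrm{Var}(T) = \tfrac{N+1}{12}\Big(N \sum_i n_i l_i^2 - \big(\sum_i n_i l_i\big)^2\Big)
 \cdot \Big(1 - \tfrac{\sum_j (t_j^3 - t_j)}{N^3 - N}\Big),\]

where \(t_j\) are the tie-group sizes; \(z = (T - E(T))/\sqrt{\mathrm{Var}(T)}\)
is referred to the standard normal. Scores default to consecutive integers
1..G; the z statistic is invariant to affine rescaling of the scores, which
the tests assert, so the choice is immaterial. P-values are two-sided by
default (one-sided available by flag). Degenerate inputs (all observations
equal) return z = 0, p = 1. The implementation is validated against a
10,000-permutation null in the acceptance checks. No multiple-testing
correction is applied inside this module; per-signature outputs carry raw
p-values.

Survival uses Kaplan–Meier estimates with the standard logrank test, and a
logrank trend version for ordered groups:
\(z = s'(O - E) / \sqrt{s' V s}\) with integer scores \(s\) and the logrank
observed-minus-expected vector and covariance matrix. Multivariable models
use Cox proportional hazards with Efron tie handling; constant and collinear
covariates are rejected up front with the offending names.

# The synthetic cohort generator

The generator is first-class, tested code, and its defaults are the study
conditions of the package's checks. One master integer seed drives every
stage through fixed offsets, so a configuration reproduces a cohort
byte-identically.

- **Coding sequences.** Each CDS starts with ATG, ends with a stop, is a
  multiple of 3 long with no internal stop; body bases are i.i.d. with the
  target GC probability (default 0.5), re-drawing stop codons. Generation
  fails explicitly if the realized pooled GC misses the target by more than
  0.05 plus a 3-sigma binomial sampling allowance.
- **Signature catalog.** Toy profiles: `apobec_CtoT` and `apobec_CtoG`
  place 95% of their mass uniformly on the four T[C>T]N / T[C>G]N classes;
  `age_like` on the four N[C>T]G classes; `flat` is uniform; `brca_like` is
  a broad featureless profile over the T-reference classes.
- **Mutations.** Exposures are symmetric Dirichlet (concentration 1.0 —
  the least-informative simplex prior); per-sample counts are Poisson
  (default mean 500, of the order of coding substitution loads in
  heavily-mutated cohorts). Each mutation samples a signature, then a class
  from its profile, then a uniformly chosen CDS site with that
  (strand-normalized) context; the generating signature is recorded as
  hidden ground truth for attribution-accuracy tests. Mutations are placed
  on coding sequence only, so consequence annotation is always defined —
  the analyses only ever use coding, non-silent substitutions.
- **Expression.** Planted TIL and MCC modules add
  `effect × z(covariate)` (log2 units per covariate standard deviation) to
  their member genes over a N(7, 1) baseline with N(0, noise_sd²) residuals;
  the TIL module tracks the per-sample count of charge-increasing
  substitutions of the APOBEC C>G-like signature, the MCC module the total
  substitution count. Default effects of 0.8 make the module means clearly
  but not deterministically covariate-driven. Missing values are encoded as
  `NA` in the TSV output; the default missing rate is 0.
- **Clinical.** Survival times are exponential with hazard
  \(\propto \exp(\sum \beta \cdot z(\text{score}))\) (baseline median 60
  months; default log-HRs +0.7 for the MCC score, −0.7 for the TIL score),
  censored by an independent uniform time calibrated to the target
  censoring fraction (default 0.3). The ordinal infiltrate is a latent
  Gaussian with mean \(\sum \gamma \cdot z(\text{score})\) (default
  \(\gamma = 1.0\) on the APOBEC C>G charge-increase count), thresholded at
  its empirical tertiles into none < mild < moderate/severe. Scores are
  standardized before the linear predictors so stated effect sizes are
  per-standard-deviation and comparable across covariates.

What the generator does *not* emulate: signature interactions and regional
mutation-rate heterogeneity, realistic gene length and codon-usage
distributions, expression compositionality and batch effects, competing
risks, or the correlation structure of real clinical covariates. Passing
tests therefore demonstrate that the pipeline recovers the effects it is
pointed at under clean planted conditions — not that those effects are
identifiable in any given real cohort.

# Problem sizes and numerical choices

The bundled checks use cohorts chosen as the smallest sizes at which the
targeted properties are stable: exposure recovery uses 50 samples × 2,000
mutations against the 4-signature toy catalog; attribution accuracy uses 30
samples × 1,000 mutations on a well-separated 3-signature catalog; the
end-to-end planted-trend study uses 100 seeds of 100-sample cohorts with
Poisson(200) mutations; the survival layer uses 200 replicates at n = 500
(Cox) and 100 at n = 300 (logrank trend). The charge-mechanism oracle is
exhaustive (576 codon changes) and the Cuzick fixture is hand-computable
(T = 50, E = 42, Var = 14, z ≈ 2.138).

Numerical conventions worth knowing: NNLS is solved by an active-set method
(`pracma::lsqnonneg`); spectra and catalogs are validated to 1e-9 on column
sums; proportions of zero-mutation samples are reported as all-zero rows
rather than NaN; stable input order breaks all ranking ties (burden groups,
variance selection, quartiles) so reruns are deterministic.

# Known limitations

- Exposure refitting quality degrades for strongly collinear catalogs; the
  toy catalog is well-conditioned by construction, real catalogs (e.g. the
  full COSMIC set) are not, and per-mutation attribution inherits that
  uncertainty. The posterior margin column exists to quantify it.
- Hard argmax attribution undercounts signatures that are everywhere
  non-dominant.
- The binding predictor interface deliberately does not model MHC binding;
  plugging in a real predictor's output table is the intended use.
- The ordinal infiltrate model (latent Gaussian, tertile thresholds) is a
  convenience; real pathology grading is neither Gaussian nor balanced.
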