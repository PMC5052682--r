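Package: sigimmune
Title: Mutational Signature Attribution and Immune-Phenotype Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links somatic substitutions attributed to mutational signatures with
    their protein-level consequences and with transcriptome-derived immune and
    proliferation phenotypes. Classifies substitutions into the 96 strand-normalized
    trinucleotide context classes, refits per-sample signature exposures against a
    fixed catalog by non-negative least squares, attributes each mutation to a
    signature, translates substitutions to amino-acid consequences, scores charge
    and Kyte-Doolittle hydrophobicity changes, extracts candidate neo-epitope
    peptide windows with a pluggable MHC binding predictor, computes gene-set
    expression scores with quartile stratification, and provides the statistical
    layer (Mann-Whitney U, Kruskal-Wallis, Cuzick's trend test, contingency tests,
    Kaplan-Meier/logrank with trend, Cox proportional hazards). A synthetic-cohort
    generator with planted effects makes every stage testable without access to
    controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    pracma,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
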