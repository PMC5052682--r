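# Shared fixtures: all built in code at test time.

# two signatures with disjoint single-class support (orthogonal columns)
orthogonal_catalog <- function(class_a = "A[C>A]A", class_b = "A[C>G]A") {
  classes <- context_classes_96()
  m <- matrix(0, 96, 2, dimnames = list(classes, c("sigA", "sigB")))
  m[class_a, "sigA"] <- 1
  m[class_b, "sigB"] <- 1
  m
}

tiny_cohort <- function(seed = 42, n_samples = 20, mutations_per_sample = 150,
                        ...) {
  simulate_cohort(cohort_config(
    n_samples = n_samples, n_genes = 30, cds_length_range = c(300, 900),
    mutations_per_sample = mutations_per_sample, n_transcripts = 80,
    module_size = 15, seed = seed, ...))
}

# exhaustive enumeration of the 576 single-nucleotide codon changes, each
# embedded as codon 2 of ATG-<codon>-TAA so the flanking context is defined
enumerate_codon_changes <- function() {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  rows <- list()
  for (cod in codons) for (p in 1:3) for (alt in setdiff(bases, substr(cod, p, p))) {
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = "s1", gene_id = cod, pos_1based_cds = 3L + p,
      ref = substr(cod, p, p), alt = alt, codon = cod, codon_pos = p,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# independent translation oracle: whole-protein translation via Biostrings
translate_oracle <- function(seq) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(seq),
                                     no.init.codon = TRUE))
}
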