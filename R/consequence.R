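# Codon-level consequence annotation, mutant peptide windowing, 9-mer
# enumeration and the strong-binder decision rule with a pluggable MHC class I
# binding predictor.

#' Annotate coding consequences of substitutions
#'
#' Translates the wild-type and mutant codon with the standard genetic code
#' and classifies the change: silent (wt == mut), nonsense (mut is a stop),
#' stop_loss (wt is a stop), start_loss (codon 1 loses its Met), otherwise
#' missense.
#'
#' @param mutations data.frame with `gene_id`, `pos_1based_cds`, `ref`, `alt`
#'   (and any additional columns, which are carried through).
#' @param cds named character vector of coding sequences (length divisible
#'   by 3).
#' @return `mutations` with `codon_index`, `wt_aa`, `mut_aa`, `consequence`
#'   appended.
#' @export
annotate_coding_consequence <- function(mutations, cds) {
  cds <- as_cds_character(cds)
  gc <- Biostrings::GENETIC_CODE
  lens <- nchar(cds)
  if (any(lens %% 3 != 0)) stop("CDS length must be divisible by 3")
  missing <- setdiff(unique(mutations$gene_id), names(cds))
  if (length(missing)) stop("unknown gene(s): ", paste(missing, collapse = ", "))
  seqs <- cds[mutations$gene_id]
  pos <- as.integer(mutations$pos_1based_cds)
  if (any(pos < 1L | pos > nchar(seqs)))
    stop("position outside CDS")
  at <- substr(seqs, pos, pos)
  if (any(at != toupper(mutations$ref)))
    stop("reference base mismatch in annotation")
  codon_index <- (pos - 1L) %/% 3L + 1L
  cstart <- (codon_index - 1L) * 3L + 1L
  wt_codon <- substr(seqs, cstart, cstart + 2L)
  off <- pos - cstart + 1L
  mut_codon <- wt_codon
  substr(mut_codon, off, off) <- toupper(mutations$alt)
  wt_aa <- unname(gc[wt_codon])
  mut_aa <- unname(gc[mut_codon])
  consequence <- ifelse(wt_aa == mut_aa, "silent",
                 ifelse(mut_aa == "*", "nonsense",
                 ifelse(wt_aa == "*", "stop_loss",
                 ifelse(codon_index == 1L & wt_aa == "M", "start_loss",
                        "missense"))))
  mutations$codon_index <- codon_index
  mutations$wt_aa <- wt_aa
  mutations$mut_aa <- mut_aa
  mutations$consequence <- consequence
  mutations
}

#' Extract the mutant peptide window around a substituted residue
#'
#' Takes up to `flank` residues on either side of the mutant position (a
#' 17-mer when the protein is long enough), clamped at the protein ends.
#' Windows shorter than 9 residues are rejected.
#'
#' @param protein protein sequence (single string, no stop symbol).
#' @param mutant_pos 1-based position of the mutant residue.
#' @param flank residues kept on each side (default 8).
#' @return list with `peptide`, `offset` (1-based position of the mutant
#'   residue within the window), or `NULL` with attribute-free rejection via
#'   an error condition when the protein is shorter than 9 residues.
#' @export
extract_peptide_window <- function(protein, mutant_pos, flank = 8L) {
  L <- nchar(protein)
  if (L < 9L) stop("protein shorter than 9 residues: window rejected")
  if (mutant_pos < 1L || mutant_pos > L) stop("mutant position outside protein")
  if (substr(protein, mutant_pos, mutant_pos) == "*")
    stop("mutant residue is a stop symbol")
  from <- max(1L, mutant_pos - flank)
  to <- min(L, mutant_pos + flank)
  if (to - from + 1L < 9L) stop("window shorter than 9 residues: rejected")
  list(peptide = substr(protein, from, to), offset = mutant_pos - from + 1L)
}

#' Enumerate all 9-mers of a window containing the mutant residue
#'
#' @param window list as returned by [extract_peptide_window].
#' @return character vector of 9-mer peptides, each containing the mutant
#'   residue; exactly 9 peptides for a full 17-mer with centred mutant.
#' @export
enumerate_9mers <- function(window) {
  L <- nchar(window$peptide)
  if (L < 9L) stop("window shorter than 9 residues")
  starts <- seq.int(max(1L, window$offset - 8L), min(L - 8L, window$offset))
  substring(window$peptide, starts, starts + 8L)
}

#' Bundled binding predictors
#'
#' A predictor is a function `(peptides, allele) -> EC50 in nM`, vectorized
#' over peptides. `constant_predictor` always returns the same value;
#' `table_predictor` looks up a (peptide, allele, ec50_nM) table, returning
#' `fallback` for absent pairs; `pseudo_predictor` is a deterministic
#' arithmetic-hash predictor spreading EC50 log-uniformly over 1-10000 nM,
#' useful for tests that need peptide-dependent but reproducible calls.
#'
#' @param ec50_nM constant EC50 returned by `constant_predictor`.
#' @return a predictor function.
#' @export
constant_predictor <- function(ec50_nM = 500) {
  force(ec50_nM)
  function(peptides, allele) rep(ec50_nM, length(peptides))
}

#' @rdname constant_predictor
#' @param table data.frame with columns `peptide`, `allele`, `ec50_nM`.
#' @param fallback EC50 for pairs absent from the table.
#' @export
table_predictor <- function(table, fallback = 5000) {
  stopifnot(all(c("peptide", "allele", "ec50_nM") %in% names(table)))
  key <- paste(table$peptide, table$allele)
  function(peptides, allele) {
    hit <- match(paste(peptides, allele), key)
    out <- table$ec50_nM[hit]
    out[is.na(hit)] <- fallback
    out
  }
}

#' @rdname constant_predictor
#' @param salt integer mixed into the hash so different predictors disagree.
#' @export
pseudo_predictor <- function(salt = 0L) {
  force(salt)
  function(peptides, allele) {
    h <- vapply(paste0(peptides, "|", allele), function(k) {
      s <- as.numeric(salt)
      for (x in utf8ToInt(k)) s <- (s * 131 + x) %% 1000003
      s
    }, 0, USE.NAMES = FALSE)
    10^(4 * (h %% 99991) / 99991)
  }
}

#' The ten HLA-A2 alleles used as the default prediction panel
#' @return character vector of allele names.
#' @export
hla_a2_alleles <- function() {
  sprintf("HLA-A2:%02d", c(1, 2, 3, 6, 11, 12, 16, 17, 19, 50))
}

#' Apply the strong-binder decision rule to one substitution's peptides
#'
#' A substitution is flagged as harbouring a potential neo-epitope when any of
#' its candidate 9-mers is predicted to bind any allele with EC50 strictly
#' below the threshold (50 nM by default); an EC50 of exactly 50 nM is not a
#' strong binder. Predictor failures are logged and treated as non-binders.
#'
#' @param peptides character vector of candidate 9-mers.
#' @param predictor a predictor function (see [constant_predictor]).
#' @param alleles allele panel (default [hla_a2_alleles]).
#' @param threshold_nM strong-binder EC50 threshold.
#' @return list with `strong_binder`, `n_predictions` (evaluated
#'   peptide-allele pairs), `min_ec50_nM` and `n_failed`.
#' @export
call_neoepitope <- function(peptides, predictor, alleles = hla_a2_alleles(),
                            threshold_nM = 50) {
  if (!length(alleles)) stop("allele panel must be non-empty")
  n_fail <- 0L
  ec50 <- unlist(lapply(alleles, function(a) {
    out <- tryCatch(predictor(peptides, a), error = function(e) {
      warning("predictor failed for allele ", a, ": ", conditionMessage(e))
      rep(Inf, length(peptides))
    })
    if (any(!is.finite(out))) n_fail <<- n_fail + sum(!is.finite(out))
    out
  }))
  list(strong_binder = any(ec50 < threshold_nM),
       n_predictions = length(ec50),
       min_ec50_nM = if (length(ec50)) min(ec50) else Inf,
       n_failed = n_fail)
}

#' Annotate peptide windows and neo-epitope calls for a mutation table
#'
#' Restricts to missense substitutions (silent and terminating changes never
#' reach peptide windowing), extracts the mutant-protein window, enumerates
#' 9-mers and applies the strong-binder rule.
#'
#' @param annotations output of [annotate_coding_consequence].
#' @param cds named character vector of coding sequences.
#' @param predictor binding predictor function.
#' @param alleles allele panel.
#' @param threshold_nM strong-binder threshold.
#' @param flank window flank (default 8 for 17-mers).
#' @return missense subset of `annotations` with `window`, `window_offset`,
#'   `n_9mers`, `strong_binder`, `min_ec50_nM` appended; rejected records
#'   (protein < 9 aa) are dropped with a message.
#' @export
neoepitope_calls <- function(annotations, cds, predictor,
                             alleles = hla_a2_alleles(), threshold_nM = 50,
                             flank = 8L) {
  cds <- as_cds_character(cds)
  mis <- annotations[annotations$consequence == "missense", , drop = FALSE]
  if (!nrow(mis)) return(cbind(mis, window = character(0)))
  prot <- translate_cds(cds)
  keep <- nchar(prot[mis$gene_id]) >= 9L
  if (any(!keep))
    message(sum(!keep), " record(s) rejected: protein shorter than 9 residues")
  mis <- mis[keep, , drop = FALSE]
  mut_prot <- prot[mis$gene_id]
  substr(mut_prot, mis$codon_index, mis$codon_index) <- mis$mut_aa
  res <- lapply(seq_len(nrow(mis)), function(i) {
    w <- extract_peptide_window(mut_prot[i], mis$codon_index[i], flank)
    nine <- enumerate_9mers(w)
    call <- call_neoepitope(nine, predictor, alleles, threshold_nM)
    c(w["peptide"], w["offset"], list(n = length(nine)), call)
  })
  mis$window <- vapply(res, function(r) r$peptide, "")
  mis$window_offset <- vapply(res, function(r) r$offset, 0L)
  mis$n_9mers <- vapply(res, function(r) r$n, 0L)
  mis$strong_binder <- vapply(res, function(r) r$strong_binder, TRUE)
  mis$min_ec50_nM <- vapply(res, function(r) r$min_ec50_nM, 0)
  mis
}

#' Fraction of neo-epitope-flagged substitutions per signature
#'
#' @param calls output of [neoepitope_calls]; must contain
#'   `assigned_signature` and `strong_binder` columns.
#' @return data.frame: signature, n (attributed missense substitutions),
#'   n_flagged, fraction (NA when the denominator is zero).
#' @export
neoepitope_fraction_by_signature <- function(calls) {
  if (!"assigned_signature" %in% names(calls))
    stop("every substitution must carry an attribution")
  sigs <- sort(unique(calls$assigned_signature))
  n <- as.integer(table(factor(calls$assigned_signature, levels = sigs)))
  flg <- as.integer(tapply(calls$strong_binder,
                           factor(calls$assigned_signature, levels = sigs),
                           sum, default = 0L))
  data.frame(signature = sigs, n = n, n_flagged = flg,
             fraction = ifelse(n > 0, flg / n, NA_real_),
             stringsAsFactors = FALSE)
}

#' Translate coding sequences to proteins (terminal stop removed)
#' @param cds named character vector of CDS.
#' @return named character vector of protein sequences.
#' @export
translate_cds <- function(cds) {
  cds <- as_cds_character(cds)
  gc <- Biostrings::GENETIC_CODE
  out <- vapply(cds, function(s) {
    n <- nchar(s)
    codons <- substring(s, seq(1, n, 3), seq(3, n, 3))
    aa <- paste(gc[codons], collapse = "")
    sub("\\*$", "", aa)
  }, "")
  out
}
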