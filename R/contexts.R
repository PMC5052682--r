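# Trinucleotide context classification: the 96 strand-normalized substitution
# classes "X[R>A]Y" with the mutated base a pyrimidine (C or T) after reverse
# complementing purine references.

#' The 96 canonical trinucleotide substitution class labels
#'
#' Labels have the form `"X[R>A]Y"` where `R` is the pyrimidine reference base
#' (C or T), `A` the alternate base and `X`/`Y` the 5' and 3' flanking bases.
#' The ordering is alphabetical by label (C-locale) and is the canonical row
#' order of every spectrum and catalog in the package.
#'
#' @return character vector of length 96.
#' @export
#' @examples
#' head(context_classes_96())
context_classes_96 <- function() {
  labs <- character(0)
  for (ref in c("C", "T")) for (alt in setdiff(DNA_BASES, ref))
    for (p5 in DNA_BASES) for (p3 in DNA_BASES)
      labs <- c(labs, sprintf("%s[%s>%s]%s", p5, ref, alt, p3))
  sort(labs, method = "radix")
}

#' Classify substitutions into the 96 trinucleotide context classes
#'
#' If the reference base is a purine the class is computed on the reverse
#' complement: reference, alternate and both flanks are complemented and the
#' flanks swapped, so that the mutated base is always reported as a pyrimidine.
#'
#' @param sequence character vector of contig/CDS sequences (recycled).
#' @param pos_1based 1-based position of the substituted base.
#' @param ref,alt reference and alternate base on the supplied strand.
#' @return character vector of class labels `"X[R>A]Y"`; `NA` (with a warning)
#'   where a flanking base is not one of A/C/G/T.
#' @export
#' @examples
#' trinucleotide_context("ATCGA", 3, "C", "T")  # "T[C>T]G"
#' trinucleotide_context("ACGTA", 3, "G", "A")  # "A[C>T]G"
trinucleotide_context <- function(sequence, pos_1based, ref, alt) {
  n <- max(length(sequence), length(pos_1based), length(ref), length(alt))
  sequence <- rep_len(toupper(sequence), n)
  pos <- rep_len(as.integer(pos_1based), n)
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)

  len <- nchar(sequence)
  if (any(pos <= 1L | pos >= len))
    stop("position must satisfy 1 < pos < length(sequence) so both flanks exist")
  if (any(ref == alt)) stop("ref and alt must differ")

  at <- substr(sequence, pos, pos)
  bad <- at != ref
  if (any(bad))
    stop(sprintf("reference mismatch at position %s: sequence has '%s', record says '%s'",
                 paste(pos[bad][1]), at[bad][1], ref[bad][1]))

  b5 <- substr(sequence, pos - 1L, pos - 1L)
  b3 <- substr(sequence, pos + 1L, pos + 1L)

  flank_ok <- b5 %in% DNA_BASES & b3 %in% DNA_BASES
  if (any(!flank_ok))
    warning(sprintf("%d record(s) skipped: flanking base outside A/C/G/T", sum(!flank_ok)))

  pur <- ref %in% c("A", "G")
  # strand-normalize purine references onto the opposite strand
  r <- ifelse(pur, DNA_COMP[ref], ref)
  a <- ifelse(pur, DNA_COMP[alt], alt)
  f5 <- ifelse(pur, DNA_COMP[b3], b5)
  f3 <- ifelse(pur, DNA_COMP[b5], b3)

  out <- sprintf("%s[%s>%s]%s", f5, r, a, f3)
  out[!flank_ok] <- NA_character_
  out
}

#' Add context classes to a mutation table
#'
#' @param mutations data.frame with columns `sample_id`, `gene_id`,
#'   `pos_1based_cds`, `ref`, `alt` (and optionally `strand`, `true_signature`).
#' @param cds named character vector (or `DNAStringSet`) of reference coding
#'   sequences keyed by `gene_id`.
#' @return `mutations` with a `class` column appended.
#' @export
classify_mutations <- function(mutations, cds) {
  cds <- as_cds_character(cds)
  missing <- setdiff(unique(mutations$gene_id), names(cds))
  if (length(missing))
    stop("mutation table references genes absent from the reference: ",
         paste(utils::head(missing, 5), collapse = ", "))
  mutations$class <- trinucleotide_context(
    cds[mutations$gene_id], mutations$pos_1based_cds, mutations$ref, mutations$alt)
  mutations
}

#' Build 96-class mutation spectra
#'
#' @param mutations data.frame with a `class` column (see [classify_mutations]),
#'   and a `sample_id` column when `per_sample = TRUE`.
#' @param per_sample if `TRUE` return a samples x 96 count matrix, else a
#'   single named 96-count vector.
#' @return integer vector of length 96, or matrix with one row per sample, in
#'   canonical class order.
#' @export
build_spectrum <- function(mutations, per_sample = FALSE) {
  classes <- context_classes_96()
  if (nrow(mutations) == 0L) {
    warning("empty mutation table: returning all-zero spectrum")
    if (per_sample) return(matrix(0L, 0, 96, dimnames = list(NULL, classes)))
    return(stats::setNames(integer(96), classes))
  }
  f <- factor(mutations$class, levels = classes)
  if (anyNA(f)) stop("unclassifiable records present; run classify_mutations first")
  if (!per_sample) {
    tab <- table(f)
    return(stats::setNames(as.integer(tab), classes))
  }
  out <- table(factor(mutations$sample_id, levels = unique(mutations$sample_id)), f)
  m <- matrix(as.integer(out), nrow = nrow(out),
              dimnames = list(rownames(out), classes))
  m
}

as_cds_character <- function(cds) {
  if (inherits(cds, "DNAStringSet")) {
    out <- as.character(cds)
    names(out) <- names(cds)
    return(out)
  }
  if (!is.character(cds) || is.null(names(cds)))
    stop("'cds' must be a named character vector or DNAStringSet")
  toupper(cds)
}
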