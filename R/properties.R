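# Amino-acid property deltas: integer electric charge (Asp/Glu negative;
# Lys/Arg/His positive) and Kyte-Doolittle hydrophobicity. The bundled
# constants table (inst/extdata/aa_properties.tsv) is the single source of
# both scales.

.aa_cache <- new.env(parent = emptyenv())

#' The bundled amino-acid property table
#'
#' Twenty standard residues with their Kyte-Doolittle hydropathy value and
#' integer charge assignment (D, E = -1; K, R, H = +1; all others 0).
#'
#' @return data.frame with columns `aa`, `name`, `kd_scale`, `charge`.
#' @export
aa_property_table <- function() {
  if (is.null(.aa_cache$tab)) {
    path <- system.file("extdata", "aa_properties.tsv", package = "sigimmune",
                        mustWork = TRUE)
    .aa_cache$tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  .aa_cache$tab
}

aa_lookup <- function(aa, column) {
  tab <- aa_property_table()
  i <- match(aa, tab$aa)
  if (anyNA(i))
    stop("nonstandard amino acid(s): ",
         paste(unique(aa[is.na(i)]), collapse = ", "))
  tab[[column]][i]
}

#' Integer electric charge of an amino acid
#' @param aa one-letter amino-acid code(s).
#' @return integer vector in \{-1, 0, +1\}.
#' @export
#' @examples
#' charge(c("D", "K", "G"))  # -1  1  0
charge <- function(aa) as.integer(aa_lookup(aa, "charge"))

#' Kyte-Doolittle hydropathy of an amino acid
#' @param aa one-letter amino-acid code(s).
#' @return numeric vector.
#' @export
kd_hydropathy <- function(aa) aa_lookup(aa, "kd_scale")

#' Charge change of an amino-acid substitution
#'
#' Delta is charge(mutant) - charge(wild-type); class is `increase` for a
#' positive delta, `decrease` for a negative one, `none` otherwise. A double
#' step (e.g. Glu to Lys, delta +2) is classed like a single step; the
#' magnitude is retained in `delta`.
#'
#' @param wt_aa,mut_aa one-letter codes (vectorized).
#' @return data.frame with `delta` (integer in [-2, 2]) and `class`.
#' @export
#' @examples
#' charge_delta_class("E", "K")  # delta +2, increase
charge_delta_class <- function(wt_aa, mut_aa) {
  if (any(wt_aa == mut_aa)) stop("wild-type and mutant residues must differ")
  d <- charge(mut_aa) - charge(wt_aa)
  data.frame(delta = d,
             class = ifelse(d > 0, "increase", ifelse(d < 0, "decrease", "none")),
             stringsAsFactors = FALSE)
}

#' Hydrophobicity change of an amino-acid substitution
#'
#' The difference is computed as KD(wild-type) - KD(mutant) and a positive
#' difference is labelled `increase` (this direction is deliberate and can be
#' swapped with `label_convention = "mutant_minus_wt"` which also negates the
#' reported difference).
#'
#' @param wt_aa,mut_aa one-letter codes (vectorized).
#' @param label_convention `"wt_minus_mutant"` (default) or
#'   `"mutant_minus_wt"`.
#' @return data.frame with `difference` and `class`.
#' @export
#' @examples
#' hydrophobicity_delta_class("I", "R")  # difference 9.0, increase
hydrophobicity_delta_class <- function(wt_aa, mut_aa,
                                       label_convention = c("wt_minus_mutant",
                                                            "mutant_minus_wt")) {
  label_convention <- match.arg(label_convention)
  d <- kd_hydropathy(wt_aa) - kd_hydropathy(mut_aa)
  if (label_convention == "mutant_minus_wt") d <- -d
  data.frame(difference = d,
             class = ifelse(d > 0, "increase", ifelse(d < 0, "decrease", "none")),
             stringsAsFactors = FALSE)
}

#' Count property-changing substitutions per signature (and per sample)
#'
#' Only missense substitutions are scored. Within each signature (and sample,
#' when `per_sample = TRUE`) the table counts substitutions whose charge
#' increases or decreases and whose hydrophobicity increases or decreases;
#' charge classes partition the missense set (`charge_none` completes it).
#'
#' @param annotations output of [annotate_coding_consequence], restricted or
#'   not; non-missense rows are ignored.
#' @param attributions optional; if `annotations` lacks an
#'   `assigned_signature` column, a data.frame carrying one keyed by row
#'   correspondence is required.
#' @param per_sample return a per-sample breakdown.
#' @return data.frame of counts per signature (x sample).
#' @export
count_property_changes <- function(annotations, attributions = NULL,
                                   per_sample = FALSE) {
  ann <- annotations
  if (!"assigned_signature" %in% names(ann)) {
    if (is.null(attributions))
      stop("annotations carry no attribution; supply 'attributions'")
    key_a <- mutation_key(ann)
    key_b <- mutation_key(attributions)
    hit <- match(key_a, key_b)
    if (anyNA(hit[ann$consequence == "missense"]))
      stop("missing attribution for missense record(s): ",
           paste(utils::head(key_a[ann$consequence == "missense" & is.na(hit)], 3),
                 collapse = ", "))
    ann$assigned_signature <- attributions$assigned_signature[hit]
  }
  mis <- ann[ann$consequence == "missense", , drop = FALSE]
  if (!nrow(mis)) {
    return(data.frame(signature = character(0), sample_id = character(0),
                      n_missense = integer(0), charge_increase = integer(0),
                      charge_decrease = integer(0), charge_none = integer(0),
                      hydro_increase = integer(0), hydro_decrease = integer(0),
                      hydro_none = integer(0)))
  }
  cd <- charge_delta_class(mis$wt_aa, mis$mut_aa)
  hd <- hydrophobicity_delta_class(mis$wt_aa, mis$mut_aa)
  keys <- if (per_sample) list(signature = mis$assigned_signature,
                               sample_id = mis$sample_id)
          else list(signature = mis$assigned_signature)
  agg <- function(x) stats::aggregate(x, by = keys, FUN = sum)
  out <- agg(data.frame(
    n_missense = 1L,
    charge_increase = as.integer(cd$class == "increase"),
    charge_decrease = as.integer(cd$class == "decrease"),
    charge_none = as.integer(cd$class == "none"),
    hydro_increase = as.integer(hd$class == "increase"),
    hydro_decrease = as.integer(hd$class == "decrease"),
    hydro_none = as.integer(hd$class == "none")))
  out[order(out$signature), , drop = FALSE]
}

mutation_key <- function(df) {
  paste(df$sample_id, df$gene_id, df$pos_1based_cds, df$ref, df$alt, sep = ":")
}

#' Trend of per-sample charge-increasing substitution counts across infiltrate
#'
#' Applies Cuzick's trend test to the per-sample number of charge-increasing
#' substitutions (of one signature, or of all signatures combined, optionally
#' excluding some) across the ordered lymphocytic-infiltrate groups.
#'
#' @param per_sample_counts output of
#'   `count_property_changes(..., per_sample = TRUE)`.
#' @param infiltrate_labels named ordered labels (named by sample id), e.g.
#'   integers 0 < 1 < 2 for none < mild < moderate/severe.
#' @param signature_id one signature id, or `"ALL"` to pool.
#' @param exclude signatures removed before pooling (only with `"ALL"`).
#' @return an [cuzick_trend] result.
#' @export
charge_increase_trend <- function(per_sample_counts, infiltrate_labels,
                                  signature_id = "ALL", exclude = NULL) {
  pc <- per_sample_counts
  if (identical(signature_id, "ALL")) {
    if (!is.null(exclude)) pc <- pc[!pc$signature %in% exclude, , drop = FALSE]
  } else pc <- pc[pc$signature == signature_id, , drop = FALSE]
  samples <- names(infiltrate_labels)
  if (is.null(samples)) stop("infiltrate_labels must be named by sample id")
  counts <- tapply(pc$charge_increase,
                   factor(pc$sample_id, levels = samples), sum, default = 0L)
  counts[is.na(counts)] <- 0L
  if (sum(counts) == 0 && nrow(pc) == 0)
    stop("no contributing substitutions after exclusion")
  cuzick_trend(as.numeric(counts), infiltrate_labels)
}
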