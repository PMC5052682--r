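# Exposure refitting against a fixed catalog (non-negative least squares) and
# per-mutation signature attribution, plus the sample-grouping rules used by
# the downstream association analyses.

#' Refit signature exposures for one spectrum by non-negative least squares
#'
#' Finds non-negative weights minimizing `||spectrum - catalog %*% w||`; the
#' fitted weights are on the count scale (they sum approximately to the number
#' of mutations) and are also returned normalized to proportions.
#'
#' @param spectrum named 96-count vector in canonical class order.
#' @param catalog 96 x S signature catalog.
#' @return list with `weights` (fitted counts per signature), `proportions`
#'   (normalized weights), `residual` (Euclidean residual norm) and `total`
#'   (sum of the spectrum).
#' @export
fit_exposures <- function(spectrum, catalog) {
  validate_catalog(catalog)
  if (length(spectrum) != 96L) stop("spectrum must have 96 entries")
  if (any(spectrum < 0)) stop("spectrum must be non-negative")
  if (sum(spectrum) == 0) stop("no mutations to fit")
  fit <- pracma::lsqnonneg(catalog, as.numeric(spectrum))
  w <- stats::setNames(fit$x, colnames(catalog))
  props <- if (sum(w) > 0) w / sum(w) else w
  list(weights = w, proportions = props,
       residual = sqrt(fit$resid.norm), total = sum(spectrum))
}

#' Refit exposures for every sample of a per-sample spectrum matrix
#' @param spectra samples x 96 count matrix (see [build_spectrum]).
#' @param catalog 96 x S signature catalog.
#' @return list with `weights` and `proportions` (samples x S matrices) and
#'   `residual` (per-sample vector). Zero-mutation samples get all-zero rows.
#' @export
fit_exposures_all <- function(spectra, catalog) {
  validate_catalog(catalog)
  s <- ncol(catalog)
  w <- matrix(0, nrow(spectra), s,
              dimnames = list(rownames(spectra), colnames(catalog)))
  res <- stats::setNames(numeric(nrow(spectra)), rownames(spectra))
  for (i in seq_len(nrow(spectra))) {
    if (sum(spectra[i, ]) == 0) next
    f <- fit_exposures(spectra[i, ], catalog)
    w[i, ] <- f$weights
    res[i] <- f$residual
  }
  tot <- rowSums(w)
  p <- w / ifelse(tot > 0, tot, 1)
  list(weights = w, proportions = p, residual = res)
}

#' Attribute each mutation to a signature by maximum posterior
#'
#' For a mutation of class `c` in sample `j`, the posterior over signatures is
#' proportional to `exposure[j, s] * catalog[c, s]`. Assignment is the argmax;
#' exact ties are broken towards the lowest signature index in catalog order
#' and flagged. When every exposed signature gives the class zero probability
#' the posterior is uniform over exposed signatures and the record is flagged
#' unresolvable.
#'
#' @param mutations data.frame with `sample_id` and `class` columns.
#' @param catalog 96 x S signature catalog.
#' @param exposures samples x S matrix of (non-negative) exposures; rownames
#'   must cover all samples present in `mutations`.
#' @return `mutations` with columns `assigned_signature`, `posterior`,
#'   `margin` (gap to the runner-up posterior), `tie` and `unresolved`.
#' @export
attribute_mutations <- function(mutations, catalog, exposures) {
  validate_catalog(catalog)
  sig_ids <- colnames(catalog)
  if (!identical(colnames(exposures), sig_ids))
    stop("exposure columns must match catalog signatures")
  missing <- setdiff(unique(mutations$sample_id), rownames(exposures))
  if (length(missing))
    stop("exposures not fitted for sample(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  e <- exposures[mutations$sample_id, , drop = FALSE]
  pr <- catalog[mutations$class, , drop = FALSE]
  post <- e * pr
  tot <- rowSums(post)
  unresolved <- tot == 0
  if (any(unresolved)) {
    exposed <- exposures[mutations$sample_id[unresolved], , drop = FALSE] > 0
    post[unresolved, ] <- exposed / pmax(rowSums(exposed), 1)
    tot[unresolved] <- rowSums(post[unresolved, , drop = FALSE])
  }
  post <- post / tot
  best <- max.col(post, ties.method = "first")
  p1 <- post[cbind(seq_len(nrow(post)), best)]
  if (ncol(post) > 1L) {
    tmp <- post
    tmp[cbind(seq_len(nrow(tmp)), best)] <- -Inf
    p2 <- do.call(pmax, as.data.frame(tmp))
  } else p2 <- rep(0, nrow(post))
  mutations$assigned_signature <- sig_ids[best]
  mutations$posterior <- as.numeric(p1)
  mutations$margin <- as.numeric(p1 - p2)
  mutations$tie <- mutations$margin <= .Machine$double.eps * 4
  mutations$unresolved <- unresolved
  attr(mutations, "posterior_matrix") <- post
  mutations
}

#' Per-sample counts and proportions of attributed substitutions per signature
#'
#' @param attributions output of [attribute_mutations].
#' @param samples optional sample universe (to report zero-mutation samples).
#' @param signatures optional signature universe (defaults to those observed).
#' @return list with `counts` and `proportions` (samples x signatures
#'   matrices) and `total` (per-sample totals). Rows of `proportions` sum to 1
#'   except for zero-mutation samples, which are all-zero.
#' @export
signature_proportions <- function(attributions, samples = NULL, signatures = NULL) {
  samples <- samples %||% unique(attributions$sample_id)
  signatures <- signatures %||% sort(unique(attributions$assigned_signature))
  tab <- table(factor(attributions$sample_id, levels = samples),
               factor(attributions$assigned_signature, levels = signatures))
  counts <- matrix(as.integer(tab), nrow = length(samples),
                   dimnames = list(samples, signatures))
  total <- rowSums(counts)
  props <- counts / ifelse(total > 0, total, 1)
  list(counts = counts, proportions = props, total = total)
}

#' Group samples by dominance of one signature
#'
#' A sample is `HIGH` when at least `hi` of its substitutions are attributed
#' to the signature, `LOW` when the proportion is below `lo`, otherwise
#' `EXCLUDED`; the HIGH-vs-LOW contrast is considered valid only when both
#' groups hold at least `min_n` samples.
#'
#' @param proportions samples x signatures proportion matrix.
#' @param signature_id column to group on.
#' @param hi,lo,min_n grouping thresholds (defaults 0.50, 0.20, 15).
#' @return list with `group` (named factor HIGH/LOW/EXCLUDED) and `valid`.
#' @export
dominant_signature_groups <- function(proportions, signature_id,
                                      hi = 0.50, lo = 0.20, min_n = 15L) {
  p <- proportions[, signature_id]
  lab <- ifelse(p >= hi, "HIGH", ifelse(p < lo, "LOW", "EXCLUDED"))
  group <- factor(lab, levels = c("HIGH", "LOW", "EXCLUDED"))
  names(group) <- rownames(proportions)
  valid <- sum(group == "HIGH") >= min_n && sum(group == "LOW") >= min_n
  list(group = group, valid = valid)
}

#' Group samples by extreme total mutational burden
#'
#' Samples are ranked on total substitution count over the whole input (the
#' pooled cohort, not within strata); the top and bottom `floor(frac * n)`
#' samples are labelled TOP and BOTTOM. Ties are broken by stable input order.
#'
#' @param total_counts named numeric vector of per-sample totals.
#' @param frac extreme fraction (default 0.20).
#' @return named factor with levels TOP, MIDDLE, BOTTOM.
#' @export
burden_extreme_groups <- function(total_counts, frac = 0.20) {
  n <- length(total_counts)
  if (n < 5L) stop("need at least 5 samples")
  k <- floor(frac * n)
  if (length(unique(total_counts)) == 1L)
    warning("all totals equal; extreme groups determined by input order")
  ord <- order(total_counts)  # stable for ties
  lab <- rep("MIDDLE", n)
  lab[ord[seq_len(k)]] <- "BOTTOM"
  lab[ord[seq(n - k + 1L, n)]] <- "TOP"
  out <- factor(lab, levels = c("TOP", "MIDDLE", "BOTTOM"))
  names(out) <- names(total_counts)
  out
}
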