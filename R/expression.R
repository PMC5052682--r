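# Expression-matrix preprocessing (missingness filter, variance selection,
# median centring, sample-correlation clustering) and gene-set phenotype
# scores with quartile / combined TIL-MCC stratification.

#' Filter transcripts by missingness and keep the most variable ones
#'
#' Transcripts missing in more than `max_missing_frac` of samples are removed;
#' the remainder are ranked by variance (missing values ignored) and the
#' `top_n` most variable are retained. Zero-variance rows rank last; ties are
#' broken by input order.
#'
#' @param matrix transcripts x samples numeric matrix (log2 scale, NAs
#'   allowed).
#' @param max_missing_frac maximum tolerated missing fraction (default 0.20).
#' @param top_n number of transcripts to keep (default 5000).
#' @return the filtered submatrix.
#' @export
filter_and_select_variable <- function(matrix, max_missing_frac = 0.20,
                                       top_n = 5000L) {
  if (!nrow(matrix)) stop("empty expression matrix")
  miss <- rowMeans(is.na(matrix))
  keep <- matrix[miss <= max_missing_frac, , drop = FALSE]
  if (!nrow(keep)) stop("all transcripts removed by the missingness filter")
  v <- apply(keep, 1L, stats::var, na.rm = TRUE)
  v[is.na(v)] <- -Inf
  if (nrow(keep) <= top_n) {
    if (nrow(keep) < top_n)
      warning("fewer than top_n transcripts remain after filtering; keeping all")
    return(keep)
  }
  ord <- order(-v)  # stable: ties keep input order
  keep[sort(ord[seq_len(top_n)]), , drop = FALSE]
}

#' Median-centre each transcript row
#'
#' Subtracts the per-transcript median over non-missing entries; idempotent.
#'
#' @param matrix transcripts x samples numeric matrix.
#' @return the centred matrix.
#' @export
median_center <- function(matrix) {
  med <- apply(matrix, 1L, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 0
  matrix - med
}

# Uncentred-correlation distance between columns of m:
# d(x,y) = 1 - sum(x*y) / sqrt(sum(x^2) * sum(y^2)) over pairwise-complete
# entries (the Cluster 3.0 metric).
uncentered_correlation_dist <- function(m) {
  p <- ncol(m)
  d <- matrix(0, p, p, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(p - 1L)) for (j in seq.int(i + 1L, p)) {
    ok <- !is.na(m[, i]) & !is.na(m[, j])
    x <- m[ok, i]; y <- m[ok, j]
    den <- sqrt(sum(x^2) * sum(y^2))
    u <- if (den > 0) sum(x * y) / den else 0
    d[i, j] <- d[j, i] <- 1 - u
  }
  stats::as.dist(d)
}

#' Cluster samples on their Pearson correlation matrix
#'
#' Computes the Pearson correlation between all sample pairs (pairwise
#' complete observations), then hierarchically clusters the columns of the
#' correlation matrix with uncentred-correlation distance and average linkage.
#'
#' @param matrix transcripts x samples numeric matrix (typically filtered and
#'   median-centred first).
#' @param k number of clusters to cut (optional).
#' @param cut_height dendrogram cut height (alternative to `k`).
#' @return list with `hclust` (the tree), `correlation` (samples x samples)
#'   and, when requested, `cluster` (named integer labels).
#' @export
sample_correlation_cluster <- function(matrix, k = NULL, cut_height = NULL) {
  if (ncol(matrix) < 3L) stop("need at least 3 samples")
  if (nrow(matrix) < 2L) stop("need at least 2 transcripts")
  sds <- apply(matrix, 2L, stats::sd, na.rm = TRUE)
  if (any(!is.na(sds) & sds == 0))
    stop("zero-variance sample(s): ",
         paste(colnames(matrix)[!is.na(sds) & sds == 0], collapse = ", "))
  cc <- stats::cor(matrix, use = "pairwise.complete.obs")
  if (anyNA(cc)) stop("undefined correlations (insufficient overlap)")
  hc <- stats::hclust(uncentered_correlation_dist(cc), method = "average")
  out <- list(hclust = hc, correlation = cc)
  if (!is.null(k) || !is.null(cut_height))
    out$cluster <- stats::cutree(hc, k = k, h = cut_height)
  out
}

#' Average-expression score of a gene set per sample
#'
#' @param matrix transcripts x samples matrix.
#' @param gene_list character vector of member transcript ids.
#' @param name score name.
#' @return list with `name`, `score` (named per-sample means over the member
#'   genes present, missing entries excluded per sample), `n_genes_used`, and
#'   `absent` (listed genes not in the matrix).
#' @export
geneset_score <- function(matrix, gene_list, name = "geneset") {
  present <- intersect(gene_list, rownames(matrix))
  if (!length(present)) stop("no listed genes present in the matrix")
  absent <- setdiff(gene_list, present)
  if (length(absent))
    message(length(absent), " listed gene(s) absent from the matrix")
  sc <- colMeans(matrix[present, , drop = FALSE], na.rm = TRUE)
  list(name = name, score = sc, n_genes_used = length(present), absent = absent)
}

#' Label the top quartile of samples by score
#'
#' The `ceiling(n/4)` highest-scoring samples are `TOP_QUARTILE`, the rest
#' `REST`. Ties at the boundary are broken by stable sample order with a
#' warning.
#'
#' @param scores named numeric vector of per-sample scores.
#' @return named factor with levels `TOP_QUARTILE`, `REST`.
#' @export
quartile_group <- function(scores) {
  n <- length(scores)
  if (n < 4L) stop("need at least 4 samples")
  k <- ceiling(n / 4)
  ord <- order(-scores)  # stable
  top <- ord[seq_len(k)]
  boundary <- scores[ord[k]]
  if (k < n && scores[ord[k + 1L]] == boundary)
    warning("tie at the quartile boundary broken by sample order")
  lab <- rep("REST", n)
  lab[top] <- "TOP_QUARTILE"
  out <- factor(lab, levels = c("TOP_QUARTILE", "REST"))
  names(out) <- names(scores)
  out
}

#' Three-group TIL/MCC stratification
#'
#' Group `high_TIL` holds samples in the TIL top quartile but not the MCC top
#' quartile; `high_MCC` the converse; everything else (including double-top
#' and double-rest samples) is `intermediate`. Levels are ordered
#' `high_TIL < intermediate < high_MCC` so the label can feed a trend test
#' directly (expected hazard increases along the order).
#'
#' @param til_scores,mcc_scores named per-sample score vectors over the same
#'   samples.
#' @return named ordered factor with the three levels.
#' @export
til_mcc_groups <- function(til_scores, mcc_scores) {
  if (!identical(names(til_scores), names(mcc_scores)))
    stop("score vectors must cover the same samples in the same order")
  til_top <- quartile_group(til_scores) == "TOP_QUARTILE"
  mcc_top <- quartile_group(mcc_scores) == "TOP_QUARTILE"
  lab <- ifelse(til_top & !mcc_top, "high_TIL",
         ifelse(mcc_top & !til_top, "high_MCC", "intermediate"))
  out <- factor(lab, levels = c("high_TIL", "intermediate", "high_MCC"),
                ordered = TRUE)
  names(out) <- names(til_scores)
  out
}

#' Read / write an expression TSV (transcripts x samples, "NA" for missing)
#' @param path file path.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression_tsv
#' @param matrix transcripts x samples matrix.
#' @export
write_expression_tsv <- function(matrix, path) {
  df <- data.frame(transcript_id = rownames(matrix), matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
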