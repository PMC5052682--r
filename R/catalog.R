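# Signature catalogs: 96-class probability profiles, one column per signature.

TOY_SIGNATURE_IDS <- c("age_like", "apobec_CtoT", "apobec_CtoG", "flat", "brca_like")

#' Build a toy signature catalog
#'
#' The supported toy profiles emulate well-known substitution processes:
#' `age_like` concentrates C>T mutations in an NCG context (clock-like
#' deamination of methylated CpG), `apobec_CtoT` and `apobec_CtoG` concentrate
#' C>T and C>G mutations respectively in a TCN context (APOBEC/AID cytidine
#' deaminase activity), `flat` is uniform over the 96 classes and `brca_like`
#' is a broad, featureless profile spread over the T-reference classes
#' (mimicking the diffuse pattern of homologous-recombination deficiency).
#'
#' @param signature_ids character vector drawn from
#'   `c("age_like","apobec_CtoT","apobec_CtoG","flat","brca_like")`.
#' @param focus_mass probability mass placed on the characteristic context
#'   classes of the focused profiles (default 0.95, i.e. >=90% as the profiles
#'   advertise, with the remainder spread uniformly).
#' @return numeric matrix 96 x S, rows in canonical class order, columns named
#'   by signature id; every column sums to 1.
#' @export
#' @examples
#' cat96 <- make_toy_catalog(c("apobec_CtoG", "age_like", "flat"))
#' colSums(cat96)
make_toy_catalog <- function(signature_ids, focus_mass = 0.95) {
  unknown <- setdiff(signature_ids, TOY_SIGNATURE_IDS)
  if (length(unknown))
    stop("unknown signature id(s): ", paste(unknown, collapse = ", "),
         "; supported ids are: ", paste(TOY_SIGNATURE_IDS, collapse = ", "))
  if (anyDuplicated(signature_ids)) stop("duplicate signature ids")
  classes <- context_classes_96()
  focus_profile <- function(hot) {
    p <- rep((1 - focus_mass) / (96 - length(hot)), 96)
    p[match(hot, classes)] <- focus_mass / length(hot)
    p
  }
  cols <- lapply(signature_ids, function(id) {
    switch(id,
      flat = rep(1 / 96, 96),
      apobec_CtoT = focus_profile(sprintf("T[C>T]%s", DNA_BASES)),
      apobec_CtoG = focus_profile(sprintf("T[C>G]%s", DNA_BASES)),
      age_like = focus_profile(sprintf("%s[C>T]G", DNA_BASES)),
      brca_like = {
        hot <- grep("\\[T>", classes)
        p <- rep(0, 96); p[hot] <- 1 / length(hot); p
      })
  })
  m <- do.call(cbind, cols)
  dimnames(m) <- list(classes, signature_ids)
  validate_catalog(m)
  m
}

#' Validate a signature catalog matrix
#' @param catalog numeric 96 x S matrix, canonical class rownames.
#' @return the catalog, invisibly, after checks.
#' @export
validate_catalog <- function(catalog) {
  if (!is.matrix(catalog) || nrow(catalog) != 96L)
    stop("catalog must be a 96 x S matrix")
  if (!identical(rownames(catalog), context_classes_96()))
    stop("catalog rows must be the 96 canonical class labels in canonical order")
  if (any(catalog < 0)) stop("catalog probabilities must be non-negative")
  s <- colSums(catalog)
  if (any(abs(s - 1) > 1e-9))
    stop("every catalog column must sum to 1 (tolerance 1e-9)")
  invisible(catalog)
}

#' Read / write a catalog TSV (class label column + one column per signature)
#' @param path file path.
#' @return for the reader, a validated 96 x S matrix.
#' @export
read_catalog <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m <- m[match(context_classes_96(), rownames(m)), , drop = FALSE]
  validate_catalog(m)
  m
}

#' @rdname read_catalog
#' @param catalog 96 x S catalog matrix.
#' @export
write_catalog <- function(catalog, path) {
  validate_catalog(catalog)
  df <- data.frame(class = rownames(catalog), catalog, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
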