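# Synthetic cohort generator: coding sequences, signature-driven mutation
# catalogs, expression matrices with planted co-expressed modules, and clinical
# tables with planted survival / infiltrate effects. Every stream is derived
# from a single integer seed by fixed offsets so a config reproduces the cohort
# byte-identically.

SEED_OFFSET <- c(cds = 11L, exposures = 17L, mutations = 23L,
                 expression = 37L, clinical = 53L)

#' Configuration of a synthetic cohort
#'
#' @param n_samples number of samples.
#' @param n_genes number of synthetic coding sequences.
#' @param cds_length_range min/max CDS length in nucleotides (rounded to
#'   multiples of 3; minimum 30).
#' @param gc_content target GC fraction of the coding body.
#' @param signature_ids toy signature ids used for the catalog (see
#'   [make_toy_catalog]).
#' @param exposure_concentration symmetric Dirichlet concentration for the
#'   per-sample exposure mixtures.
#' @param mutations_per_sample mean of the per-sample Poisson mutation count.
#' @param effect_sizes named list of planted effect sizes; recognised names:
#'   `til_expression`, `mcc_expression` (module-mean shift in log2 units per
#'   covariate s.d.), `infiltrate_charge` (ordinal-infiltrate latent slope per
#'   s.d. of the APOBEC C>G charge-increase count), `hazard_mcc`, `hazard_til`
#'   (log hazard ratios per score s.d.).
#' @param censor_rate target fraction of censored survival records.
#' @param n_transcripts number of transcripts in the expression matrix.
#' @param module_size number of genes in each planted TIL / MCC module.
#' @param noise_sd per-gene residual s.d. of expression values (log2 units).
#' @param missing_rate missing-at-random fraction of expression entries.
#' @param til_signature the toy signature whose charge-increasing substitutions
#'   drive the planted infiltrate / TIL effects (the signature-13 analogue).
#' @param seed single integer master seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 50, n_genes = 100,
                          cds_length_range = c(300, 1500), gc_content = 0.5,
                          signature_ids = c("age_like", "apobec_CtoT",
                                            "apobec_CtoG", "flat"),
                          exposure_concentration = 1,
                          mutations_per_sample = 500,
                          effect_sizes = list(),
                          censor_rate = 0.3,
                          n_transcripts = 200, module_size = 25,
                          noise_sd = 1, missing_rate = 0,
                          til_signature = "apobec_CtoG",
                          seed = 1L) {
  stopifnot_scalar_count(n_samples, "n_samples")
  stopifnot_scalar_count(n_genes, "n_genes")
  stopifnot_scalar_count(n_transcripts, "n_transcripts")
  stopifnot_scalar_count(module_size, "module_size")
  stopifnot_fraction(gc_content, "gc_content")
  stopifnot_fraction(censor_rate, "censor_rate", open = FALSE)
  stopifnot_fraction(missing_rate, "missing_rate", open = FALSE)
  if (length(cds_length_range) != 2L || cds_length_range[1] < 30 ||
      diff(cds_length_range) < 0)
    stop("cds_length_range must be an increasing pair with minimum >= 30 nt")
  if (!is.numeric(mutations_per_sample) || mutations_per_sample <= 0)
    stop("mutations_per_sample must be positive")
  if (!til_signature %in% signature_ids)
    stop("til_signature must be one of signature_ids")
  defaults <- list(til_expression = 0.8, mcc_expression = 0.8,
                   infiltrate_charge = 1.0, hazard_mcc = 0.7,
                   hazard_til = -0.7)
  unknown <- setdiff(names(effect_sizes), names(defaults))
  if (length(unknown)) stop("unknown effect_sizes: ", paste(unknown, collapse = ", "))
  defaults[names(effect_sizes)] <- effect_sizes
  structure(list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    cds_length_range = as.integer(cds_length_range), gc_content = gc_content,
    signature_ids = signature_ids,
    exposure_concentration = exposure_concentration,
    mutations_per_sample = mutations_per_sample,
    effect_sizes = defaults, censor_rate = censor_rate,
    n_transcripts = as.integer(n_transcripts),
    module_size = as.integer(module_size),
    noise_sd = noise_sd, missing_rate = missing_rate,
    til_signature = til_signature, seed = as.integer(seed)),
    class = "cohort_config")
}

#' Generate synthetic reference coding sequences
#'
#' Each CDS begins with ATG, ends with a stop codon, has length divisible by 3
#' and contains no internal stop codon. Bases of the coding body (codons
#' between start and stop) are drawn i.i.d. with the target GC probability,
#' re-drawing any stop codon; the realized pooled body GC must fall within
#' 0.05 of the target or generation fails.
#'
#' @param config a [cohort_config].
#' @return named character vector of CDS, names `gene_0001`, ...
#' @export
generate_reference_cds <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  g <- config$gc_content
  base_prob <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
  stops <- c("TAA", "TAG", "TGA")
  with_seed(config$seed + SEED_OFFSET[["cds"]], {
    n_codons <- pmax(10L, round(stats::runif(config$n_genes,
      config$cds_length_range[1], config$cds_length_range[2]) / 3))
    seqs <- vapply(n_codons, function(nc) {
      draw <- function(k) {
        b <- sample(DNA_BASES, 3L * k, replace = TRUE, prob = base_prob)
        apply(matrix(b, nrow = 3L), 2L, paste, collapse = "")
      }
      codons <- draw(nc - 2L)
      for (it in 1:100) {
        bad <- codons %in% stops
        if (!any(bad)) break
        codons[bad] <- draw(sum(bad))
      }
      if (any(codons %in% stops)) stop("failed to draw stop-free coding body")
      paste0("ATG", paste(codons, collapse = ""), sample(stops, 1L))
    }, "")
    body <- substr(seqs, 4L, nchar(seqs) - 3L)
    n_body <- sum(nchar(body))
    gc_obs <- sum(vapply(strsplit(body, ""),
                         function(b) sum(b %in% c("G", "C")), 0)) / n_body
    # 0.05 band plus a sampling allowance so tiny references are not rejected
    # for pure binomial noise
    tol <- 0.05 + 3 * sqrt(g * (1 - g) / n_body)
    if (abs(gc_obs - g) > tol)
      stop(sprintf("GC target %.2f unreachable under coding constraints (realized %.3f)",
                   g, gc_obs))
    names(seqs) <- sprintf("gene_%04d", seq_along(seqs))
    seqs
  })
}

#' Write/read coding sequences as FASTA
#' @param cds named character vector of sequences.
#' @param path file path.
#' @export
write_cds_fasta <- function(cds, path) {
  x <- Biostrings::DNAStringSet(as_cds_character(cds))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_cds_fasta
#' @export
read_cds_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Draw per-sample signature exposures from a symmetric Dirichlet
#' @param n_samples number of samples.
#' @param signature_ids character vector of signature ids.
#' @param concentration symmetric Dirichlet concentration.
#' @param seed integer seed.
#' @return n_samples x S matrix of mixing weights, rows summing to 1.
#' @export
draw_exposures <- function(n_samples, signature_ids, concentration = 1, seed = 1L) {
  s <- length(signature_ids)
  with_seed(seed, {
    g <- matrix(stats::rgamma(n_samples * s, shape = concentration), n_samples, s)
    w <- g / rowSums(g)
    dimnames(w) <- list(sprintf("s%03d", seq_len(n_samples)), signature_ids)
    w
  })
}

# Index every internal CDS position by its pyrimidine-normalized trinucleotide
# context (3-mer key "5'-ref-3'"); pyr marks sites where the coding-strand base
# is itself the pyrimidine.
index_contexts <- function(cds) {
  cds <- as_cds_character(cds)
  parts <- lapply(names(cds), function(gid) {
    b <- strsplit(cds[[gid]], "")[[1]]
    L <- length(b)
    pos <- 2:(L - 1L)
    ref <- b[pos]
    pyr <- ref %in% c("C", "T")
    key <- ifelse(pyr,
                  paste0(b[pos - 1L], ref, b[pos + 1L]),
                  paste0(DNA_COMP[b[pos + 1L]], DNA_COMP[ref], DNA_COMP[b[pos - 1L]]))
    data.frame(gene = gid, pos = pos, pyr = pyr, key = key,
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, parts)
  split(all[c("gene", "pos", "pyr")], all$key)
}

#' Simulate signature-driven somatic substitutions on synthetic CDS
#'
#' Each mutation draws a generating signature from the sample's exposure
#' vector, a 96-class from that signature's profile, and then a uniformly
#' chosen CDS site whose strand-normalized trinucleotide context matches the
#' class. The emitted ref/alt are reported on the coding strand (strand "+"),
#' so purine-site records reverse-complement back to the sampled class. The
#' generating signature is recorded as hidden ground truth.
#'
#' @param cds named character vector of coding sequences.
#' @param catalog 96 x S signature catalog.
#' @param exposures n_samples x S exposure matrix, rows summing to 1; rownames
#'   are the sample ids.
#' @param n_per_sample integer vector (recycled over samples) of mutation counts.
#' @param seed integer seed.
#' @param max_retry bound on class resampling when a context is absent from
#'   the reference.
#' @return data.frame: sample_id, gene_id, pos_1based_cds, ref, alt, strand,
#'   class, true_signature.
#' @export
simulate_mutations <- function(cds, catalog, exposures, n_per_sample, seed = 1L,
                               max_retry = 50L) {
  validate_catalog(catalog)
  cds <- as_cds_character(cds)
  if (any(exposures < 0)) stop("exposures must be non-negative")
  if (any(abs(rowSums(exposures) - 1) > 1e-6)) stop("exposure rows must sum to 1")
  sig_ids <- colnames(catalog)
  if (!identical(colnames(exposures), sig_ids))
    stop("exposure columns must match catalog signatures")

  classes <- context_classes_96()
  class_key <- paste0(substr(classes, 1, 1), substr(classes, 3, 3),
                      substr(classes, 7, 7))
  class_ref <- substr(classes, 3, 3)
  class_alt <- substr(classes, 5, 5)
  idx <- index_contexts(cds)
  have_sites <- class_key %in% names(idx)

  n_samples <- nrow(exposures)
  n_per_sample <- rep_len(as.integer(n_per_sample), n_samples)
  samples <- rownames(exposures) %||% sprintf("s%03d", seq_len(n_samples))

  with_seed(seed, {
    sig <- unlist(lapply(seq_len(n_samples), function(j) {
      if (n_per_sample[j] == 0L) return(character(0))
      sample(sig_ids, n_per_sample[j], replace = TRUE, prob = exposures[j, ])
    }))
    sample_id <- rep(samples, n_per_sample)
    n_tot <- length(sig)
    cls <- character(n_tot)
    for (s in sig_ids) {
      rows <- sig == s
      if (any(rows))
        cls[rows] <- sample(classes, sum(rows), replace = TRUE, prob = catalog[, s])
    }
    for (it in seq_len(max_retry)) {
      bad <- !have_sites[match(cls, classes)]
      if (!any(bad)) break
      for (s in unique(sig[bad])) {
        rows <- bad & sig == s
        cls[rows] <- sample(classes, sum(rows), replace = TRUE, prob = catalog[, s])
      }
    }
    if (any(!have_sites[match(cls, classes)]))
      stop("sampled context class absent from reference after ",
           max_retry, " retries")

    gene <- character(n_tot); pos <- integer(n_tot); pyr <- logical(n_tot)
    for (cl in unique(cls)) {
      rows <- which(cls == cl)
      sites <- idx[[class_key[match(cl, classes)]]]
      pick <- sites[sample.int(nrow(sites), length(rows), replace = TRUE), ,
                    drop = FALSE]
      gene[rows] <- pick$gene; pos[rows] <- pick$pos; pyr[rows] <- pick$pyr
    }
    ref_p <- class_ref[match(cls, classes)]
    alt_p <- class_alt[match(cls, classes)]
    data.frame(
      sample_id = sample_id, gene_id = gene, pos_1based_cds = pos,
      ref = ifelse(pyr, ref_p, unname(DNA_COMP[ref_p])),
      alt = ifelse(pyr, alt_p, unname(DNA_COMP[alt_p])),
      strand = "+", class = cls, true_signature = sig,
      stringsAsFactors = FALSE)
  })
}

#' Simulate a log2 expression matrix with planted co-expressed modules
#'
#' Background transcripts are baseline plus noise; each planted module adds
#' `effect * z(covariate)` (covariate standardized over samples) to every
#' member gene, so the per-sample module mean correlates with the covariate
#' with the sign of `effect`.
#'
#' @param samples character vector of sample ids.
#' @param module_spec named list; each element is
#'   `list(genes = <ids>, covariate = <name>, effect = <real>)`. Modules must
#'   be disjoint.
#' @param covariates data.frame of per-sample covariates (rows in `samples`
#'   order) referenced by the modules.
#' @param noise_sd residual s.d. (log2 units).
#' @param seed integer seed.
#' @param n_background number of additional background transcripts.
#' @param missing_rate missing-at-random fraction (encoded as NA).
#' @return numeric matrix transcripts x samples (log2 scale).
#' @export
simulate_expression <- function(samples, module_spec, covariates,
                                noise_sd = 1, seed = 1L,
                                n_background = 100L, missing_rate = 0) {
  mod_genes <- lapply(module_spec, `[[`, "genes")
  if (length(mod_genes) > 1) {
    for (i in seq_along(mod_genes)[-1])
      if (length(intersect(mod_genes[[i]], unlist(mod_genes[seq_len(i - 1)]))))
        stop("planted modules must be disjoint")
  }
  n <- length(samples)
  zscore <- function(x) {
    if (!all(is.finite(x))) stop("non-finite covariate values")
    s <- stats::sd(x)
    if (is.na(s) || s == 0) return(rep(0, n))
    (x - mean(x)) / s
  }
  with_seed(seed, {
    bg_ids <- if (n_background > 0) sprintf("bg_%04d", seq_len(n_background)) else character(0)
    genes <- c(unlist(mod_genes, use.names = FALSE), bg_ids)
    base <- stats::rnorm(length(genes), mean = 7, sd = 1)
    m <- matrix(rep(base, n), nrow = length(genes), ncol = n,
                dimnames = list(genes, samples))
    if (noise_sd > 0)
      m <- m + matrix(stats::rnorm(length(m), sd = noise_sd), nrow(m))
    for (spec in module_spec) {
      z <- zscore(covariates[[spec$covariate]])
      m[spec$genes, ] <- m[spec$genes, , drop = FALSE] +
        matrix(rep(spec$effect * z, each = length(spec$genes)), length(spec$genes))
    }
    if (missing_rate > 0)
      m[stats::runif(length(m)) < missing_rate] <- NA_real_
    m
  })
}

#' Simulate a clinical table with planted survival and infiltrate effects
#'
#' Survival times are exponential with hazard proportional to
#' `exp(sum(beta * z(score)))` (median 60 months at the baseline), censored by
#' an independent uniform time calibrated to the target censoring fraction.
#' The ordinal infiltrate label is a latent Gaussian with mean
#' `sum(gamma * z(score))`, thresholded at its empirical tertiles into three
#' ordered levels (0 = none < 1 = mild < 2 = moderate/severe).
#'
#' @param scores data.frame of per-sample scores (rownames = sample ids).
#' @param hazard_betas named numeric, log hazard ratios per score s.d.
#'   (names must be columns of `scores`).
#' @param infiltrate_betas named numeric, latent slopes per score s.d.
#' @param censor_rate target censoring fraction in [0,1).
#' @param seed integer seed.
#' @param median_months baseline median survival.
#' @return data.frame: sample_id, time_months, event, infiltrate, grade,
#'   er_status.
#' @export
simulate_clinical <- function(scores, hazard_betas = numeric(0),
                              infiltrate_betas = numeric(0),
                              censor_rate = 0.3, seed = 1L,
                              median_months = 60) {
  if (!all(vapply(scores, function(x) all(is.finite(x)), TRUE)))
    stop("non-finite scores")
  n <- nrow(scores)
  zscore <- function(x) {
    s <- stats::sd(x); if (is.na(s) || s == 0) rep(0, n) else (x - mean(x)) / s
  }
  lin <- function(betas) {
    lp <- rep(0, n)
    for (nm in names(betas)) {
      if (!nm %in% names(scores)) stop("unknown score: ", nm)
      lp <- lp + betas[[nm]] * zscore(scores[[nm]])
    }
    lp
  }
  with_seed(seed, {
    lp <- lin(hazard_betas)
    t_true <- stats::rexp(n, rate = log(2) / median_months * exp(lp))
    if (censor_rate > 0) {
      f <- function(cmax) mean(pmin(t_true / cmax, 1)) - censor_rate
      cmax <- stats::uniroot(f, c(1e-9, 1e9))$root
      cens <- stats::runif(n, 0, cmax)
      time <- pmin(t_true, cens)
      event <- as.integer(t_true <= cens)
    } else {
      time <- t_true
      event <- rep(1L, n)
    }
    latent <- lin(infiltrate_betas) + stats::rnorm(n)
    cuts <- stats::quantile(latent, c(1, 2) / 3)
    infiltrate <- as.integer(latent > cuts[1]) + as.integer(latent > cuts[2])
    data.frame(
      sample_id = rownames(scores) %||% sprintf("s%03d", seq_len(n)),
      time_months = time, event = event, infiltrate = infiltrate,
      grade = sample(1:3, n, replace = TRUE),
      er_status = "pos", stringsAsFactors = FALSE)
  })
}

#' Simulate a complete synthetic cohort
#'
#' Generates the reference CDS, toy catalog, Dirichlet exposures, Poisson
#' mutation counts, the mutation table (with generating-signature ground
#' truth), an expression matrix with TIL and MCC modules planted on
#' mutation-derived covariates, and a clinical table whose survival depends on
#' the MCC/TIL module scores and whose infiltrate depends on the
#' charge-increasing substitution count of the APOBEC C>G-like signature.
#'
#' @param config a [cohort_config].
#' @return list with elements `config`, `cds`, `catalog`, `exposures_true`,
#'   `mutations`, `expression`, `clinical`, `gene_sets` (TIL/MCC member ids)
#'   and `covariates` (the planted per-sample drivers).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cds <- generate_reference_cds(config)
  catalog <- make_toy_catalog(config$signature_ids)
  exposures <- draw_exposures(config$n_samples, config$signature_ids,
                              config$exposure_concentration,
                              config$seed + SEED_OFFSET[["exposures"]])
  n_mut <- with_seed(config$seed + SEED_OFFSET[["exposures"]] + 1L,
                     pmax(1L, stats::rpois(config$n_samples,
                                           config$mutations_per_sample)))
  muts <- simulate_mutations(cds, catalog, exposures, n_mut,
                             seed = config$seed + SEED_OFFSET[["mutations"]])

  # planted per-sample covariates from ground truth
  samples <- rownames(exposures)
  ann <- annotate_coding_consequence(muts, cds)
  mis <- ann[ann$consequence == "missense", ]
  delta <- charge_delta_class(mis$wt_aa, mis$mut_aa)
  inc <- mis[delta$class == "increase", ]
  total <- as.integer(table(factor(muts$sample_id, levels = samples)))
  sig13_inc <- as.integer(table(factor(
    inc$sample_id[inc$true_signature == config$til_signature], levels = samples)))
  covariates <- data.frame(total_substitutions = total,
                           sig13_charge_inc = sig13_inc,
                           row.names = samples)

  module_size <- config$module_size
  til_genes <- sprintf("TIL_%03d", seq_len(module_size))
  mcc_genes <- sprintf("MCC_%03d", seq_len(module_size))
  n_bg <- max(0L, config$n_transcripts - 2L * module_size)
  expr <- simulate_expression(
    samples,
    module_spec = list(
      TIL = list(genes = til_genes, covariate = "sig13_charge_inc",
                 effect = config$effect_sizes$til_expression),
      MCC = list(genes = mcc_genes, covariate = "total_substitutions",
                 effect = config$effect_sizes$mcc_expression)),
    covariates = covariates, noise_sd = config$noise_sd,
    seed = config$seed + SEED_OFFSET[["expression"]],
    n_background = n_bg, missing_rate = config$missing_rate)

  scores <- data.frame(
    mcc_score = colMeans(expr[mcc_genes, , drop = FALSE], na.rm = TRUE),
    til_score = colMeans(expr[til_genes, , drop = FALSE], na.rm = TRUE),
    sig13_charge_inc = sig13_inc,
    row.names = samples)
  clinical <- simulate_clinical(
    scores,
    hazard_betas = c(mcc_score = config$effect_sizes$hazard_mcc,
                     til_score = config$effect_sizes$hazard_til),
    infiltrate_betas = c(sig13_charge_inc = config$effect_sizes$infiltrate_charge),
    censor_rate = config$censor_rate,
    seed = config$seed + SEED_OFFSET[["clinical"]])

  list(config = config, cds = cds, catalog = catalog,
       exposures_true = exposures, mutations = muts, expression = expr,
       clinical = clinical,
       gene_sets = list(TIL = til_genes, MCC = mcc_genes),
       covariates = covariates)
}
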