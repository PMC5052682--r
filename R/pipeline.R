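# Pipeline orchestration: validated run configuration and the
# simulate -> attribute -> annotate -> score -> associate composition with
# TSV outputs and a reproducibility manifest.

CONFIG_DEFAULTS <- list(
  hi = 0.50, lo = 0.20, min_n = 15L,
  ec50_threshold_nM = 50, max_missing_frac = 0.20, top_n = 5000L,
  exclude_signatures = character(0), seed = 1L)

CONFIG_KEYS <- c(names(CONFIG_DEFAULTS),
                 "simulate", "mutations", "fasta", "catalog",
                 "expression", "clinical", "til_genes", "mcc_genes", "out")

#' Validate a pipeline run configuration
#'
#' Accepts a YAML file path or a list. Unknown keys, type errors, threshold
#' ordering violations and missing input files are all collected and reported
#' together. Defaults: hi = 0.50, lo = 0.20, min_n = 15, EC50 threshold
#' 50 nM, missingness 0.20, top_n = 5000.
#'
#' @param config path to a YAML file, or a named list.
#' @return a validated `run_config` list with defaults filled.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config) %||% list()
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  problems <- character(0)
  unknown <- setdiff(names(config), CONFIG_KEYS)
  if (length(unknown))
    problems <- c(problems, paste0("unknown key(s): ",
                                   paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(CONFIG_DEFAULTS, config[intersect(names(config),
                                                             CONFIG_KEYS)])
  num1 <- function(key) {
    if (!is.numeric(cfg[[key]]) || length(cfg[[key]]) != 1L)
      problems <<- c(problems, paste0("'", key, "' must be a single number"))
  }
  for (key in c("hi", "lo", "min_n", "ec50_threshold_nM",
                "max_missing_frac", "top_n", "seed")) num1(key)
  if (is.numeric(cfg$hi) && is.numeric(cfg$lo) && length(cfg$hi) == 1 &&
      length(cfg$lo) == 1 && cfg$hi <= cfg$lo)
    problems <- c(problems, "'hi' must exceed 'lo'")
  for (key in c("mutations", "fasta", "catalog", "expression", "clinical",
                "til_genes", "mcc_genes"))
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      problems <- c(problems, paste0("missing file for '", key, "': ", cfg[[key]]))
  if (!is.null(cfg$simulate) && !is.list(cfg$simulate))
    problems <- c(problems, "'simulate' must be a mapping of cohort_config fields")
  if (length(problems))
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Composes the stages: obtain inputs (simulate a synthetic cohort, or load
#' mutation/FASTA/catalog and optional expression/clinical files), classify
#' substitutions, refit exposures, attribute mutations, annotate consequences
#' and neo-epitope windows, score amino-acid property changes, compute
#' TIL/MCC gene-set scores and strata, and run the association and survival
#' analyses. All stage tables are written as TSV under `out` together with a
#' manifest of checksums; reruns with the same inputs and seed reproduce the
#' tables byte-identically.
#'
#' @param config a `run_config` (see [validate_config]) or anything it
#'   accepts.
#' @param out output directory (created if absent); overrides `config$out`.
#' @param predictor MHC binding predictor (default a deterministic
#'   pseudo-predictor seeded by the run seed).
#' @return (invisibly) a list of result tables: `til_association`
#'   (TIL-quartile contrast per signature, absolute and proportional),
#'   `infiltrate_trend` (per-signature trend), `charge_trend` (overall, per
#'   key signature, and with the APOBEC C>G-like signature excluded),
#'   `neoepitope_fractions`, `survival` (3-group logrank-trend and
#'   multivariable Cox), plus `manifest`.
#' @export
run_pipeline <- function(config = list(), out = NULL, predictor = NULL) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  out <- out %||% cfg$out %||% stop("no output directory given")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  predictor <- predictor %||% pseudo_predictor(cfg$seed)

  # ---- stage: inputs ----
  if (!is.null(cfg$simulate) || is.null(cfg$mutations)) {
    sim_args <- cfg$simulate %||% list()
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    cohort <- do.call(cohort_config, sim_args)
    cohort <- simulate_cohort(cohort)
    cds <- cohort$cds
    catalog <- cohort$catalog
    mutations <- cohort$mutations
    expression <- cohort$expression
    clinical <- cohort$clinical
    til_genes <- cohort$gene_sets$TIL
    mcc_genes <- cohort$gene_sets$MCC
    write_cds_fasta(cds, file.path(out, "reference_cds.fa"))
    write_catalog(catalog, file.path(out, "catalog.tsv"))
    write_tsv(mutations, file.path(out, "mutations.tsv"))
  } else {
    cds <- read_cds_fasta(cfg$fasta)
    catalog <- read_catalog(cfg$catalog)
    mutations <- utils::read.delim(cfg$mutations, stringsAsFactors = FALSE)
    expression <- if (!is.null(cfg$expression)) read_expression_tsv(cfg$expression)
    clinical <- if (!is.null(cfg$clinical))
      utils::read.delim(cfg$clinical, stringsAsFactors = FALSE)
    til_genes <- if (!is.null(cfg$til_genes)) readLines(cfg$til_genes)
    mcc_genes <- if (!is.null(cfg$mcc_genes)) readLines(cfg$mcc_genes)
  }

  # ---- stage: attribution ----
  mutations <- classify_mutations(mutations, cds)
  samples <- unique(mutations$sample_id)
  spectra <- build_spectrum(mutations, per_sample = TRUE)
  exposures <- fit_exposures_all(spectra, catalog)
  muts <- attribute_mutations(mutations, catalog, exposures$proportions)
  props <- signature_proportions(muts, samples = samples,
                                 signatures = colnames(catalog))
  write_tsv(muts, file.path(out, "attributions.tsv"))
  write_tsv(data.frame(sample_id = rownames(exposures$proportions),
                       exposures$proportions, check.names = FALSE),
            file.path(out, "exposures.tsv"))

  # ---- stage: consequences & properties ----
  ann <- annotate_coding_consequence(muts, cds)
  calls <- neoepitope_calls(ann, cds, predictor,
                            threshold_nM = cfg$ec50_threshold_nM)
  write_tsv(calls[, setdiff(names(calls), "true_signature")],
            file.path(out, "annotations.tsv"))
  prop_counts <- count_property_changes(ann, per_sample = TRUE)
  write_tsv(prop_counts, file.path(out, "property_counts.tsv"))
  neo <- neoepitope_fraction_by_signature(calls)
  write_tsv(neo, file.path(out, "neoepitope_fractions.tsv"))

  results <- list(neoepitope_fractions = neo)

  # ---- stage: expression scores ----
  til_scores <- mcc_scores <- NULL
  if (!is.null(expression) && !is.null(til_genes) && !is.null(mcc_genes)) {
    til_scores <- geneset_score(expression, til_genes, "TIL")$score
    mcc_scores <- geneset_score(expression, mcc_genes, "MCC")$score
    strata <- til_mcc_groups(til_scores, mcc_scores)
    scores_df <- data.frame(sample_id = names(til_scores),
                            til_score = til_scores, mcc_score = mcc_scores,
                            til_quartile = quartile_group(til_scores),
                            mcc_quartile = quartile_group(mcc_scores),
                            til_mcc_group = as.character(strata))
    write_tsv(scores_df, file.path(out, "geneset_scores.tsv"))

    til_grp <- quartile_group(til_scores)
    counts <- props$counts[names(til_grp), , drop = FALSE]
    t1_abs <- per_signature_group_association(counts, til_grp, "absolute",
                                              cfg$exclude_signatures)
    t1_prop <- per_signature_group_association(counts, til_grp, "proportional",
                                               cfg$exclude_signatures)
    t1_abs$mode <- "absolute"; t1_prop$mode <- "proportional"
    results$til_association <- rbind(t1_abs, t1_prop)
    write_tsv(results$til_association, file.path(out, "til_association.tsv"))
    results$scores <- scores_df
  }

  # ---- stage: infiltrate & charge trends ----
  if (!is.null(clinical)) {
    infl <- stats::setNames(factor(clinical$infiltrate, levels = 0:2,
                                   ordered = TRUE), clinical$sample_id)
    infl <- infl[intersect(names(infl), rownames(props$counts))]
    t2 <- infiltrate_trend_per_signature(props$counts, infl, "absolute",
                                         cfg$exclude_signatures)
    results$infiltrate_trend <- t2
    write_tsv(t2, file.path(out, "infiltrate_trend.tsv"))

    apobec_cg <- intersect(c("apobec_CtoG", "13"), colnames(catalog))[1]
    pc_sample <- count_property_changes(ann, per_sample = TRUE)
    trend_row <- function(label, res)
      data.frame(analysis = label, z = res$z, p_value = res$p_value)
    ct_all <- charge_increase_trend(pc_sample, infl, "ALL")
    ct <- list(trend_row("charge_increase_all", ct_all))
    if (!is.na(apobec_cg)) {
      ct <- c(ct, list(
        trend_row(paste0("charge_increase_", apobec_cg),
                  charge_increase_trend(pc_sample, infl, apobec_cg)),
        trend_row(paste0("charge_increase_excluding_", apobec_cg),
                  charge_increase_trend(pc_sample, infl, "ALL",
                                        exclude = apobec_cg))))
    }
    results$charge_trend <- do.call(rbind, ct)
    write_tsv(results$charge_trend, file.path(out, "charge_trend.tsv"))

    # ---- stage: survival ----
    if (!is.null(til_scores)) {
      cl <- clinical[match(names(til_scores), clinical$sample_id), ]
      strata <- til_mcc_groups(til_scores, mcc_scores)
      lr <- km_logrank(cl$time_months, cl$event, strata, trend = TRUE)
      cov <- data.frame(
        high_TIL = as.integer(quartile_group(til_scores) == "TOP_QUARTILE"),
        high_MCC = as.integer(quartile_group(mcc_scores) == "TOP_QUARTILE"))
      cox <- cox_ph(cov, cl$time_months, cl$event)
      results$survival <- list(
        logrank_trend = data.frame(test = "logrank_trend", z = lr$z,
                                   p_value = lr$p_value),
        cox = cox)
      write_tsv(results$survival$logrank_trend,
                file.path(out, "survival_trend.tsv"))
      write_tsv(cox, file.path(out, "survival_cox.tsv"))
    }
  }

  # ---- manifest ----
  files <- sort(list.files(out, pattern = "\\.(tsv|fa)$", full.names = TRUE))
  manifest <- list(
    package = "sigimmune",
    version = as.character(utils::packageVersion("sigimmune")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out")],
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  results$manifest <- manifest
  invisible(results)
}
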