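# Statistical layer: rank tests, Cuzick's trend test (implemented from its
# rank-sum formulas with mid-ranks and tie-corrected variance), contingency
# tests with the low-count rule, per-signature association tables, Kaplan-Meier
# / logrank (with trend) and the Cox proportional-hazards contract.

assoc_result <- function(test, statistic, p_value, group_n,
                         group_summary = NULL, ...) {
  structure(list(test = test, statistic = statistic, p_value = p_value,
                 group_n = group_n, group_summary = group_summary, ...),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)\n",
              x$test, x$statistic, x$p_value,
              paste(x$group_n, collapse = "/")))
  invisible(x)
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact p-value for small samples without ties; otherwise the normal
#' approximation with tie correction.
#'
#' @param x,y numeric vectors for the two groups.
#' @return an `assoc_result` with the U statistic.
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  assoc_result("Mann-Whitney U", statistic = unname(wt$statistic),
               p_value = wt$p.value, group_n = c(length(x), length(y)),
               group_summary = c(mean_x = mean(x), mean_y = mean(y),
                                 median_x = stats::median(x),
                                 median_y = stats::median(y)))
}

#' Kruskal-Wallis test
#' @param groups list of numeric vectors (>= 2 non-empty groups).
#' @return an `assoc_result` with the tie-corrected H statistic.
#' @export
kruskal_wallis <- function(groups) {
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2L) stop("need at least 2 non-empty groups")
  if (length(unique(unlist(groups))) == 1L)
    return(assoc_result("Kruskal-Wallis", statistic = 0, p_value = 1,
                        group_n = lengths(groups),
                        group_summary = vapply(groups, mean, 0)))
  kw <- stats::kruskal.test(groups)
  assoc_result("Kruskal-Wallis", statistic = unname(kw$statistic),
               p_value = kw$p.value, group_n = lengths(groups),
               group_summary = vapply(groups, mean, 0))
}

#' Cuzick's nonparametric test for trend across ordered groups
#'
#' An adjunct to the Kruskal-Wallis test. With pooled mid-ranks `R_i`
#' (rank-sum of group `i`), group scores `l_i` and sizes `n_i`, the statistic
#' is `T = sum(l_i R_i)` with `E(T) = (N+1)/2 * sum(n_i l_i)` and
#' `Var(T) = (N+1)/12 * (N sum(n_i l_i^2) - (sum(n_i l_i))^2)`, the variance
#' multiplied by the tie-correction factor `1 - sum(t^3 - t)/(N^3 - N)`;
#' `z = (T - E(T)) / sqrt(Var(T))` is referred to the standard normal.
#' The z statistic is invariant to affine rescaling of the scores.
#'
#' @param values numeric vector of observations.
#' @param groups ordered group membership (ordered factor, or values coercible
#'   to one; the sort order of unique values defines the ordering).
#' @param scores group scores (default consecutive integers 1..G over the
#'   occupied groups).
#' @param alternative `"two.sided"` (default), `"increasing"` or
#'   `"decreasing"`.
#' @return an `assoc_result` with fields `statistic` (T), `z`, `expectation`,
#'   `variance`, `p_value` and per-group means.
#' @export
#' @examples
#' cuzick_trend(c(1, 2, 3, 4, 5, 6), rep(1:3, each = 2))  # T = 50, z = 2.138
cuzick_trend <- function(values, groups, scores = NULL,
                         alternative = c("two.sided", "increasing",
                                         "decreasing")) {
  alternative <- match.arg(alternative)
  g <- if (is.factor(groups)) droplevels(groups) else factor(groups)
  G <- nlevels(g)
  if (G < 2L) stop("need at least 2 occupied ordered groups")
  l <- scores %||% seq_len(G)
  if (length(l) != G || any(diff(l) <= 0))
    stop("scores must be strictly increasing, one per occupied group")
  N <- length(values)
  r <- rank(values)  # mid-ranks for ties
  Ri <- as.numeric(tapply(r, g, sum))
  ni <- as.numeric(table(g))
  Tstat <- sum(l * Ri)
  ET <- (N + 1) / 2 * sum(ni * l)
  varT <- (N + 1) / 12 * (N * sum(ni * l^2) - sum(ni * l)^2)
  ties <- table(values)
  tiecor <- 1 - sum(ties^3 - ties) / (N^3 - N)
  varT <- varT * tiecor
  z <- if (varT > 0) (Tstat - ET) / sqrt(varT) else 0
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(z)),
              increasing = stats::pnorm(z, lower.tail = FALSE),
              decreasing = stats::pnorm(z))
  assoc_result("Cuzick trend", statistic = Tstat, p_value = min(p, 1),
               group_n = ni, group_summary = tapply(values, g, mean),
               z = z, expectation = ET, variance = varT, scores = l)
}

#' Pearson chi-square / Fisher's exact test with the low-count rule
#'
#' Reports the Pearson chi-square test (no continuity correction) and, when
#' any expected cell count is below 5 (or the table is 2x2 with low counts),
#' Fisher's exact test as the primary p-value; which test is primary is
#' recorded.
#'
#' @param table non-negative integer matrix.
#' @return an `assoc_result` with `p_value` (primary), `chisq_p`, `fisher_p`
#'   (2x2 or small tables) and `primary` ("chisq" or "fisher").
#' @export
contingency_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != floor(table)))
    stop("table must hold non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate table: zero margin")
  cs <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  low <- any(cs$expected < 5)
  fisher_p <- tryCatch(stats::fisher.test(table)$p.value, error = function(e) NA_real_)
  primary <- if (low && !is.na(fisher_p)) "fisher" else "chisq"
  assoc_result("contingency",
               statistic = unname(cs$statistic),
               p_value = if (primary == "fisher") fisher_p else cs$p.value,
               group_n = rowSums(table),
               chisq_p = cs$p.value, fisher_p = fisher_p, primary = primary)
}

#' Per-signature association of substitution counts with a two-group label
#'
#' For each signature a Mann-Whitney U test compares the per-sample counts
#' (or, in `proportional` mode, counts divided by the sample total, removing
#' total mutational load as a confounder) between the two groups, reporting
#' per-group means. Signatures in `exclude_signatures` are reported as
#' `N.D.` without a test; `n` counts the samples with more than zero
#' substitutions of the signature.
#'
#' @param counts samples x signatures count matrix.
#' @param group_labels named two-level factor over the samples.
#' @param mode `"absolute"` or `"proportional"`.
#' @param exclude_signatures signatures to skip (default none; the cohort
#'   analyses typically exclude rarely observed ones).
#' @return data.frame: signature, n, p_value, mean_group1, mean_group2, note.
#' @export
per_signature_group_association <- function(counts, group_labels,
                                            mode = c("absolute", "proportional"),
                                            exclude_signatures = NULL) {
  mode <- match.arg(mode)
  g <- factor(group_labels)
  if (nlevels(g) != 2L) stop("group_labels must have exactly 2 levels")
  if (any(table(g) == 0)) stop("empty group")
  x <- counts[names(group_labels), , drop = FALSE]
  if (mode == "proportional") {
    tot <- rowSums(x)
    if (any(tot == 0)) stop("proportional mode requires totals > 0")
    x <- x / tot
  }
  lev <- levels(g)
  rows <- lapply(colnames(counts), function(s) {
    n_pos <- sum(counts[, s] > 0)
    if (s %in% exclude_signatures)
      return(data.frame(signature = s, n = n_pos, p_value = NA_real_,
                        mean_group1 = NA_real_, mean_group2 = NA_real_,
                        note = "N.D."))
    mw <- mann_whitney_u(x[g == lev[1], s], x[g == lev[2], s])
    data.frame(signature = s, n = n_pos, p_value = mw$p_value,
               mean_group1 = mean(x[g == lev[1], s]),
               mean_group2 = mean(x[g == lev[2], s]), note = "")
  })
  out <- do.call(rbind, rows)
  names(out)[4:5] <- paste0("mean_", lev)
  attr(out, "mode") <- mode
  out
}

#' Per-signature trend of substitution counts across ordered infiltrate groups
#'
#' Cuzick's trend test per signature on absolute or total-corrected
#' (proportional) counts, with per-level means.
#'
#' @param counts samples x signatures count matrix.
#' @param infiltrate_labels named ordered labels over the samples.
#' @param mode `"absolute"` or `"proportional"`.
#' @param exclude_signatures signatures reported as `N.D.` without a test.
#' @return data.frame: signature, n, p_value, z, one mean column per level,
#'   note.
#' @export
infiltrate_trend_per_signature <- function(counts, infiltrate_labels,
                                           mode = c("absolute", "proportional"),
                                           exclude_signatures = NULL) {
  mode <- match.arg(mode)
  g <- if (is.factor(infiltrate_labels)) droplevels(infiltrate_labels)
       else factor(infiltrate_labels)
  x <- counts[names(infiltrate_labels), , drop = FALSE]
  if (mode == "proportional") {
    tot <- rowSums(x)
    if (any(tot == 0)) stop("proportional mode requires totals > 0")
    x <- x / tot
  }
  lev <- levels(g)
  rows <- lapply(colnames(counts), function(s) {
    n_pos <- sum(counts[, s] > 0)
    means <- tapply(x[, s], g, mean)
    base <- data.frame(signature = s, n = n_pos, p_value = NA_real_,
                       z = NA_real_)
    for (i in seq_along(lev)) base[[paste0("mean_", lev[i])]] <- means[[i]]
    if (s %in% exclude_signatures) { base$note <- "N.D."; return(base) }
    ct <- cuzick_trend(x[, s], g)
    base$p_value <- ct$p_value; base$z <- ct$z; base$note <- ""
    base
  })
  out <- do.call(rbind, rows)
  attr(out, "mode") <- mode
  out
}

#' Kaplan-Meier curves with logrank or logrank-trend test
#'
#' Standard logrank across groups; with `trend = TRUE` and ordered groups the
#' logrank trend statistic `z = s'(O - E) / sqrt(s' V s)` with integer group
#' scores `s`, where `O - E` and `V` are the logrank observed-minus-expected
#' vector and its covariance matrix.
#'
#' @param time,event numeric survival time and 0/1 event indicator.
#' @param group group labels (ordered factor for the trend test).
#' @param trend compute the trend version.
#' @return an `assoc_result` with the chi-square (or trend z) and a `km`
#'   element holding the `survfit` object.
#' @export
km_logrank <- function(time, event, group, trend = FALSE) {
  g <- if (is.factor(group)) droplevels(group) else factor(group)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (sum(event) < 1) stop("no events")
  fit <- survival::survfit(survival::Surv(time, event) ~ g)
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  if (!trend) {
    df <- nlevels(g) - 1L
    return(assoc_result("logrank", statistic = sd$chisq,
                        p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
                        group_n = as.numeric(table(g)), km = fit,
                        obs = sd$obs, exp = sd$exp))
  }
  s <- seq_len(nlevels(g))
  oe <- sd$obs - sd$exp
  v <- as.numeric(t(s) %*% sd$var %*% s)
  z <- sum(s * oe) / sqrt(v)
  assoc_result("logrank trend", statistic = z^2,
               p_value = 2 * stats::pnorm(-abs(z)),
               group_n = as.numeric(table(g)), km = fit, z = z,
               obs = sd$obs, exp = sd$exp)
}

#' Cox proportional-hazards fit (Efron ties)
#'
#' @param covariates data.frame of covariates (numeric or factor).
#' @param time,event numeric survival time and 0/1 event indicator.
#' @return data.frame with one row per coefficient: `term`, `hr`, `ci_lo`,
#'   `ci_hi`, `p_value`, plus the fitted model as attribute `"fit"`.
#' @export
cox_ph <- function(covariates, time, event) {
  if (sum(event) < 1) stop("no events")
  const <- vapply(covariates, function(x) length(unique(x)) <= 1L, TRUE)
  if (any(const))
    stop("constant covariate(s): ", paste(names(covariates)[const], collapse = ", "))
  mm <- stats::model.matrix(~ ., data = covariates)
  if (qr(mm)$rank < ncol(mm))
    stop("covariate matrix is rank deficient (collinear covariates)")
  dat <- cbind(covariates, .time = time, .event = event)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(names(covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  if (!is.null(fit$info) && !fit$info$converged)
    stop("Cox fit did not converge")
  sm <- summary(fit)
  out <- data.frame(term = rownames(sm$coefficients),
                    hr = sm$conf.int[, "exp(coef)"],
                    ci_lo = sm$conf.int[, "lower .95"],
                    ci_hi = sm$conf.int[, "upper .95"],
                    p_value = sm$coefficients[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  out
}
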