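# Context classification, exposure refitting, per-mutation attribution and
# the sample-grouping rules.

test_that("trinucleotide classes are computed with strand normalization", {
  expect_equal(trinucleotide_context("ATCGA", 3, "C", "T"), "T[C>T]G")
  # purine reference: computed on the reverse complement
  expect_equal(trinucleotide_context("ACGTA", 3, "G", "A"), "A[C>T]G")
  expect_equal(trinucleotide_context("AGAAT", 3, "A", "G"), "T[T>C]C")
  expect_error(trinucleotide_context("ATCGA", 3, "G", "T"), "mismatch")
  expect_warning(out <- trinucleotide_context("ANCGA", 3, "C", "T"), "skipped")
  expect_true(is.na(out))
})

test_that("classification is involutive under reverse complement", {
  set.seed(7)
  for (i in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), 11, replace = TRUE), collapse = "")
    pos <- 6L
    ref <- substr(s, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    rc <- sigimmune:::revcomp(s)
    rc_pos <- nchar(s) - pos + 1L
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    expect_equal(trinucleotide_context(s, pos, ref, alt),
                 trinucleotide_context(rc, rc_pos, comp[[ref]], comp[[alt]]))
  }
})

test_that("spectra count, order canonically, and add", {
  muts <- data.frame(sample_id = "s1", class = rep("T[C>G]A", 3))
  sp <- build_spectrum(muts)
  expect_equal(sum(sp), 3)
  expect_equal(unname(sp["T[C>G]A"]), 3L)
  expect_equal(names(sp), context_classes_96())
  more <- data.frame(sample_id = "s1",
                     class = c("A[C>A]A", "T[C>G]A"))
  expect_equal(build_spectrum(rbind(muts, more)),
               sp + build_spectrum(more))
  expect_warning(empty <- build_spectrum(muts[0, ]), "empty")
  expect_true(all(empty == 0))
})

test_that("NNLS refitting recovers orthogonal and noiseless mixtures exactly", {
  cat2 <- orthogonal_catalog()
  sp <- setNames(numeric(96), context_classes_96())
  sp["A[C>A]A"] <- 30; sp["A[C>G]A"] <- 70
  f <- fit_exposures(sp, cat2)
  expect_equal(unname(f$proportions), c(0.3, 0.7), tolerance = 1e-12)
  expect_equal(f$residual, 0, tolerance = 1e-9)

  cat4 <- make_toy_catalog(c("age_like", "apobec_CtoT", "apobec_CtoG", "flat"))
  sp2 <- setNames(as.numeric(cat4[, "apobec_CtoG"] * 100), rownames(cat4))
  f2 <- fit_exposures(sp2, cat4)
  expect_equal(unname(f2$weights["apobec_CtoG"]), 100, tolerance = 1e-6)
  expect_lt(max(f2$weights[names(f2$weights) != "apobec_CtoG"]), 1e-8)
  expect_lt(f2$residual, 1e-8)

  w <- c(age_like = 200, apobec_CtoT = 50, apobec_CtoG = 300, flat = 450)
  sp3 <- setNames(as.numeric(cat4 %*% w), rownames(cat4))
  f3 <- fit_exposures(sp3, cat4)
  expect_equal(f3$weights, w, tolerance = 1e-6)
  expect_error(fit_exposures(setNames(numeric(96), context_classes_96()), cat4),
               "no mutations")
})

test_that("NNLS agrees with an exhaustive simplex grid search on small problems", {
  # independent oracle: scan the exposure simplex (direction grid, optimal
  # scale in closed form) and compare the normalized optimum
  set.seed(31)
  for (rep in 1:3) {
    A <- matrix(rexp(6 * 3), 6, 3)
    A <- sweep(A, 2, colSums(A), "/")
    y <- as.numeric(A %*% runif(3, 0, 100)) + rnorm(6, sd = 1)
    y <- pmax(y, 0)
    step <- 1e-3
    g <- seq(0, 1, by = step)
    grid <- expand.grid(w1 = g, w2 = g)
    grid <- grid[grid$w1 + grid$w2 <= 1 + 1e-12, ]
    W <- rbind(grid$w1, grid$w2, 1 - grid$w1 - grid$w2)
    AW <- A %*% W
    num <- colSums(AW * y)
    den <- colSums(AW^2)
    score <- ifelse(den > 0, num^2 / den, 0)  # larger = smaller residual
    best <- W[, which.max(score)]

    classes <- context_classes_96()
    A96 <- matrix(0, 96, 3, dimnames = list(classes, paste0("s", 1:3)))
    A96[1:6, ] <- A
    y96 <- setNames(numeric(96), classes)
    y96[1:6] <- y
    f <- fit_exposures(y96, A96)
    expect_equal(unname(f$proportions), unname(best), tolerance = 1e-2)
  }
})

test_that("mixture recovery over random cohorts has small exposure error", {
  cat4 <- make_toy_catalog(c("age_like", "apobec_CtoT", "apobec_CtoG", "flat"))
  cds <- generate_reference_cds(cohort_config(n_genes = 50, seed = 14))
  expo <- draw_exposures(20, colnames(cat4), 1, seed = 15)
  muts <- simulate_mutations(cds, cat4, expo, 2000, seed = 16)
  sp <- build_spectrum(muts, per_sample = TRUE)
  fit <- fit_exposures_all(sp[rownames(expo), ], cat4)
  expect_lt(mean(abs(fit$proportions - expo)), 0.05)
})

test_that("attribution assigns by maximum posterior with sane edge handling", {
  cat2 <- orthogonal_catalog()
  expo <- matrix(c(0.5, 0.5), 1, 2, dimnames = list("s1", colnames(cat2)))
  muts <- data.frame(sample_id = "s1", class = "A[C>A]A")
  att <- attribute_mutations(muts, cat2, expo)
  expect_equal(att$assigned_signature, "sigA")
  expect_equal(att$posterior, 1.0)

  # degenerate exposure: everything goes to the exposed signature
  cat4 <- make_toy_catalog(c("apobec_CtoG", "flat"))
  expo2 <- matrix(c(1, 0), 1, 2, dimnames = list("s1", colnames(cat4)))
  muts2 <- data.frame(sample_id = "s1",
                      class = c("T[C>G]A", "A[T>C]C", "G[C>T]G"))
  att2 <- attribute_mutations(muts2, cat4, expo2)
  expect_true(all(att2$assigned_signature == "apobec_CtoG"))

  # posteriors sum to one over signatures
  expo3 <- matrix(c(0.4, 0.6), 1, 2, dimnames = list("s1", colnames(cat4)))
  att3 <- attribute_mutations(muts2, cat4, expo3)
  pm <- attr(att3, "posterior_matrix")
  expect_equal(unname(rowSums(pm)), rep(1, nrow(pm)), tolerance = 1e-12)

  # class unreachable under exposed signatures: uniform + unresolved flag
  catz <- orthogonal_catalog()
  expoz <- matrix(c(1, 0), 1, 2, dimnames = list("s1", colnames(catz)))
  mz <- data.frame(sample_id = "s1", class = "T[T>G]T")
  attz <- attribute_mutations(mz, catz, expoz)
  expect_true(attz$unresolved)
})

test_that("attribution recovers ground truth on a well-separated catalog", {
  cat2 <- make_toy_catalog(c("apobec_CtoG", "age_like"))
  cds <- generate_reference_cds(cohort_config(n_genes = 50, seed = 18))
  expo <- draw_exposures(10, colnames(cat2), 1, seed = 19)
  muts <- simulate_mutations(cds, cat2, expo, 500, seed = 20)
  sp <- build_spectrum(muts, per_sample = TRUE)
  fit <- fit_exposures_all(sp[rownames(expo), ], cat2)
  att <- attribute_mutations(muts, cat2, fit$proportions)
  expect_gte(mean(att$assigned_signature == att$true_signature), 0.9)
})

test_that("per-sample proportions conserve counts and sum to one", {
  co <- tiny_cohort(seed = 23, n_samples = 8, mutations_per_sample = 60)
  sp <- build_spectrum(co$mutations, per_sample = TRUE)
  fit <- fit_exposures_all(sp, co$catalog)
  att <- attribute_mutations(co$mutations, co$catalog, fit$proportions)
  pr <- signature_proportions(att)
  expect_equal(sum(pr$counts), nrow(co$mutations))
  expect_equal(unname(rowSums(pr$proportions)), rep(1, nrow(pr$proportions)),
               tolerance = 1e-9)
})

test_that("dominant-signature grouping applies the 50/20/15 rules", {
  p <- matrix(c(0.6, 0.1, 0.35, 0.5, 0.199), ncol = 1,
              dimnames = list(paste0("s", 1:5), "sig"))
  g <- dominant_signature_groups(p, "sig")
  expect_equal(as.character(g$group),
               c("HIGH", "LOW", "EXCLUDED", "HIGH", "LOW"))
  expect_false(g$valid)  # 2 vs 2 < 15 in both groups

  p2 <- matrix(c(rep(0.8, 14), rep(0.05, 40)), ncol = 1,
               dimnames = list(paste0("s", 1:54), "sig"))
  expect_false(dominant_signature_groups(p2, "sig")$valid)  # 14 HIGH < 15
  p3 <- matrix(c(rep(0.8, 15), rep(0.05, 40)), ncol = 1,
               dimnames = list(paste0("s", 1:55), "sig"))
  expect_true(dominant_signature_groups(p3, "sig")$valid)

  p0 <- matrix(0, 10, 1, dimnames = list(paste0("s", 1:10), "sig"))
  g0 <- dominant_signature_groups(p0, "sig")
  expect_true(all(g0$group == "LOW"))
  expect_false(g0$valid)
})

test_that("burden extremes take the pooled top and bottom fifth", {
  counts <- setNames(1:10, paste0("s", 1:10))
  g <- burden_extreme_groups(counts, frac = 0.2)
  expect_equal(names(g)[g == "TOP"], c("s9", "s10"))
  expect_equal(names(g)[g == "BOTTOM"], c("s1", "s2"))
  expect_warning(burden_extreme_groups(setNames(rep(5, 10), paste0("s", 1:10))),
                 "input order")
  expect_error(burden_extreme_groups(1:4), "at least 5")
})
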