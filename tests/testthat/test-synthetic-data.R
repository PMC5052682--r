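# Synthetic cohort generators: structural constraints, determinism, and the
# statistical structure the downstream analyses assume.

test_that("generated CDS satisfy coding constraints and hit the GC target", {
  cfg <- cohort_config(n_genes = 100, cds_length_range = c(999, 999),
                       gc_content = 0.5, seed = 3)
  cds <- generate_reference_cds(cfg)
  expect_length(cds, 100)
  expect_true(all(nchar(cds) %% 3 == 0))
  expect_true(all(substr(cds, 1, 3) == "ATG"))
  expect_true(all(substring(cds, nchar(cds) - 2) %in% c("TAA", "TAG", "TGA")))
  internal_codons <- unlist(lapply(cds, function(s) {
    n <- nchar(s)
    substring(s, seq(4, n - 3, 3), seq(6, n - 3, 3))
  }))
  expect_false(any(internal_codons %in% c("TAA", "TAG", "TGA")))
  pooled <- paste(cds, collapse = "")
  gc <- sum(strsplit(pooled, "")[[1]] %in% c("G", "C")) / nchar(pooled)
  expect_gt(gc, 0.45)
  expect_lt(gc, 0.55)
})

test_that("a minimal CDS is a valid 10-codon gene", {
  cfg <- cohort_config(n_genes = 1, cds_length_range = c(30, 30), seed = 1)
  cds <- generate_reference_cds(cfg)
  expect_equal(nchar(cds[[1]]), 30)
  expect_equal(substr(cds[[1]], 1, 3), "ATG")
  expect_true(substring(cds[[1]], 28) %in% c("TAA", "TAG", "TGA"))
})

test_that("the same seed reproduces every generator byte-identically", {
  cfg <- cohort_config(n_samples = 10, n_genes = 15, seed = 99,
                       mutations_per_sample = 50, n_transcripts = 60,
                       module_size = 10)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cds, b$cds)
  expect_identical(a$mutations, b$mutations)
  expect_identical(a$expression, b$expression)
  expect_identical(a$clinical, b$clinical)
  fa1 <- tempfile(fileext = ".fa"); fa2 <- tempfile(fileext = ".fa")
  write_cds_fasta(a$cds, fa1); write_cds_fasta(b$cds, fa2)
  expect_identical(readLines(fa1), readLines(fa2))
})

test_that("toy catalog profiles place their mass as advertised", {
  cat5 <- make_toy_catalog(TOY <- c("age_like", "apobec_CtoT", "apobec_CtoG",
                                    "flat", "brca_like"))
  expect_equal(unname(colSums(cat5)), rep(1, 5), tolerance = 1e-12)
  expect_equal(unname(cat5[, "flat"]), rep(1 / 96, 96))
  tcg <- sprintf("T[C>G]%s", c("A", "C", "G", "T"))
  tct <- sprintf("T[C>T]%s", c("A", "C", "G", "T"))
  ncg <- sprintf("%s[C>T]G", c("A", "C", "G", "T"))
  expect_gte(sum(cat5[tcg, "apobec_CtoG"]), 0.9)
  expect_gte(sum(cat5[tct, "apobec_CtoT"]), 0.9)
  expect_gte(sum(cat5[ncg, "age_like"]), 0.9)
  expect_error(make_toy_catalog("sig13"), "supported ids")
})

test_that("a degenerate single-class mixture emits only that class", {
  classes <- context_classes_96()
  m <- matrix(0, 96, 1, dimnames = list(classes, "only"))
  m["T[C>A]A", 1] <- 1
  cds <- generate_reference_cds(cohort_config(n_genes = 20, seed = 5))
  expo <- matrix(1, 4, 1, dimnames = list(sprintf("s%03d", 1:4), "only"))
  muts <- simulate_mutations(cds, m, expo, 25, seed = 8)
  expect_equal(nrow(muts), 100)
  expect_true(all(muts$class == "T[C>A]A"))
  # re-derive the class from the emitted coordinates: must agree
  reclassified <- classify_mutations(muts[setdiff(names(muts), "class")], cds)
  expect_equal(reclassified$class, muts$class)
})

test_that("mutation table size is samples x n_per_sample", {
  co <- tiny_cohort(seed = 2)
  cat2 <- co$catalog
  expo <- draw_exposures(20, colnames(cat2), 1, seed = 4)
  muts <- simulate_mutations(co$cds, cat2, expo, 500, seed = 4)
  expect_equal(nrow(muts), 10000)
  expect_equal(unname(table(muts$sample_id)[rownames(expo)]),
               rep(500L, 20), ignore_attr = TRUE)
})

test_that("pooled spectrum converges to the exposure-weighted mixture", {
  cds <- generate_reference_cds(cohort_config(n_genes = 60, seed = 11))
  cat4 <- make_toy_catalog(c("age_like", "apobec_CtoT", "apobec_CtoG", "flat"))
  w <- c(0.3, 0.2, 0.3, 0.2)
  expo <- matrix(w, 1, 4, dimnames = list("s001", colnames(cat4)))
  muts <- simulate_mutations(cds, cat4, expo, 50000, seed = 12)
  spec <- build_spectrum(muts)
  emp <- spec / sum(spec)
  target <- as.numeric(cat4 %*% w)
  expect_lt(sum(abs(emp - target)) / 2, 0.05)  # total variation
  # flat component alone passes a goodness-of-fit test against uniform
  flat_expo <- matrix(1, 1, 1, dimnames = list("s001", "flat"))
  fm <- simulate_mutations(cds, cat4[, "flat", drop = FALSE], flat_expo,
                           50000, seed = 13)
  fs <- build_spectrum(fm)
  gof <- suppressWarnings(stats::chisq.test(as.integer(fs),
                                            p = rep(1 / 96, 96)))
  expect_gt(gof$p.value, 0.01)
})

test_that("every simulated mutation carries its generating signature", {
  co <- tiny_cohort(seed = 21)
  expect_true(all(co$mutations$true_signature %in% colnames(co$catalog)))
  expect_false(anyNA(co$mutations$true_signature))
})

test_that("expression modules track their covariates as planted", {
  samples <- sprintf("s%03d", 1:50)
  set.seed(123)
  cov <- data.frame(x = rnorm(50))
  spec0 <- list(M = list(genes = sprintf("g%02d", 1:20), covariate = "x",
                         effect = 0))
  m0 <- simulate_expression(samples, spec0, cov, noise_sd = 1, seed = 5,
                            n_background = 10)
  r0 <- cor(colMeans(m0[sprintf("g%02d", 1:20), ]), cov$x)
  expect_lt(abs(r0), 0.2)

  # noiseless limit: module mean is an exact affine map of the covariate
  spec1 <- list(M = list(genes = sprintf("g%02d", 1:20), covariate = "x",
                         effect = 1))
  m1 <- simulate_expression(samples, spec1, cov, noise_sd = 0, seed = 5,
                            n_background = 0)
  mm <- colMeans(m1)
  z <- (cov$x - mean(cov$x)) / sd(cov$x)
  expect_equal(unname(mm - mean(mm)), z, tolerance = 1e-12)

  # planted effect 0.8 at n = 200: module mean correlates > 0.5
  hits <- vapply(1:100, function(s) {
    cv <- data.frame(total = rpois(200, 100))
    mx <- simulate_expression(sprintf("t%03d", 1:200),
      list(MCC = list(genes = sprintf("g%02d", 1:20), covariate = "total",
                      effect = 0.8)),
      cv, noise_sd = 1, seed = s, n_background = 0)
    cor(colMeans(mx), cv$total) > 0.5
  }, TRUE)
  expect_gte(mean(hits), 0.95)
  # overlapping modules are rejected
  expect_error(simulate_expression(samples,
    list(A = list(genes = "g01", covariate = "x", effect = 1),
         B = list(genes = "g01", covariate = "x", effect = 1)),
    cov, seed = 1), "disjoint")
})

test_that("clinical simulation honours censoring and plants infiltrate trends", {
  sc <- data.frame(x = rnorm(100), row.names = sprintf("s%03d", 1:100))
  cl0 <- simulate_clinical(sc, censor_rate = 0, seed = 3)
  expect_true(all(cl0$event == 1L))
  cl3 <- simulate_clinical(sc, censor_rate = 0.3, seed = 3)
  expect_equal(mean(cl3$event == 0), 0.3, tolerance = 0.12)
  expect_setequal(unique(cl3$infiltrate), 0:2)
  expect_error(simulate_clinical(data.frame(x = c(1, NA)), seed = 1),
               "non-finite")

  # planted gamma = 1 on a count covariate: Cuzick detects it almost always
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    cov <- data.frame(cnt = rpois(300, 40))
    cl <- simulate_clinical(cov, infiltrate_betas = c(cnt = 1.0),
                            censor_rate = 0, seed = s)
    ct <- cuzick_trend(cov$cnt, factor(cl$infiltrate, levels = 0:2,
                                       ordered = TRUE))
    ct$p_value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.90)
})

test_that("null survival effects give uniform logrank behaviour", {
  rej <- vapply(1:200, function(s) {
    sc <- data.frame(x = rnorm(60), row.names = sprintf("s%03d", 1:60))
    cl <- simulate_clinical(sc, hazard_betas = c(x = 0), censor_rate = 0.2,
                            seed = s)
    grp <- factor(sc$x > median(sc$x))
    km_logrank(cl$time_months, cl$event, grp)$p_value < 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.015)
  expect_lte(mean(rej), 0.10)
})
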