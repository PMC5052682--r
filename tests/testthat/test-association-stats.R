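# The statistical layer: rank tests, Cuzick's trend test, contingency tests,
# per-signature association tables, survival tests.

test_that("Mann-Whitney U gives exact small-sample p-values", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)  # 2 of the 6 assignments
  same <- mann_whitney_u(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_gt(same$p_value, 0.9)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney U holds its size under the null", {
  rej <- vapply(1:2000, function(s) {
    set.seed(s)
    mann_whitney_u(rnorm(30), rnorm(30))$p_value < 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.035)
  expect_lte(mean(rej), 0.065)
})

test_that("Kruskal-Wallis behaves and orders consistently with MWU", {
  expect_equal(kruskal_wallis(list(rep(2, 5), rep(2, 4)))$statistic, 0)
  expect_error(kruskal_wallis(list(1:3)), "at least 2")
  set.seed(4)
  ps <- t(vapply(1:30, function(i) {
    x <- rnorm(12); y <- rnorm(12, mean = runif(1, 0, 2))
    c(mwu = mann_whitney_u(x, y)$p_value,
      kw = kruskal_wallis(list(x, y))$p_value)
  }, c(mwu = 0, kw = 0)))
  expect_gt(cor(rank(ps[, "mwu"]), rank(ps[, "kw"])), 0.99)
})

test_that("Cuzick's trend statistic matches the hand-computed fixture", {
  ct <- cuzick_trend(c(1, 2, 3, 4, 5, 6), rep(1:3, each = 2))
  expect_equal(ct$statistic, 50)
  expect_equal(ct$expectation, 42)
  expect_equal(ct$variance, 14)
  expect_equal(ct$z, 8 / sqrt(14), tolerance = 1e-12)
  expect_equal(ct$p_value, 2 * pnorm(-8 / sqrt(14)), tolerance = 1e-12)
})

test_that("Cuzick handles degenerate, reversed and rescaled inputs", {
  const <- cuzick_trend(rep(3, 9), rep(1:3, each = 3))
  expect_equal(const$z, 0)
  expect_equal(const$p_value, 1)
  x <- c(5, 1, 4, 2, 8, 9, 3, 3, 7)
  g <- rep(1:3, each = 3)
  fwd <- cuzick_trend(x, g)
  rev <- cuzick_trend(x, factor(g, levels = 3:1))
  expect_equal(rev$z, -fwd$z, tolerance = 1e-12)
  expect_equal(rev$p_value, fwd$p_value, tolerance = 1e-12)
  # affine invariance of the group scores
  sc0 <- cuzick_trend(x, g, scores = c(0, 1, 2))
  sc10 <- cuzick_trend(x, g, scores = c(10, 30, 50))
  expect_equal(sc0$z, fwd$z, tolerance = 1e-12)
  expect_equal(sc10$z, fwd$z, tolerance = 1e-12)
  expect_error(cuzick_trend(1:3, rep(1, 3)), "at least 2")
})

test_that("contingency tests apply the low-count rule", {
  bal <- contingency_test(matrix(c(5, 5, 5, 5), 2))
  expect_equal(bal$fisher_p, 1)
  diag <- contingency_test(matrix(c(10, 0, 0, 10), 2))
  expect_equal(diag$fisher_p, 2 / choose(20, 10), tolerance = 1e-9)
  low <- contingency_test(matrix(c(6, 1, 2, 7), 2))
  expect_equal(low$primary, "fisher")  # expected cells below 5
  big <- contingency_test(matrix(c(50, 30, 30, 55), 2))
  expect_equal(big$primary, "chisq")
  expect_error(contingency_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
  # chi-square and Fisher agree in ordering on well-filled tables
  set.seed(12)
  ps <- t(vapply(1:100, function(i) {
    tab <- matrix(rpois(4, 40) + 5, 2)
    r <- contingency_test(tab)
    c(r$chisq_p, r$fisher_p)
  }, c(0, 0)))
  expect_gt(cor(rank(ps[, 1]), rank(ps[, 2])), 0.98)
})

test_that("per-signature group association reports means and N.D. entries", {
  set.seed(5)
  counts <- cbind(sig_a = c(rpois(10, 50), rpois(10, 10)),
                  sig_b = rpois(20, 20),
                  sig_rare = rep(0L, 20))
  rownames(counts) <- sprintf("s%02d", 1:20)
  grp <- setNames(factor(rep(c("HIGH", "LOW"), each = 10)), rownames(counts))
  res <- per_signature_group_association(counts, grp, "absolute",
                                         exclude_signatures = "sig_rare")
  expect_equal(res$note, c("", "", "N.D."))
  expect_lt(res$p_value[res$signature == "sig_a"], 0.01)
  expect_true(is.na(res$p_value[res$signature == "sig_rare"]))
  expect_equal(res$mean_HIGH[1], mean(counts[1:10, "sig_a"]))

  # proportional mode is invariant to per-sample scaling
  res_p <- per_signature_group_association(counts[, 1:2], grp, "proportional")
  scaled <- counts[, 1:2] * rep(c(1, 7), each = 10)
  res_s <- per_signature_group_association(scaled, grp, "proportional")
  expect_equal(res_p$p_value, res_s$p_value, tolerance = 1e-12)
})

test_that("per-signature infiltrate trend mirrors the table layout", {
  set.seed(6)
  infl <- setNames(factor(rep(0:2, each = 10), ordered = TRUE),
                   sprintf("s%02d", 1:30))
  counts <- cbind(up = rpois(30, rep(c(5, 15, 40), each = 10)),
                  flat = rep(7L, 30))
  rownames(counts) <- names(infl)
  res <- infiltrate_trend_per_signature(counts, infl, "absolute")
  expect_lt(res$p_value[res$signature == "up"], 0.001)
  expect_equal(res$p_value[res$signature == "flat"], 1)
  expect_equal(res$mean_0[res$signature == "flat"], 7)
  expect_equal(names(res)[5:7], c("mean_0", "mean_1", "mean_2"))
})

test_that("logrank and its trend version behave on constructed survival data", {
  t1 <- c(5, 10, 15, 20, 25, 30, 35, 40)
  d <- data.frame(time = rep(t1, 2), event = 1,
                  g = rep(c("a", "b"), each = 8))
  r <- km_logrank(d$time, d$event, d$g)
  expect_lt(r$statistic, 1e-10)
  expect_gt(r$p_value, 0.99)

  set.seed(8)
  n <- 150
  g <- factor(rep(1:3, each = n / 3), ordered = TRUE)
  haz <- c(1, 1.5, 2.25)[as.integer(g)]
  tt <- rexp(n, rate = 0.02 * haz)
  tr <- km_logrank(tt, rep(1, n), g, trend = TRUE)
  expect_lt(tr$p_value, 0.05)
  expect_gt(tr$z, 0)  # higher ordered groups die faster
  expect_error(km_logrank(tt, rep(0, n), g), "no events")
})

test_that("Cox fits report HRs and reject degenerate designs", {
  set.seed(14)
  n <- 400
  x <- rbinom(n, 1, 0.5)
  tt <- rexp(n, rate = 0.01 * exp(log(2) * x))
  cx <- cox_ph(data.frame(x = x), tt, rep(1, n))
  expect_gt(cx$hr, 1.4)
  expect_lt(cx$hr, 2.9)
  expect_lt(cx$p_value, 0.001)
  expect_error(cox_ph(data.frame(x = x, y = x), tt, rep(1, n)),
               "rank deficient")
  expect_error(cox_ph(data.frame(x = rep(1, n)), tt, rep(1, n)), "constant")
})
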