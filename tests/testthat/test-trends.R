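test_that("paired log10 t test is antisymmetric and guards its domain", {
  x <- c(2.3, 4.1, 1.2, 8.8, 3.3)
  y <- c(3.1, 3.9, 2.2, 9.9, 4.0)
  ab <- paired_t_log10(x, y)
  ba <- paired_t_log10(y, x)
  expect_equal(ab$statistic, -ba$statistic, tolerance = 1e-12)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  expect_equal(ab$n_pairs, 5)

  expect_error(paired_t_log10(x, x), "zero variance")
  expect_error(paired_t_log10(c(1, -2, 3), c(1, 2, 3)), "positive")
  # pairs with a missing member are dropped before testing
  xm <- c(x, NA); ym <- c(y, 5)
  expect_equal(paired_t_log10(xm, ym)$n_pairs, 5)
})

test_that("signed-rank test scores all-positive shifts at the maximum", {
  x <- c(1, 2, 3, 4, 5)
  res <- wilcoxon_signed_rank(x, x + 2)
  expect_equal(res$w_plus, 15)
  # a constant shift ties all |d| in one group of 5, so the tie-corrected
  # variance is 5*6*11/24 - (5^3 - 5)/48 = 11.25
  expect_equal(res$statistic, 7.5 / sqrt(11.25), tolerance = 1e-12)
  # no sign pattern with these ties scores a larger Z
  perturbed <- wilcoxon_signed_rank(x, x + c(2, 2, 2, 2, -2))
  expect_lt(perturbed$statistic, res$statistic)
  expect_error(wilcoxon_signed_rank(x, x), "zero")
})

test_that("signed-rank Z agrees in ordering with exact enumeration (n <= 10)", {
  set.seed(99)
  fixtures <- lapply(1:25, function(i) {
    n <- sample(4:10, 1)
    x <- round(runif(n, 1, 20), 1)
    d <- round(rnorm(n, sample(c(-1, 0.5, 1.5), 1), 2), 1)
    list(x = x, y = x + ifelse(d == 0, 0.3, d))
  })
  p_norm <- sapply(fixtures, function(f) wilcoxon_signed_rank(f$x, f$y)$p_value)
  p_exact <- sapply(fixtures, function(f) exact_wilcoxon_p(f$x, f$y))
  n_eff <- sapply(fixtures, function(f) sum(f$y != f$x))
  # among fixtures of equal size the approximation must rank the evidence
  # exactly as the enumeration does (across sizes the exact p's granularity
  # changes, so global ordering is not an invariant of the approximation)
  for (i in seq_along(fixtures)) {
    for (j in seq_along(fixtures)) {
      if (n_eff[i] == n_eff[j] && p_exact[i] < p_exact[j] - 1e-9) {
        expect_lte(p_norm[i], p_norm[j] + 1e-9)
      }
    }
  }
  expect_gt(cor(rank(p_norm), rank(p_exact)), 0.98)
})

test_that("signed-rank Z is invariant under positive affine transforms", {
  set.seed(5)
  x <- runif(12, 1, 10); y <- x + rnorm(12)
  z0 <- wilcoxon_signed_rank(x, y)$statistic
  expect_equal(wilcoxon_signed_rank(10 * x + 3, 10 * y + 3)$statistic, z0,
               tolerance = 1e-12)
})

test_that("spearman matches its closed-form extremes and the stats oracle", {
  x <- c(1, 2, 5, 9, 14)
  expect_equal(spearman(x, x^3)$rho, 1.0)
  expect_equal(spearman(x, -x)$rho, -1.0)
  expect_error(spearman(c(1, 1, 1, 1), x[1:4]), "constant")
  expect_error(spearman(1:3, 3:1), "at least 4")

  set.seed(8)
  a <- rnorm(20); b <- 0.5 * a + rnorm(20)
  s <- spearman(a, b)
  oracle <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                             exact = FALSE))
  expect_equal(s$rho, unname(oracle$estimate), tolerance = 1e-12)
  expect_equal(s$p_value, oracle$p.value, tolerance = 1e-9)
})

test_that("Holm step-down flags match the rule and the p.adjust oracle", {
  expect_equal(holm_adjust(c(0.001, 0.04, 0.3)), c(TRUE, FALSE, FALSE))
  expect_equal(holm_adjust(rep(1, 4)), rep(FALSE, 4))
  expect_equal(holm_adjust(0.04), TRUE)
  expect_error(holm_adjust(c(0.2, 1.4)), "\\[0, 1\\]")

  set.seed(123)
  for (i in 1:200) {
    p <- runif(sample(1:12, 1))^sample(1:3, 1)
    flags <- holm_adjust(p)
    expect_equal(flags, stats::p.adjust(p, method = "holm") <= 0.05)
    # monotone: anything smaller than a flagged p is flagged
    if (any(flags)) expect_true(all(flags[p <= max(p[flags])]))
  }
})

test_that("correlation tables recover built-in dependence and ignore noise", {
  tissue <- generate_tissue(generator_config(n_sites = 20, seed = 44))
  cs <- chem_site_summary(tissue)
  cm <- correlation_matrix(cs[, c("total_ots", "TPT", "TBT")])
  row <- cm[cm$var1 == "total_ots" & cm$var2 == "TPT", ]
  expect_gt(row$rho, 0.9)  # TPT dominates the generator's totals
  expect_true(row$significant)

  set.seed(10)
  indep <- data.frame(a = rnorm(29), b = rnorm(29))
  cm2 <- correlation_matrix(indep)
  expect_equal(nrow(cm2), 1)
  expect_lt(abs(cm2$rho), 0.4)
  expect_false(cm2$significant)
})

test_that("epoch comparisons on the packaged table reproduce published statistics", {
  tr <- epoch_trends()
  pick <- function(var, from, to) tr[tr$variable == var &
                                       tr$epoch_from == from &
                                       tr$epoch_to == to, ]
  expect_equal(pick("mean_vdsi", "2010", "2015")$n_pairs, 10)
  expect_equal(pick("mean_vdsi", "2004-06", "2010")$n_pairs, 28)
  expect_equal(pick("rpsi", "2004-06", "2010")$df, 27)

  dc <- distance_correlations(epoch = "2010")
  vdsi_row <- dc[dc$var2 == "mean_vdsi" | dc$var1 == "mean_vdsi", ]
  expect_lt(vdsi_row$rho, 0)  # imposex declines away from shipping
})
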