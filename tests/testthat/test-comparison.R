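test_that("functional-site calling follows the stated rules", {
  d <- mutational_dataset(1:3, c(0.99, 1.0, 2.5))
  d <- call_functional_sites(d, "effect_threshold", 1)
  expect_equal(d$functional, c(FALSE, TRUE, TRUE))   # strict |effect| >= 1

  d2 <- mutational_dataset(1:3, c(0, 0, 0),
                           n_deleterious = c(8L, 7L, 13L),
                           n_tested = c(13L, 13L, 13L))
  d2 <- call_functional_sites(d2, "count_threshold", 8)
  expect_equal(d2$functional, c(TRUE, FALSE, TRUE))
  # raising the threshold never adds functional sites
  prev <- rep(TRUE, 3)
  for (thr in 1:10) {
    cur <- call_functional_sites(d2, "count_threshold", thr)$functional
    expect_true(all(cur[!prev] == FALSE))
    expect_true(all(!cur | prev))
    prev <- cur
  }
  expect_error(call_functional_sites(d, "nope", 1))
})

test_that("contingency tables cross-tabulate membership by function", {
  # the PDZ-style layout: 80 scored positions, 20 functional, a 21-position
  # set capturing 14 of them
  d <- mutational_dataset(1:80, rep(0, 80))
  d$functional <- c(rep(TRUE, 20), rep(FALSE, 60))
  setA <- c(1:14, 21:27)
  tab <- contingency(setA, d)
  expect_equal(unname(tab), matrix(c(14, 7, 6, 53), 2, byrow = TRUE))
  expect_equal(sum(tab), 80)
  expect_equal(unname(contingency(integer(0), d)[1, ]), c(0, 0))
  expect_equal(unname(contingency(1:80, d)[2, ]), c(0, 0))
  expect_error(contingency(99, d), "outside")
})

test_that("one-tailed Fisher matches hand-derived values", {
  tab <- matrix(c(14, 7, 6, 53), 2, byrow = TRUE)
  expect_equal(fisher_one_tailed(tab), 1.561503e-06, tolerance = 1e-4)
  expect_equal(fisher_one_tailed(matrix(c(1, 1, 1, 1), 2)), 5 / 6,
               tolerance = 1e-12)
  # observed zero: whole upper tail
  expect_equal(fisher_one_tailed(matrix(c(0, 3, 4, 5), 2, byrow = TRUE)), 1)
  expect_warning(p <- fisher_one_tailed(matrix(c(0, 0, 4, 5), 2, byrow = TRUE)),
                 "degenerate")
  expect_equal(p, 1)
})

test_that("Fisher agrees with enumeration and fisher.test on small tables", {
  set.seed(2)
  for (rep in 1:40) {
    tot <- sample(4:30, 1)
    cells <- as.vector(stats::rmultinom(1, tot, rep(0.25, 4)))
    tab <- matrix(cells, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisher_one_tailed(tab)
    expect_equal(p, bf_fisher_tail(tab), tolerance = 1e-10)
    expect_equal(p, stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-8)
    expect_gt(p, 0); expect_lte(p, 1)
  }
})

test_that("chi-squared table comparison has the documented edge behavior", {
  tabA <- matrix(c(14, 7, 6, 53), 2, byrow = TRUE)
  res <- chi2_compare_tables(tabA, tabA)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
  # orthogonal rows: statistic 40 (all expected counts are 10)
  t1 <- matrix(c(20, 0, 0, 0), 2, byrow = TRUE)
  t2 <- matrix(c(0, 20, 0, 0), 2, byrow = TRUE)
  res2 <- chi2_compare_tables(t1, t2)
  expect_equal(res2$statistic, 40)
  expect_lt(res2$p.value, 1e-9)
  expect_warning(res3 <- chi2_compare_tables(matrix(c(0, 0, 1, 1), 2),
                                             matrix(c(0, 0, 1, 1), 2)),
                 "zero expected")
  expect_true(is.na(res3$p.value))
  # Yates option changes the statistic for non-identical rows
  res4 <- chi2_compare_tables(tabA, matrix(c(12, 9, 8, 51), 2, byrow = TRUE),
                              yates = TRUE)
  res5 <- chi2_compare_tables(tabA, matrix(c(12, 9, 8, 51), 2, byrow = TRUE))
  expect_lt(res4$statistic, res5$statistic)
})

test_that("Mann-Whitney exact mode matches enumeration and wilcox.test", {
  d <- mutational_dataset(1:6, c(1, 2, 3, 10, 11, 12))
  mw <- mannwhitney_effects(d, 1:3, 4:6)
  expect_equal(mw$p.value, 0.1, tolerance = 1e-12)
  expect_equal(mw$method, "exact")
  # identical samples
  expect_equal(mannwhitney_effects(d, 1:3, 1:3)$p.value, 1)
  # rank statistic invariant under monotone transforms
  d2 <- mutational_dataset(1:6, exp(c(1, 2, 3, 10, 11, 12)))
  expect_equal(mannwhitney_effects(d2, 1:3, 4:6)$p.value, mw$p.value)
  # agreement with the exact U null distribution on random tie-free samples
  set.seed(9)
  for (rep in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    a <- sample(100, n1); b <- sample(100, n2)
    while (any(b %in% a)) b <- sample(100, n2)
    p <- mannwhitney_values(a, b)$p.value
    expect_equal(p, bf_mw_exact(a, b), tolerance = 1e-10)
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = TRUE))
    expect_equal(p, wt$p.value, tolerance = 1e-8)
  }
})

test_that("Mann-Whitney normal approximation matches wilcox.test with ties", {
  set.seed(10)
  a <- sample(1:5, 20, replace = TRUE)
  b <- sample(2:7, 25, replace = TRUE)
  p <- mannwhitney_values(a, b)$p.value
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = FALSE))
  expect_equal(p, wt$p.value, tolerance = 1e-10)
  expect_error(mannwhitney_effects(mutational_dataset(1, 1), integer(0), 1),
               "nonempty")
})

test_that("sector-size sweep reports p-values and overlap fractions", {
  aln <- sample_independent_alignment(300, 40, heterogeneous_profile(40), seed = 21)
  res <- run_sca(aln, q_aa = aa_background("uniform"))
  data <- sample_mutational_effects(res$D, noise_sd = 0.2,
                                    functional_threshold = 1, seed = 22)
  sw <- sweep_sector_size(res$spec, res$D, data, sizes = c(5, 10, 40))
  expect_true(all(sw$overlap >= 0 & sw$overlap <= 1))
  # k = n: both sets are the whole universe
  expect_equal(sw$p_mannwhitney[sw$size == 40], 1)
  expect_equal(sw$overlap[sw$size == 40], 1)
  expect_error(sweep_sector_size(res$spec, res$D, data, sizes = 0))
})

test_that("phenotype regression recovers exact linear structure", {
  set.seed(12)
  V <- qr.Q(qr(matrix(rnorm(100), 20, 5)))
  V <- sweep(V, 2, sign(colSums(V) + 1e-15), "*")
  spec <- list(values = 5:1, vectors = V)
  pheno <- 2 * V[, 1] - V[, 2]
  fit <- suppressWarnings(      # lm flags the noise-free, exact fit
    regress_phenotypes_on_eigenvectors(pheno, spec, 1:20, 2))
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients[2:3]), c(2, -1), tolerance = 1e-8)
  # m = 0: intercept only
  fit0 <- regress_phenotypes_on_eigenvectors(pheno, spec, 1:20, 0)
  expect_equal(fit0$r_squared, 0)
  expect_equal(unname(fit0$fitted), rep(mean(pheno), 20))
  expect_error(regress_phenotypes_on_eigenvectors(pheno[1:3], spec, 1:3, 3),
               "underdetermined")
})

test_that("null-phenotype regression R2 is near m/(npts - 1)", {
  set.seed(13)
  V <- qr.Q(qr(matrix(rnorm(100 * 6), 100, 6)))
  spec <- list(values = 6:1, vectors = V)
  r2 <- replicate(200, {
    regress_phenotypes_on_eigenvectors(rnorm(100), spec, 1:100, 3)$r_squared
  })
  expect_equal(mean(r2), 3 / 99, tolerance = 0.3)
  expect_lt(max(r2), 0.25)
})
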