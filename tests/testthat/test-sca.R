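uq <- function(aln) background_with_gap(aln, aa_background("uniform"))

test_that("positional weights match the log-odds form", {
  # f = q: weight 0
  f <- matrix(c(rep(0.05, 20), 0), ncol = 1)
  rownames(f) <- rownames(column_frequencies(aln_from_strings("A")))
  q <- c(aa_background("uniform"), "-" = 0)
  phi <- positional_weights(f, q)
  expect_equal(unname(phi[, 1]), rep(0, 20))
  # f = 0.5, q = 0.05: ln 19
  f2 <- f; f2[1:20, 1] <- c(0.5, rep(0.5 / 19, 19))
  phi2 <- positional_weights(f2, q)
  expect_equal(unname(phi2["A", 1]), log(0.5 / 0.5 * 0.95 / 0.05), tolerance = 1e-12)
  expect_equal(unname(phi2["A", 1]), log(19), tolerance = 1e-12)
  # below-background frequencies give negative weights
  expect_true(all(phi2[2:20, 1] < 0))
  # degenerate background rejected
  qbad <- q; qbad[1] <- 0
  expect_error(positional_weights(f, qbad), "strictly in")
})

test_that("projection zeroes gaps and self-normalizes single-residue columns", {
  aln <- aln_from_strings(c("A-", "AC", "AC", "A-"))
  f <- column_frequencies(aln)
  phi <- positional_weights(f, uq(aln))
  xt <- project_alignment(aln, f, phi)
  expect_equal(xt[c(1, 4), 2], c(0, 0))            # gap cells are zero
  # column 1 has a single residue: all entries equal with magnitude 1
  expect_equal(abs(xt[, 1]), rep(1, 4))
  # degenerate column (f = q exactly) becomes all-zero with a warning
  q0 <- c(aa_background("uniform"), "-" = 0)
  f2 <- f; f2[, 1] <- q0
  phi2 <- positional_weights(f2, q0)
  expect_warning(xt2 <- project_alignment(aln, f2, phi2), "zero projection norm")
  expect_equal(xt2[, 1], rep(0, 4))
})

test_that("SCA matrix equals the absolute population covariance (oracle)", {
  set.seed(42)
  xt <- matrix(rnorm(20), 5, 4)
  C <- sca_matrix(xt)
  expect_equal(C, bf_abs_cov(xt), tolerance = 1e-12)
  expect_true(isSymmetric(C))
  expect_true(all(C >= 0))
  # identical sequences give a zero matrix
  aln <- aln_from_strings(c("ACD", "ACD", "ACD"))
  f <- column_frequencies(aln)
  xt0 <- project_alignment(aln, f, positional_weights(f, uq(aln)))
  expect_equal(max(sca_matrix(xt0)), 0)
  expect_error(sca_matrix(matrix(1, 1, 3)), "at least 2")
})

test_that("full SCA pipeline agrees with a first-principles recomputation", {
  set.seed(7)
  for (rep in 1:4) {
    N <- sample(3:8, 1); n <- sample(3:6, 1)
    strings <- replicate(N, paste(sample(c("A", "C", "D", "E"), n, replace = TRUE),
                                  collapse = ""))
    aln <- aln_from_strings(strings)
    res <- run_sca(aln, q_aa = aa_background("uniform"), m = 1L)
    q21 <- uq(aln)
    expect_equal(res$C, bf_sca_from_alignment(aln, q21), tolerance = 1e-10)
  }
})

test_that("spectral decomposition is ordered, unit-norm, sign-fixed, complete", {
  s <- sca_spectral(diag(c(3, 1, 2)))
  expect_equal(s$values, c(3, 2, 1))
  expect_equal(abs(s$vectors[, 1]), c(1, 0, 0))
  set.seed(8)
  A <- crossprod(matrix(rnorm(49), 7))
  s <- sca_spectral(A)
  expect_true(all(diff(s$values) <= 1e-12))
  expect_equal(colSums(s$vectors^2), rep(1, 7))
  expect_true(all(colSums(s$vectors) >= -1e-12))
  # reconstruction over all modes
  recon <- s$vectors %*% diag(s$values) %*% t(s$vectors)
  expect_equal(recon, A, tolerance = 1e-8)
  expect_error(sca_spectral(matrix(rnorm(9), 3)), "not symmetric")
})

test_that("sector extraction takes round(fraction * n) top components", {
  spec <- list(vectors = cbind(c(0.9, 0.1, 0.5)))
  expect_equal(extract_sector(spec, 3, 1 / 3)$positions, 1L)
  # sector sizes at the 25% convention
  spec2 <- list(vectors = cbind(runif(328)))
  expect_equal(extract_sector(spec2, 328, 0.25)$size, 82L)
  spec3 <- list(vectors = cbind(runif(84)))
  expect_equal(extract_sector(spec3, 84, 0.25)$size, 21L)
  expect_error(extract_sector(spec, 3, 0.01), "at least 1")
})

test_that("column permutations permute the sector; row order is irrelevant", {
  aln <- sample_independent_alignment(60, 12, heterogeneous_profile(12), seed = 3)
  res <- run_sca(aln, q_aa = aa_background("uniform"), m = 2L)
  perm <- sample(12)
  aln_p <- new_alignment(aln$seqs[, perm], aln$ids)
  res_p <- run_sca(aln_p, q_aa = aa_background("uniform"), m = 2L)
  expect_equal(res_p$C, res$C[perm, perm], tolerance = 1e-12)
  expect_equal(sort(match(res$sector$positions, perm)),
               sort(res_p$sector$positions))
  rperm <- sample(nrow(aln$seqs))
  aln_r <- new_alignment(aln$seqs[rperm, ], aln$ids[rperm])
  res_r <- run_sca(aln_r, q_aa = aa_background("uniform"), m = 2L)
  expect_equal(res_r$C, res$C, tolerance = 1e-12)
  expect_equal(res_r$spec$values, res$spec$values, tolerance = 1e-12)
  expect_equal(sort(res_r$sector$positions), sort(res$sector$positions))
})

test_that("top eigenvector tracks sqrt(diagonal) and handles degeneracy", {
  # exact proportionality for an idealized matrix
  M <- build_idealized_matrix(rep(2, 6), 0.3)
  s <- sca_spectral(M)
  expect_warning(r2 <- topvec_diag_correlation(M, s), "zero-variance")
  expect_true(is.na(r2$r_sqrt_diag))         # constant diagonal is degenerate
  # heterogeneous case: near-perfect correlation
  M2 <- build_idealized_matrix(seq(0.5, 3, length.out = 8), 0.5)
  s2 <- sca_spectral(M2)
  expect_gt(topvec_diag_correlation(M2, s2)$r_sqrt_diag, 0.99)
})

test_that("eigenvalue gap grows with conservation heterogeneity", {
  # widen the profile upward: both the spread and the summed positional
  # variance grow, and with them the dominance of the top mode
  tops <- c(0.2, 0.4, 0.55)
  gaps <- sapply(seq_along(tops), function(i) {
    prof <- heterogeneous_profile(40, 0.1, tops[i])
    aln <- sample_independent_alignment(300, 40, prof, seed = 17)
    res <- run_sca(aln, q_aa = aa_background("uniform"), m = 2L)
    res$spec$values[1] - res$spec$values[2]
  })
  expect_true(all(diff(gaps) > 0))
})
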