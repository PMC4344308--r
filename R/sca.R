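#' Positional log-odds weights
#'
#' The projection-method weight for amino acid a at column i is
#' `phi_i(a) = ln[ f_i(a) (1 - q(a)) / ((1 - f_i(a)) q(a)) ]`, evaluated with
#' the column frequency clamped to `[clamp, 1 - clamp]` so the weight stays
#' finite when an amino acid is absent or fixed. The gap symbol carries no
#' weight. `phi_i(a) = 0` exactly when the (clamped) frequency equals the
#' background.
#'
#' @param f 21 x n frequency matrix from [column_frequencies()].
#' @param q background 21-vector; only the amino-acid entries are used.
#' @param clamp regularization bound for the frequency, default 0.001.
#' @return 20 x n matrix of weights, rows named by amino acid, with attribute
#'   `"clamp"`.
#' @export
positional_weights <- function(f, q, clamp = 0.001) {
  if (nrow(f) != 21L) stop("f must be 21 x n")
  q_aa <- q[1:20]
  if (any(q_aa <= 0 | q_aa >= 1))
    stop("background frequencies must lie strictly in (0, 1) for every amino acid")
  if (clamp <= 0 || clamp >= 0.5) stop("clamp must lie in (0, 0.5)")
  fa <- pmin(pmax(f[1:20, , drop = FALSE], clamp), 1 - clamp)
  phi <- log(fa / (1 - fa)) + log((1 - q_aa) / q_aa)
  rownames(phi) <- AA20
  attr(phi, "clamp") <- clamp
  phi
}

#' Project the alignment to a numeric matrix
#'
#' Each non-gap cell (k, i) holding amino acid a becomes
#' `x_ki = phi_i(a) f_i(a) / sqrt(sum_b phi_i(b)^2 f_i(b)^2)` (sum over the 20
#' amino acids); gap cells become 0. Columns whose normalization is zero (all
#' weights vanish, e.g. frequencies equal to background everywhere) are set to
#' zero with a warning.
#'
#' @param aln the `aln` object the frequencies were computed from.
#' @param f 21 x n frequency matrix.
#' @param phi 20 x n weight matrix from [positional_weights()].
#' @return N x n numeric matrix of projected values.
#' @export
project_alignment <- function(aln, f, phi) {
  stopifnot(inherits(aln, "aln"))
  n <- ncol(aln$seqs)
  if (ncol(f) != n || ncol(phi) != n)
    stop("frequency/weight matrices do not match the alignment's column count")
  w <- phi * f[1:20, , drop = FALSE]          # phi_i(a) * f_i(a), per symbol
  norms <- sqrt(colSums(w^2))
  dead <- norms == 0
  if (any(dead)) {
    warning(sprintf("%d column(s) with zero projection norm set to zero", sum(dead)))
    norms[dead] <- 1
  }
  wn <- sweep(w, 2L, norms, "/")
  xt <- matrix(0, nrow = nrow(aln$seqs), ncol = n)
  sym <- match(aln$seqs, ALPHABET21)          # vectorized over all cells
  dim(sym) <- dim(aln$seqs)
  for (j in seq_len(n)) {
    a <- sym[, j]
    nongap <- a <= 20L
    xt[nongap, j] <- wn[a[nongap], j]
  }
  xt[, dead] <- 0
  xt
}

#' SCA matrix (projection method)
#'
#' The elementwise absolute value of the population covariance matrix of the
#' projected alignment:
#' `C_ij = | (1/N) sum_k x_ki x_kj - (1/N^2) (sum_k x_ki)(sum_l x_lj) |`.
#'
#' @param xt N x n projected matrix from [project_alignment()].
#' @return n x n symmetric nonnegative matrix.
#' @export
sca_matrix <- function(xt) {
  N <- nrow(xt)
  if (N < 2L) stop("at least 2 sequences are required to estimate covariances")
  centered <- sweep(xt, 2L, colMeans(xt))
  abs(crossprod(centered) / N)
}

#' Spectral decomposition with a fixed sign convention
#'
#' Eigenvalues in descending order; each eigenvector unit-norm with its
#' component sum made nonnegative (orientation needed for deterministic sector
#' extraction).
#'
#' @param C symmetric matrix (asymmetry beyond `tol` is an error).
#' @param m number of leading modes to return (default: all).
#' @param tol symmetry tolerance, default 1e-8.
#' @return list with `values` (length m) and `vectors` (n x m).
#' @export
sca_spectral <- function(C, m = ncol(C), tol = 1e-8) {
  if (!isSymmetric(unname(C), tol = tol))
    stop("input matrix is not symmetric within tolerance")
  n <- ncol(C)
  if (m < 1L || m > n) stop(sprintf("m must lie in [1, %d]", n))
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  V <- e$vectors[, seq_len(m), drop = FALSE]
  flip <- colSums(V) < 0
  V[, flip] <- -V[, flip]
  list(values = e$values[seq_len(m)], vectors = V)
}

#' Extract the top-eigenvector sector
#'
#' The sector is the `round(fraction * n)` columns with the largest components
#' of the top eigenvector (rank-based extraction; ties broken by lower column
#' index), following the convention that the sector comprises about 25% of the
#' alignment positions.
#'
#' @param spec result of [sca_spectral()].
#' @param n number of alignment columns.
#' @param fraction sector-size fraction, default 0.25.
#' @return list with `positions` (column indices ordered by decreasing score),
#'   `scores` (the full top-eigenvector component vector), `fraction`, `size`.
#' @export
extract_sector <- function(spec, n, fraction = 0.25) {
  v <- spec$vectors[, 1L]
  if (length(v) != n) stop("eigenvector length does not match n")
  k <- round(fraction * n)
  if (k < 1L) stop("round(fraction * n) must be at least 1")
  ord <- order(-v, seq_len(n))
  list(positions = ord[seq_len(k)], scores = v, fraction = fraction, size = k)
}

#' Correlation of the top eigenvector with the matrix diagonal and conservation
#'
#' Pearson correlations of the top-eigenvector components against the square
#' root of the SCA matrix diagonal, and (optionally) against a conservation
#' profile. Zero-variance inputs give `NA` with a warning.
#'
#' @param C SCA matrix.
#' @param spec result of [sca_spectral()] on `C`.
#' @param D optional conservation vector.
#' @return list with `r_sqrt_diag`, `r_conservation` (NA if `D` missing or
#'   degenerate), and the paired data (`v_top`, `sqrt_diag`, `D`).
#' @export
topvec_diag_correlation <- function(C, spec, D = NULL) {
  if (ncol(C) < 3L) stop("need at least 3 columns for a meaningful correlation")
  v <- spec$vectors[, 1L]
  sd_ <- sqrt(diag(C))
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("zero-variance input; correlation undefined")
      return(NA_real_)
    }
    stats::cor(a, b)
  }
  r1 <- safe_cor(v, sd_)
  r2 <- if (is.null(D)) NA_real_ else safe_cor(v, D)
  list(r_sqrt_diag = r1, r_conservation = r2,
       v_top = v, sqrt_diag = sd_, D = D)
}

#' Run the full SCA computation on an alignment
#'
#' Convenience wrapper: frequencies, background, conservation, positional
#' weights, projection, SCA matrix, spectral decomposition, and sector.
#'
#' @param aln an `aln` object (already gap-filtered if desired).
#' @param q_aa 20-amino-acid background, default [aa_background()].
#' @param gap_mode gap convention for the background, see [background_with_gap()].
#' @param clamp frequency clamp for the weights.
#' @param fraction sector-size fraction.
#' @param m number of eigenmodes to keep (default 6 or n, whichever is less).
#' @return list with `f`, `q`, `D`, `phi`, `xt`, `C`, `spec`, `sector`.
#' @export
run_sca <- function(aln, q_aa = aa_background(), gap_mode = "average_gap",
                    clamp = 0.001, fraction = 0.25,
                    m = min(6L, ncol(aln$seqs))) {
  f <- column_frequencies(aln)
  q <- background_with_gap(aln, q_aa, gap_mode)
  D <- conservation_profile(f, q)
  phi <- positional_weights(f, q, clamp)
  xt <- project_alignment(aln, f, phi)
  C <- sca_matrix(xt)
  spec <- sca_spectral(C, m = m)
  sector <- extract_sector(spec, ncol(C), fraction)
  list(f = f, q = q, D = D, phi = phi, xt = xt, C = C,
       spec = spec, sector = sector)
}
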