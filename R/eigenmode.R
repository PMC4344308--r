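#' Build the idealized SCA-like matrix
#'
#' The simplified matrix has conservation-like diagonal levels `Delta_i` and
#' uniformly scaled off-diagonal entries
#' `M_ij = x * d_i * d_j` with `d_i = sqrt(Delta_i)` for `i != j`.
#' It models an SCA matrix whose off-diagonal magnitudes carry a uniform
#' positive bias of relative size x.
#'
#' @param delta positive vector of diagonal levels, length >= 2.
#' @param x off-diagonal scale, >= 0.
#' @return symmetric matrix of dimension `length(delta)`.
#' @export
build_idealized_matrix <- function(delta, x) {
  if (length(delta) < 2L) stop("need dimension n >= 2")
  if (any(delta <= 0)) stop("all diagonal levels must be positive")
  if (x < 0) stop("x must be nonnegative")
  d <- sqrt(delta)
  M <- x * outer(d, d)
  diag(M) <- delta
  M
}

#' Closed-form approximations for the top eigenmode
#'
#' When the top eigenvalue dominates the diagonal levels, the idealized matrix
#' has `lambda_top ~ x / (1 + x) * sum(Delta_i)` and a top eigenvector
#' proportional to `sqrt(Delta_i)` (unit-normalized, nonnegative orientation).
#' The approximation degrades when `lambda_top` is comparable to the largest
#' diagonal level; `in_regime` flags whether `lambda_approx >= 10 * max(Delta)`
#' (the regime in which the eigenvector approximation is accurate).
#'
#' @param delta positive vector of diagonal levels.
#' @param x off-diagonal scale.
#' @return list with `lambda`, `vector`, `in_regime`.
#' @export
top_mode_approximations <- function(delta, x) {
  if (any(delta <= 0)) stop("all diagonal levels must be positive")
  lam <- x / (1 + x) * sum(delta)
  v <- sqrt(delta)
  v <- v / sqrt(sum(v^2))
  list(lambda = lam, vector = v, in_regime = lam >= 10 * max(delta))
}

#' Residual of the exact eigenmode self-consistency relation
#'
#' For an exact eigenpair (lambda, v) of the idealized matrix, the eigenvalue
#' equation implies, componentwise,
#' `v_i * (lambda - Delta_i (1 - x)) = x * d_i * sum_j d_j v_j`.
#' Returns the maximum absolute residual of this relation; exact eigenpairs
#' give residuals at numerical noise level, perturbed vectors do not.
#'
#' @param delta diagonal levels of the idealized matrix.
#' @param x off-diagonal scale.
#' @param lambda candidate eigenvalue.
#' @param v candidate eigenvector.
#' @return maximum absolute componentwise residual.
#' @export
eigen_relation_residual <- function(delta, x, lambda, v) {
  d <- sqrt(delta)
  s <- sum(d * v)
  max(abs(v * (lambda - delta * (1 - x)) - x * d * s))
}

#' Estimate the off-diagonal scale of an SCA matrix
#'
#' `x_hat` is the mean over pairs i < j of `C_ij / sqrt(C_ii * C_jj)`. Pairs
#' with a zero diagonal entry are excluded with a warning. For a matrix built
#' by [build_idealized_matrix()] this recovers x exactly.
#'
#' @param C symmetric nonnegative matrix with positive diagonal.
#' @return the estimate `x_hat`.
#' @export
estimate_offdiag_scale <- function(C) {
  n <- ncol(C)
  if (n < 2L) stop("need dimension n >= 2")
  dg <- diag(C)
  ok <- dg > 0
  if (!all(ok)) warning("zero diagonal entries; corresponding pairs excluded")
  if (sum(ok) < 2L) stop("fewer than 2 positive diagonal entries")
  Cs <- C[ok, ok, drop = FALSE]
  d <- sqrt(diag(Cs))
  R <- Cs / outer(d, d)
  mean(R[upper.tri(R)])
}

#' Scaling of the off-diagonal magnitude with alignment depth
#'
#' Generates synthetic alignments of increasing depth N with a named
#' generator, runs the SCA computation, estimates the off-diagonal scale
#' `x_hat` of each SCA matrix, and fits a power law `log x_hat ~ log N` by
#' least squares. Off-diagonal magnitudes arising from sampling noise decay
#' with N (negative exponent); magnitudes arising from true uniform
#' correlations (e.g. shared ancestry) stay approximately flat.
#'
#' @param generator one of `"independent"`, `"star_phylogeny"`.
#' @param N_values at least 3 alignment depths.
#' @param n number of columns for every generated alignment.
#' @param profile conservation profile passed to the generator (defaults to a
#'   heterogeneous ramp, see [heterogeneous_profile()]).
#' @param replicates replicates per depth, default 3.
#' @param seed integer seed; replicate r at depth index i uses a distinct
#'   stream derived from it.
#' @param q_aa background used in the SCA computation (default uniform, which
#'   matches the generators' symbol usage).
#' @param ... extra arguments passed to the generator (e.g. `n_ancestors`,
#'   `mutation_rate`).
#' @return list with `exponent`, `fit` (lm object), and `table`
#'   (N, replicate, x_hat).
#' @export
scaling_experiment <- function(generator = c("independent", "star_phylogeny"),
                               N_values, n = 50L,
                               profile = heterogeneous_profile(n),
                               replicates = 3L, seed = 1L,
                               q_aa = aa_background("uniform"), ...) {
  generator <- match.arg(generator)
  if (length(N_values) < 3L) stop("need at least 3 values of N")
  gen <- switch(generator,
                independent = function(N, s)
                  sample_independent_alignment(N, n, profile, seed = s),
                star_phylogeny = function(N, s)
                  sample_star_phylogeny_alignment(N, n, profile, seed = s, ...))
  rows <- list()
  for (i in seq_along(N_values)) {
    for (r in seq_len(replicates)) {
      s <- seed + 1000L * i + r
      aln <- gen(N_values[i], s)
      res <- run_sca(aln, q_aa = q_aa, m = 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        N = N_values[i], replicate = r, x_hat = estimate_offdiag_scale(res$C))
    }
  }
  tab <- do.call(rbind, rows)
  if (any(tab$x_hat <= 0)) stop("nonpositive x_hat estimate; cannot fit power law")
  fit <- stats::lm(log(x_hat) ~ log(N), data = tab)
  list(exponent = unname(stats::coef(fit)[2L]), fit = fit, table = tab)
}
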