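# Background amino-acid frequencies averaged over a large protein database,
# as conventionally used in the SCA literature. Order follows AA20.
BG_DATABASE <- c(
  A = 0.073, C = 0.025, D = 0.050, E = 0.061, F = 0.042,
  G = 0.072, H = 0.023, I = 0.053, K = 0.064, L = 0.089,
  M = 0.023, N = 0.043, P = 0.052, Q = 0.040, R = 0.052,
  S = 0.073, T = 0.056, V = 0.063, W = 0.013, Y = 0.033)
BG_DATABASE <- BG_DATABASE / sum(BG_DATABASE)

#' Background amino-acid distributions
#'
#' Returns a named 20-vector of background frequencies over the standard amino
#' acids (order A, C, D, ..., Y). `"database"` gives frequencies averaged over
#' a large protein database as conventionally used with SCA; `"uniform"` gives
#' 0.05 for each amino acid and makes numeric examples self-contained.
#'
#' @param kind `"database"` or `"uniform"`.
#' @return named numeric vector of length 20 summing to 1.
#' @export
aa_background <- function(kind = c("database", "uniform")) {
  kind <- match.arg(kind)
  if (kind == "uniform") {
    q <- rep(1 / 20, 20L)
    names(q) <- AA20
    q
  } else BG_DATABASE
}

#' Per-column symbol frequencies
#'
#' Counts every cell, gap included: `f_i(a) = count(a in column i) / N`.
#' Each column of the result sums to 1.
#'
#' @param aln an `aln` object.
#' @return a 21 x n matrix of frequencies; rows named by symbol
#'   (20 amino acids then `"-"`), columns by alignment column.
#' @export
column_frequencies <- function(aln) {
  stopifnot(inherits(aln, "aln"))
  N <- nrow(aln$seqs)
  f <- vapply(seq_len(ncol(aln$seqs)), function(j) {
    tabulate(match(aln$seqs[, j], ALPHABET21), nbins = 21L) / N
  }, numeric(21L))
  rownames(f) <- ALPHABET21
  f
}

#' Background distribution over the 21-symbol alphabet
#'
#' Extends a 20-amino-acid background to the gap symbol using one of two gap
#' conventions. In `average_gap` mode (the SCA default), the background gap
#' frequency is set to the gap frequency of the alignment averaged over all
#' columns, and the amino-acid entries are rescaled by `1 - q(gap)` so the
#' 21-vector sums to 1. In `ignore_gap` mode the background gap frequency is 0
#' (gapped cells are ignored column-wise by the caller).
#'
#' @param aln an `aln` object.
#' @param q_aa background distribution over the 20 amino acids (sums to 1).
#' @param gap_mode `"average_gap"` (default) or `"ignore_gap"`.
#' @return named numeric vector of length 21 summing to 1.
#' @export
background_with_gap <- function(aln, q_aa = aa_background(),
                                gap_mode = c("average_gap", "ignore_gap")) {
  gap_mode <- match.arg(gap_mode)
  stopifnot(inherits(aln, "aln"))
  if (length(q_aa) != 20L || abs(sum(q_aa) - 1) > 1e-8)
    stop("q_aa must be a distribution over the 20 amino acids summing to 1")
  q_aa <- as.numeric(q_aa)
  if (gap_mode == "average_gap") {
    qgap <- mean(gap_fractions(aln))
    q <- c(q_aa * (1 - qgap), qgap)
  } else {
    q <- c(q_aa, 0)
  }
  names(q) <- ALPHABET21
  q
}

#' Relative-entropy conservation profile
#'
#' The conservation of column i is the Kullback-Leibler divergence between the
#' column's symbol distribution and the background,
#' `D_i = sum_a f_i(a) * ln(f_i(a) / q(a))`, in nats, with the convention
#' `0 * ln(0/q) = 0`. When `q` has zero gap frequency (`ignore_gap` mode) the
#' column distributions are renormalized over the non-gap symbols first.
#'
#' @param f 21 x n frequency matrix from [column_frequencies()].
#' @param q background 21-vector from [background_with_gap()].
#' @return numeric vector of per-column conservation values (nats), all >= 0.
#' @export
conservation_profile <- function(f, q) {
  if (nrow(f) != 21L || length(q) != 21L)
    stop("f must be 21 x n and q a 21-vector")
  if (any(abs(colSums(f) - 1) > 1e-9)) stop("columns of f must each sum to 1")
  if (abs(sum(q) - 1) > 1e-9) stop("q must sum to 1")
  if (q[21L] == 0 && any(f[21L, ] > 0)) {
    # ignore-gap convention: restrict each column to non-gap symbols
    f <- f[1:20, , drop = FALSE]
    cs <- colSums(f)
    if (any(cs == 0)) stop("column with only gaps cannot be scored in ignore_gap mode")
    f <- sweep(f, 2L, cs, "/")
    f <- rbind(f, 0)
  }
  bad <- which(f > 0 & q == 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("column %d has positive frequency for symbol '%s' with zero background",
                 bad[1L, 2L], ALPHABET21[bad[1L, 1L]]))
  D <- vapply(seq_len(ncol(f)), function(j) {
    fi <- f[, j]
    pos <- fi > 0
    sum(fi[pos] * log(fi[pos] / q[pos]))
  }, numeric(1L))
  pmax(D, 0)
}

#' Most-prevalent-amino-acid conservation
#'
#' A simpler conservation comparator: the frequency of the most prevalent
#' amino acid (gap excluded) in each column. Highly correlated with the
#' relative-entropy profile in practice.
#'
#' @param f 21 x n frequency matrix.
#' @return numeric vector of per-column maxima over the 20 amino-acid rows.
#' @export
consensus_frequency <- function(f) {
  apply(f[1:20, , drop = FALSE], 2L, max)
}

#' Top conserved columns
#'
#' The k columns with the largest conservation values; ties broken by lower
#' column index. Output is ordered by decreasing conservation then increasing
#' index.
#'
#' @param D conservation vector.
#' @param k number of columns, 1 <= k <= length(D).
#' @return integer vector of k column indices.
#' @export
top_conserved_set <- function(D, k) {
  n <- length(D)
  if (k < 1L || k > n) stop(sprintf("k must lie in [1, %d]", n))
  ord <- order(-D, seq_len(n))
  ord[seq_len(k)]
}

#' Write a conservation profile as delimited text
#'
#' @param D conservation vector.
#' @param path output path (tab-separated, with header).
#' @param residue_numbers optional 1-based reference residue numbers per column.
#' @return `path`, invisibly.
#' @export
write_conservation <- function(D, path, residue_numbers = NULL) {
  df <- data.frame(column = seq_along(D),
                   residue = if (is.null(residue_numbers)) NA_integer_ else residue_numbers,
                   D = D)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
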