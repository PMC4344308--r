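# Shared fixtures and independent oracles for the test suite.

AA20_t <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# build an aln object from a character vector of row strings
aln_from_strings <- function(strings, ids = paste0("s", seq_along(strings)),
                             ...) {
  seqs <- do.call(rbind, strsplit(strings, "", fixed = TRUE))
  new_alignment(seqs, ids, ...)
}

write_temp_fasta <- function(strings, ids = paste0("s", seq_along(strings))) {
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), strings)), path)
  path
}

# --- independent SCA oracle: first-principles double loops -------------------

# population covariance with elementwise absolute value, by explicit loops
bf_abs_cov <- function(xt) {
  N <- nrow(xt); n <- ncol(xt)
  C <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s1 <- 0
    for (k in seq_len(N)) s1 <- s1 + xt[k, i] * xt[k, j]
    C[i, j] <- abs(s1 / N - sum(xt[, i]) * sum(xt[, j]) / N^2)
  }
  C
}

# full SCA matrix recomputed from scratch (scalar loops, no package code)
bf_sca_from_alignment <- function(aln, q21, clamp = 0.001) {
  seqs <- aln$seqs
  N <- nrow(seqs); n <- ncol(seqs)
  xt <- matrix(0, N, n)
  for (i in seq_len(n)) {
    f <- numeric(20)
    for (a in 1:20) f[a] <- sum(seqs[, i] == AA20_t[a]) / N
    phi <- numeric(20); w <- numeric(20)
    for (a in 1:20) {
      fc <- min(max(f[a], clamp), 1 - clamp)
      phi[a] <- log(fc * (1 - q21[a]) / ((1 - fc) * q21[a]))
      w[a] <- phi[a] * f[a]
    }
    nrm <- sqrt(sum(w^2))
    for (k in seq_len(N)) {
      a <- match(seqs[k, i], AA20_t)
      if (!is.na(a) && nrm > 0) xt[k, i] <- w[a] / nrm
    }
  }
  bf_abs_cov(xt)
}

# characteristic polynomial coefficients by the Faddeev-LeVerrier recursion:
# an eigen()-independent route to the spectrum of small matrices
charpoly_roots <- function(M) {
  n <- nrow(M)
  coefs <- numeric(n + 1); coefs[1] <- 1
  Mk <- diag(n)
  for (k in 1:n) {
    Mk <- M %*% Mk
    ck <- -sum(diag(Mk)) / k
    coefs[k + 1] <- ck
    Mk <- Mk + ck * diag(n)
  }
  r <- polyroot(rev(coefs))
  sort(Re(r), decreasing = TRUE)
}

# --- statistical oracles -----------------------------------------------------

# one-tailed Fisher enrichment p by direct hypergeometric summation
bf_fisher_tail <- function(tab) {
  a <- tab[1, 1]; K <- sum(tab[, 1]); m <- sum(tab[1, ]); N <- sum(tab)
  ks <- max(0, m - (N - K)):min(K, m)
  probs <- choose(K, ks) * choose(N - K, m - ks) / choose(N, m)
  sum(probs[ks >= a])
}

# exact two-sided Mann-Whitney p for tie-free samples via the null U pmf
bf_mw_exact <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  u <- sum(rank(c(a, b))[seq_len(n1)]) - n1 * (n1 + 1) / 2
  pmf <- stats::dwilcox(0:(n1 * n2), n1, n2)
  p_low <- sum(pmf[0:(n1 * n2) <= u])
  p_high <- sum(pmf[0:(n1 * n2) >= u])
  min(1, 2 * min(p_low, p_high))
}

# --- synthetic PDB fixture ---------------------------------------------------

pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          o = 1, alt = "") {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, alt, resn, chain, resno, "", x, y, z, o, 0,
          substr(trimws(name), 1, 1))
}

# a linear chain of residues along the x axis, one backbone per residue;
# `extra` is a data.frame(name, resno, x, y, z) of additional atoms
write_temp_pdb <- function(n_res = 3, spacing = 4, extra = NULL,
                           header = NULL, footer = "END") {
  lines <- character(0)
  serial <- 0L
  for (r in seq_len(n_res)) {
    x0 <- (r - 1) * spacing
    for (at in list(c("N", 0), c("CA", 1), c("C", 2), c("O", 2.5))) {
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line(serial, at[1], "ALA", "A", r,
                                      x0 + as.numeric(at[2]), 0, 0))
    }
  }
  if (!is.null(extra)) {
    for (i in seq_len(nrow(extra))) {
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line(serial, extra$name[i], "GLY", "A",
                                      extra$resno[i], extra$x[i], extra$y[i],
                                      extra$z[i]))
    }
  }
  path <- tempfile(fileext = ".pdb")
  writeLines(c(header, lines, footer), path)
  path
}
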