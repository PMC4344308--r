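#' Heterogeneous conservation profile
#'
#' A deterministic ramp of dominant-residue frequencies, evenly spaced between
#' `min` and `max`. The default spans background-level (unconserved) columns
#' up to strongly conserved ones while staying in the regime where the
#' projection method's per-column variance — roughly p(1 - p) in the dominant
#' frequency p — still grows with conservation, which is the single-sector
#' regime this package studies.
#'
#' @param n number of columns.
#' @param min,max dominant-residue frequency range, default 0.05 to 0.55.
#' @return numeric vector of length n.
#' @export
heterogeneous_profile <- function(n, min = 0.05, max = 0.55) {
  seq(min, max, length.out = n)
}

# draw one column of symbols: dominant residue `dom` (index into AA20) gets
# mass p, the other 19 amino acids share 1 - p uniformly; no gaps
.draw_column <- function(N, p, dom) {
  probs <- rep((1 - p) / 19, 20L)
  probs[dom] <- p
  AA20[sample.int(20L, N, replace = TRUE, prob = probs)]
}

#' Sample an alignment with independent columns
#'
#' Every column i is drawn i.i.d. across sequences from a categorical
#' distribution placing mass `profile[i]` on a column-specific dominant
#' residue and spreading the remainder uniformly over the other 19 amino
#' acids. No gaps are generated. Deterministic given the seed.
#'
#' @param N number of sequences.
#' @param n number of columns.
#' @param profile dominant-residue frequencies, values in (0, 1].
#' @param seed integer seed (mandatory).
#' @return an `aln` object with ids `seq1..seqN`.
#' @export
sample_independent_alignment <- function(N, n, profile, seed) {
  if (length(profile) == 1L) profile <- rep(profile, n)
  if (length(profile) != n) stop("profile must have one value per column")
  if (any(profile <= 0 | profile > 1)) stop("profile values must lie in (0, 1]")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  doms <- sample.int(20L, n, replace = TRUE)
  seqs <- vapply(seq_len(n), function(j) .draw_column(N, profile[j], doms[j]),
                 character(N))
  if (N == 1L) seqs <- matrix(seqs, nrow = 1L)
  new_alignment(seqs, paste0("seq", seq_len(N)))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Sample an alignment with a planted co-varying column group
#'
#' Each sequence carries a hidden binary state (+1 or -1, probability 1/2).
#' In every sector cell a latent bit equals the state with probability
#' `(1 + coupling) / 2` (a fair coin when `coupling = 0`), and the bit tilts
#' the probability of emitting the column's dominant residue:
#' `P(dominant) = p +/- delta0` with tilt `delta0 = min(p, 1 - p) / 2` (half
#' the admissible headroom) and `p = profile[i]`. Non-sector columns emit the
#' dominant residue with probability p as in
#' [sample_independent_alignment()]; the remainder is uniform over the other
#' 19 amino acids throughout.
#'
#' Because the tilted bit is marginally a fair coin, every sector column has
#' exactly the same marginal distribution as a non-sector column with the
#' same profile value: conservation cannot distinguish planted from unplanted
#' positions, while inter-column correlation (of the dominant-residue
#' indicator, the quantity the projection method sees) appears only within
#' the sector, with pairwise strength `coupling^2 * delta0^2 / (p (1 - p))`.
#' `coupling = 0` reduces the distribution to fully independent columns.
#'
#' @param N number of sequences.
#' @param n number of columns.
#' @param profile dominant-residue frequencies, values in (0, 1).
#' @param sector_positions column indices of the planted sector.
#' @param coupling latent-state coupling in \[0, 1\].
#' @param seed integer seed (mandatory).
#' @return an `aln` object; the planted positions and hidden states are
#'   attached as attributes `sector_positions` and `states`.
#' @export
sample_sector_alignment <- function(N, n, profile, sector_positions,
                                    coupling, seed) {
  if (length(profile) == 1L) profile <- rep(profile, n)
  if (length(profile) != n) stop("profile must have one value per column")
  if (any(profile <= 0 | profile >= 1))
    stop("profile values must lie in (0, 1) for the tilted sector model")
  sector_positions <- unique(as.integer(sector_positions))
  if (any(sector_positions < 1L | sector_positions > n))
    stop("sector_positions out of range")
  if (coupling < 0 || coupling > 1) stop("coupling must lie in [0, 1]")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  doms <- sample.int(20L, n, replace = TRUE)
  states <- sample(c(-1L, 1L), N, replace = TRUE)   # hidden binary state
  in_sector <- seq_len(n) %in% sector_positions
  p_match <- (1 + coupling) / 2
  seqs <- matrix("", nrow = N, ncol = n)
  for (j in seq_len(n)) {
    p <- profile[j]
    if (in_sector[j]) {
      bits <- ifelse(stats::runif(N) < p_match, states, -states)
      pdom <- p + (min(p, 1 - p) / 2) * bits
    } else {
      pdom <- rep(p, N)
    }
    hit <- stats::runif(N) < pdom
    other <- sample.int(19L, N, replace = TRUE)
    col <- integer(N)
    col[hit] <- doms[j]
    # map 1..19 onto the 20 amino acids skipping the dominant one
    oth <- other[!hit]
    col[!hit] <- oth + (oth >= doms[j])
    seqs[, j] <- AA20[col]
  }
  aln <- new_alignment(seqs, paste0("seq", seq_len(N)))
  attr(aln, "sector_positions") <- sector_positions
  attr(aln, "states") <- states
  aln
}

#' Sample an alignment with uniform global correlations (star phylogeny)
#'
#' Draws `n_ancestors` ancestor sequences from the independent-column model,
#' then builds each output sequence by copying a uniformly chosen ancestor and
#' redrawing each position independently (from the column's own distribution)
#' with probability `mutation_rate`. Shared ancestry induces weak positive
#' correlations between all column pairs; `mutation_rate = 1` reduces to the
#' independent model.
#'
#' @param N number of sequences.
#' @param n number of columns.
#' @param profile dominant-residue frequencies, values in (0, 1].
#' @param n_ancestors number of ancestor sequences, >= 1; default 5.
#' @param mutation_rate per-position redraw probability in (0, 1]; default
#'   0.25, i.e. sequences stay about 75% identical to their ancestor, so that
#'   shared ancestry rather than sampling noise dominates the off-diagonal
#'   correlation magnitudes.
#' @param seed integer seed (mandatory).
#' @return an `aln` object.
#' @export
sample_star_phylogeny_alignment <- function(N, n, profile, seed,
                                            n_ancestors = 5L,
                                            mutation_rate = 0.25) {
  if (length(profile) == 1L) profile <- rep(profile, n)
  if (n_ancestors < 1L) stop("n_ancestors must be >= 1")
  if (mutation_rate <= 0 || mutation_rate > 1)
    stop("mutation_rate must lie in (0, 1]")
  if (any(profile <= 0 | profile > 1)) stop("profile values must lie in (0, 1]")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  doms <- sample.int(20L, n, replace = TRUE)
  anc <- vapply(seq_len(n), function(j)
    .draw_column(n_ancestors, profile[j], doms[j]), character(n_ancestors))
  if (n_ancestors == 1L) anc <- matrix(anc, nrow = 1L)
  pick <- sample.int(n_ancestors, N, replace = TRUE)
  seqs <- anc[pick, , drop = FALSE]
  for (j in seq_len(n)) {
    redraw <- stats::runif(N) < mutation_rate
    if (any(redraw))
      seqs[redraw, j] <- .draw_column(sum(redraw), profile[j], doms[j])
  }
  new_alignment(seqs, paste0("seq", seq_len(N)))
}

#' Sample conservation-linked mutational effects
#'
#' Generates per-position effects `effect_i = link(D_i) + noise`, with
#' Gaussian noise of standard deviation `noise_sd`, emulating mutagenesis
#' datasets in which the magnitude of mutational effects is statistically tied
#' to conservation. The link must be monotone non-decreasing (checked
#' numerically on the observed conservation range). Functional flags are
#' assigned with [call_functional_sites()] at the given effect threshold.
#'
#' @param D conservation vector (one value per position).
#' @param link monotone non-decreasing function, default identity.
#' @param noise_sd Gaussian noise standard deviation.
#' @param functional_threshold effect threshold for the functional call.
#' @param seed integer seed (mandatory).
#' @param positions 1-based position labels, default `seq_along(D)`.
#' @return a `mutational_data` data.frame with a `functional` column.
#' @export
sample_mutational_effects <- function(D, link = identity, noise_sd,
                                      functional_threshold, seed,
                                      positions = seq_along(D)) {
  grid <- sort(unique(D))
  if (length(grid) > 1L && any(diff(link(grid)) < 0))
    stop("link must be monotone non-decreasing over the conservation range")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  eff <- link(D) + stats::rnorm(length(D), 0, noise_sd)
  data <- mutational_dataset(positions, eff)
  call_functional_sites(data, "effect_threshold", functional_threshold)
}
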