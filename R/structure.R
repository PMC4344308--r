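#' Read a protein structure from a PDB file
#'
#' Parses a PDB file (first model only for multi-model files), keeps heavy
#' atoms (hydrogens and deuteriums dropped), and resolves alternate locations
#' by keeping, for each (chain, residue, atom name), the record with the
#' highest occupancy (first on ties).
#'
#' @param path path to a PDB file.
#' @param chain optional chain identifier to restrict to; an error if absent.
#' @return object of class `structure_model`: a list with `atoms` (data.frame
#'   with chain, resno, resid, elety, x, y, z) and `residues` (data.frame of
#'   unique chain/resno/resid).
#' @export
read_structure <- function(path, chain = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop(sprintf("no ATOM records parsed from %s", path))
  if (!is.null(chain)) {
    at <- at[at$chain %in% chain, , drop = FALSE]
    if (nrow(at) == 0L) stop(sprintf("chain '%s' not found in %s", chain, path))
  }
  # drop hydrogens by element symbol, falling back to the atom-name convention
  elt <- at$elesy
  if (is.null(elt) || all(is.na(elt) | elt == "")) {
    elt <- sub("^[0-9]*", "", trimws(at$elety))
    elt <- substr(elt, 1L, 1L)
  }
  at <- at[!(trimws(elt) %in% c("H", "D")), , drop = FALSE]
  # resolve altLoc: keep highest occupancy per (chain, resno, atom name)
  key <- paste(at$chain, at$resno, at$elety, sep = "|")
  o <- if (is.null(at$o)) rep(1, nrow(at)) else ifelse(is.na(at$o), 1, at$o)
  ord <- order(key, -o)
  at <- at[ord[!duplicated(key[ord])], , drop = FALSE]
  at <- at[order(at$chain, at$resno), , drop = FALSE]
  atoms <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                      elety = trimws(at$elety),
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  residues <- unique(atoms[, c("chain", "resno", "resid")])
  structure(list(atoms = atoms, residues = residues), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("Structure: %d residues, %d heavy atoms (chains: %s)\n",
              nrow(x$residues), nrow(x$atoms),
              paste(unique(x$atoms$chain), collapse = ", ")))
  invisible(x)
}

.atom_coords <- function(s, chain, resno, names = NULL) {
  a <- s$atoms[s$atoms$chain == chain & s$atoms$resno == resno, , drop = FALSE]
  if (!is.null(names)) a <- a[a$elety %in% names, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

#' Residues touching an insertion site
#'
#' Emulates the fixed-sphere criterion for domain-insertion experiments:
#' spheres of radius `cutoff` are centered on the four atoms of the peptide
#' bond preceding the insertion residue (C and O of residue i-1, N and CA of
#' residue i), and a residue "touches" the site iff at least one of its atoms
#' lies within (<=) `cutoff` of any sphere center.
#'
#' @param s a `structure_model`.
#' @param insertion_residue residue number i; residue i-1 must exist in the
#'   chain (insertion before the chain's first residue is an error).
#' @param chain chain identifier; default the first chain in the structure.
#' @param cutoff sphere radius in Angstrom, default 4.
#' @param center_atoms atom names used as sphere centers, as a list with
#'   entries `prev` and `ins`; defaults to C, O / N, CA.
#' @return sorted integer vector of touching residue numbers.
#' @export
touching_residues <- function(s, insertion_residue, chain = s$atoms$chain[1L],
                              cutoff = 4.0,
                              center_atoms = list(prev = c("C", "O"),
                                                  ins = c("N", "CA"))) {
  resnos <- sort(unique(s$atoms$resno[s$atoms$chain == chain]))
  if (!(insertion_residue %in% resnos))
    stop(sprintf("residue %d not in chain %s", insertion_residue, chain))
  prevs <- resnos[resnos < insertion_residue]
  if (length(prevs) == 0L)
    stop("insertion at the chain's first residue: no preceding peptide bond")
  prev <- max(prevs)
  centers <- rbind(.atom_coords(s, chain, prev, center_atoms$prev),
                   .atom_coords(s, chain, insertion_residue, center_atoms$ins))
  if (nrow(centers) == 0L) stop("no peptide-bond atoms found at the insertion site")
  ca <- s$atoms[s$atoms$chain == chain, , drop = FALSE]
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  mind <- rep(Inf, nrow(xyz))
  for (i in seq_len(nrow(centers))) {
    d <- sqrt(rowSums(sweep(xyz, 2L, centers[i, ])^2))
    mind <- pmin(mind, d)
  }
  sort(unique(ca$resno[mind <= cutoff]))
}

#' Count insertion sites touched by a sector
#'
#' A site is touched iff the sector shares at least one residue with the
#' site's touching set.
#'
#' @param sector_residues residue numbers in the sector.
#' @param insertion_sites residue numbers of the insertion sites.
#' @param s a `structure_model`.
#' @param chain chain identifier.
#' @param cutoff sphere radius in Angstrom.
#' @return list with `count` and `touched` (named logical per site).
#' @export
sector_touch_counts <- function(sector_residues, insertion_sites, s,
                                chain = s$atoms$chain[1L], cutoff = 4.0) {
  touched <- vapply(insertion_sites, function(site) {
    length(intersect(sector_residues,
                     touching_residues(s, site, chain, cutoff))) > 0L
  }, logical(1L))
  names(touched) <- insertion_sites
  list(count = sum(touched), touched = touched)
}

#' Conservation versus distance from the structure's center
#'
#' Computes the geometric center of all heavy atoms (unit atom masses), each
#' residue's centroid distance from it, and the Spearman correlation between
#' that distance and the residue's conservation. Residues without a mapped
#' conservation value are skipped with a warning.
#'
#' @param s a `structure_model`.
#' @param D conservation vector indexed by alignment column.
#' @param residue_of_column integer vector mapping alignment columns to
#'   residue numbers (NA for unmapped columns), e.g. from
#'   [map_columns_to_reference()].
#' @param chain chain identifier.
#' @param use one of `"centroid"` (all heavy atoms) or `"CA"`.
#' @return list with `table` (resno, distance, D) and `spearman`.
#' @export
conservation_vs_center_distance <- function(s, D, residue_of_column,
                                            chain = s$atoms$chain[1L],
                                            use = c("centroid", "CA")) {
  use <- match.arg(use)
  at <- s$atoms[s$atoms$chain == chain, , drop = FALSE]
  center <- colMeans(as.matrix(at[, c("x", "y", "z")]))
  Dres <- D[!is.na(residue_of_column)]
  resn <- residue_of_column[!is.na(residue_of_column)]
  have <- resn %in% at$resno
  if (!all(have)) warning(sprintf("%d mapped residue(s) missing from structure; skipped",
                                  sum(!have)))
  resn <- resn[have]; Dres <- Dres[have]
  dist <- vapply(resn, function(r) {
    a <- at[at$resno == r, , drop = FALSE]
    if (use == "CA") {
      ca <- a[a$elety == "CA", , drop = FALSE]
      if (nrow(ca) > 0L) a <- ca
    }
    centroid <- colMeans(as.matrix(a[, c("x", "y", "z")]))
    sqrt(sum((centroid - center)^2))
  }, numeric(1L))
  tab <- data.frame(resno = resn, distance = dist, D = Dres)
  rho <- if (nrow(tab) >= 3L)
    stats::cor(tab$distance, tab$D, method = "spearman") else NA_real_
  list(table = tab, spearman = rho)
}
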