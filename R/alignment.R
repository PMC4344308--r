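# 20 standard amino acids in the package's canonical order, plus the gap symbol.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
GAP <- "-"
ALPHABET21 <- c(AA20, GAP)

#' Construct a multiple sequence alignment object
#'
#' An `aln` object stores an N x n character matrix of aligned sequences over
#' the 21-symbol alphabet (20 standard amino acids plus the gap `"-"`),
#' together with sequence identifiers, an optional reference sequence id, and
#' (for filtered alignments) the original index of each retained column.
#'
#' @param seqs character matrix (N x n), each cell a single symbol.
#' @param ids character vector of N sequence identifiers.
#' @param reference_id optional identifier of the reference (seed) sequence.
#' @param column_origin optional strictly increasing integer vector giving, for
#'   each column, its (1-based) index in the unfiltered alignment.
#' @return An object of class `aln` with elements `seqs`, `ids`,
#'   `reference_id`, `column_origin`.
#' @export
new_alignment <- function(seqs, ids, reference_id = NULL, column_origin = NULL) {
  if (!is.matrix(seqs) || !is.character(seqs))
    stop("`seqs` must be a character matrix")
  if (nrow(seqs) < 1L || ncol(seqs) < 1L)
    stop("alignment must have at least one sequence and one column")
  if (length(ids) != nrow(seqs))
    stop("length(ids) must equal the number of sequences")
  bad <- !(seqs %in% ALPHABET21)
  dim(bad) <- dim(seqs)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid symbol '%s' at sequence %d, column %d",
                 seqs[bad][1L], idx[1L], idx[2L]))
  }
  if (is.null(column_origin)) {
    column_origin <- seq_len(ncol(seqs))
  } else {
    column_origin <- as.integer(column_origin)
    if (length(column_origin) != ncol(seqs) || any(diff(column_origin) <= 0L))
      stop("column_origin must be strictly increasing with one entry per column")
  }
  if (!is.null(reference_id) && !reference_id %in% ids)
    stop(sprintf("reference_id '%s' not found among sequence ids", reference_id))
  structure(list(seqs = seqs, ids = as.character(ids),
                 reference_id = reference_id,
                 column_origin = column_origin),
            class = "aln")
}

#' @export
print.aln <- function(x, ...) {
  cat(sprintf("Multiple sequence alignment: %d sequences x %d columns\n",
              nrow(x$seqs), ncol(x$seqs)))
  if (!is.null(x$reference_id))
    cat("  reference:", x$reference_id, "\n")
  invisible(x)
}

#' @export
dim.aln <- function(x) dim(x$seqs)

#' Normalize raw alignment strings to the 21-symbol alphabet
#'
#' Uppercases letters, maps both `'.'` and `'-'` to the gap symbol, and maps
#' non-standard amino-acid letters (B, J, O, U, X, Z and anything else outside
#' the standard 20) to the gap symbol. The frequency model has no slot for
#' ambiguity codes, so mapping them to gap keeps real alignments usable.
#'
#' @param strings character vector of aligned sequence strings.
#' @return character vector of normalized strings.
#' @export
normalize_sequences <- function(strings) {
  strings <- toupper(strings)
  vapply(strings, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    ch[!(ch %in% AA20)] <- GAP
    paste(ch, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Read an aligned FASTA file
#'
#' Reads a multi-record FASTA file of aligned protein sequences, normalizes the
#' symbols (see [normalize_sequences()]), and returns an [new_alignment()]
#' object with rows in file order.
#'
#' @param path path to a FASTA file with at least one record.
#' @param reference_id optional id of the reference sequence; defaults to none.
#' @return an `aln` object.
#' @export
read_fasta_alignment <- function(path, reference_id = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(sprintf("empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(set))
  strings <- as.character(set)
  lens <- nchar(strings)
  if (length(unique(lens)) != 1L) {
    off <- which(lens != lens[1L])[1L]
    stop(sprintf("ragged alignment: record '%s' has length %d, expected %d",
                 ids[off], lens[off], lens[1L]))
  }
  strings <- normalize_sequences(strings)
  seqs <- do.call(rbind, strsplit(strings, "", fixed = TRUE))
  new_alignment(seqs, ids, reference_id = reference_id)
}

#' Write an alignment to FASTA
#'
#' Gap cells are written as `'-'`.
#'
#' @param aln an `aln` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "aln"))
  strings <- apply(aln$seqs, 1L, paste, collapse = "")
  set <- Biostrings::BStringSet(strings)
  names(set) <- aln$ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Per-column gap fractions
#'
#' @param aln an `aln` object.
#' @return numeric vector of length n with the fraction of gap cells per column.
#' @export
gap_fractions <- function(aln) {
  stopifnot(inherits(aln, "aln"))
  colMeans(aln$seqs == GAP)
}

#' Remove high-gap (insert-state) columns
#'
#' Columns whose gap fraction is `max_gap_fraction` or more are treated as
#' insert states and removed; columns strictly below the threshold are kept.
#' The default of 0.4 removes columns with 40% or more gaps.
#'
#' @param aln an `aln` object.
#' @param max_gap_fraction gap-fraction threshold in \[0, 1\]; default 0.4.
#' @return a filtered `aln` with `column_origin` recording retained columns
#'   (composed with any prior filtering).
#' @export
filter_gap_columns <- function(aln, max_gap_fraction = 0.4) {
  stopifnot(inherits(aln, "aln"))
  if (max_gap_fraction < 0 || max_gap_fraction > 1)
    stop("max_gap_fraction must lie in [0, 1]")
  keep <- gap_fractions(aln) < max_gap_fraction
  if (!any(keep))
    stop("all columns removed by gap filtering; nothing left to analyze")
  new_alignment(aln$seqs[, keep, drop = FALSE], aln$ids,
                reference_id = aln$reference_id,
                column_origin = aln$column_origin[keep])
}

#' Map alignment columns to reference residue numbers
#'
#' Column j maps to the count of non-gap reference symbols in columns 1..j when
#' the reference is non-gap at j, and to `NA` otherwise. Residue numbers are
#' 1-based, matching mutagenesis tables.
#'
#' @param aln an `aln` object.
#' @param ref_id identifier of the reference sequence (defaults to
#'   `aln$reference_id`).
#' @return integer vector of length n: reference residue number or `NA`.
#' @export
map_columns_to_reference <- function(aln, ref_id = aln$reference_id) {
  stopifnot(inherits(aln, "aln"))
  if (is.null(ref_id)) stop("no reference id given and none stored in alignment")
  k <- match(ref_id, aln$ids)
  if (is.na(k)) stop(sprintf("reference id '%s' not found in alignment", ref_id))
  row <- aln$seqs[k, ]
  nongap <- row != GAP
  out <- cumsum(nongap)
  out[!nongap] <- NA_integer_
  as.integer(out)
}
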