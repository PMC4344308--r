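#' Build a per-position mutational dataset
#'
#' @param position 1-based reference residue numbers (unique).
#' @param effect per-position scalar effect (mean mutational effect, free
#'   energy difference in kcal/mol, or a loss-of-function substitution count).
#' @param n_deleterious,n_tested optional substitution counts for
#'   count-threshold calling.
#' @return data.frame of class `mutational_data`.
#' @export
mutational_dataset <- function(position, effect,
                               n_deleterious = NULL, n_tested = NULL) {
  if (anyDuplicated(position)) stop("positions must be unique")
  if (length(effect) != length(position))
    stop("effect must have one value per position")
  df <- data.frame(position = as.integer(position), effect = as.numeric(effect))
  if (!is.null(n_deleterious)) df$n_deleterious <- as.integer(n_deleterious)
  if (!is.null(n_tested)) df$n_tested <- as.integer(n_tested)
  class(df) <- c("mutational_data", "data.frame")
  df
}

#' Read a mutational dataset from delimited text
#'
#' Expects a header with columns `position`, `effect` and optionally
#' `n_deleterious`, `n_tested`.
#'
#' @param path path to a tab- or comma-separated file.
#' @param sep field separator, default tab.
#' @return a `mutational_data` data.frame.
#' @export
read_mutational_data <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("position", "effect") %in% names(df)))
    stop("mutational data must have 'position' and 'effect' columns")
  mutational_dataset(df$position, df$effect,
                     n_deleterious = df[["n_deleterious"]],
                     n_tested = df[["n_tested"]])
}

#' Flag functionally significant positions
#'
#' Two calling rules are supported. `effect_threshold`: a position is
#' functional iff `|effect| >= threshold` (e.g. a 1 kcal/mol free-energy
#' criterion). `count_threshold`: functional iff `n_deleterious >= threshold`
#' (e.g. at least 8 loss-of-function substitutions).
#'
#' @param data a `mutational_data` data.frame.
#' @param rule `"effect_threshold"` or `"count_threshold"`.
#' @param threshold numeric threshold for the chosen rule.
#' @return the dataset with a logical `functional` column and attributes
#'   `rule`/`threshold` recording the call.
#' @export
call_functional_sites <- function(data,
                                  rule = c("effect_threshold", "count_threshold"),
                                  threshold) {
  rule <- match.arg(rule)
  if (rule == "effect_threshold") {
    data$functional <- abs(data$effect) >= threshold
  } else {
    if (is.null(data$n_deleterious))
      stop("count_threshold rule requires an 'n_deleterious' column")
    data$functional <- data$n_deleterious >= threshold
  }
  attr(data, "rule") <- rule
  attr(data, "threshold") <- threshold
  data
}

#' Membership-by-function contingency table
#'
#' Cross-tabulates set membership against the functional flag over the
#' universe of scored positions. Rows: in-set / not-in-set; columns:
#' functional / not-functional.
#'
#' @param setA integer vector of positions (must be scored).
#' @param data a `mutational_data` with a `functional` column.
#' @param universe positions to tabulate over; default all scored positions.
#' @return 2 x 2 integer matrix with informative dimnames.
#' @export
contingency <- function(setA, data, universe = data$position) {
  if (is.null(data$functional))
    stop("call_functional_sites() must be applied before building tables")
  if (!all(universe %in% data$position))
    stop("universe contains unscored positions")
  if (!all(setA %in% universe))
    stop("setA contains positions outside the scored universe")
  fun <- data$functional[match(universe, data$position)]
  inA <- universe %in% setA
  tab <- matrix(c(sum(inA & fun), sum(inA & !fun),
                  sum(!inA & fun), sum(!inA & !fun)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(set = c("in_set", "not_in_set"),
                                functional = c("yes", "no")))
  tab
}

#' One-tailed Fisher exact test for enrichment
#'
#' Exact hypergeometric upper-tail probability `P(X >= a)` where `a` is the
#' in-set functional count, testing enrichment of functional positions in the
#' set. Degenerate margins (a zero row or column total) give p = 1 with a
#' warning.
#'
#' @param table 2 x 2 contingency matrix from [contingency()].
#' @return the one-tailed p-value.
#' @export
fisher_one_tailed <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L), all(table >= 0))
  a <- table[1L, 1L]
  K <- sum(table[, 1L])       # functional positions
  m <- sum(table[1L, ])       # set size
  N <- sum(table)
  if (K == 0L || K == N || m == 0L || m == N) {
    warning("degenerate margin; Fisher p-value set to 1")
    return(1)
  }
  # upper tail of Hypergeometric(N, K, m) at a, summed exactly
  stats::phyper(a - 1L, K, N - K, m, lower.tail = FALSE)
}

#' Chi-squared comparison of two contingency tables
#'
#' Tests homogeneity of the in-set (functional, not-functional) rows of two
#' tables with a Pearson chi-squared test on the 2 x 2 layout
#' rows = table, columns = functional status (1 degree of freedom). The
#' out-of-set rows are nearly shared between the tables and would be double
#' counted, so only the in-set rows enter. No continuity correction by
#' default.
#'
#' @param tableA,tableB 2 x 2 contingency matrices.
#' @param yates apply Yates continuity correction, default FALSE.
#' @return list with `statistic`, `p.value` (NA with warning if an expected
#'   cell is zero).
#' @export
chi2_compare_tables <- function(tableA, tableB, yates = FALSE) {
  m <- rbind(A = tableA[1L, ], B = tableB[1L, ])
  rs <- rowSums(m); cs <- colSums(m)
  expected <- outer(rs, cs) / sum(m)
  if (any(expected == 0)) {
    warning("zero expected cell; chi-squared comparison undefined")
    return(list(statistic = NA_real_, p.value = NA_real_))
  }
  if (identical(unname(m[1L, ]), unname(m[2L, ]))) {
    stat <- if (yates) {
      sum((pmax(0, abs(m - expected) - 0.5))^2 / expected)
    } else 0
    return(list(statistic = stat, p.value = stats::pchisq(stat, 1L, lower.tail = FALSE)))
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = yates))
  list(statistic = unname(ct$statistic), p.value = ct$p.value)
}

# Mann-Whitney U statistic for sample a vs b (number of (a, b) pairs with
# a > b, counting ties as 1/2)
.mw_u <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Two-sided Mann-Whitney U test on per-position effects
#'
#' Compares the distribution of effect values between two position sets.
#' Exact enumeration of all assignments when both sets have at most
#' `exact_max` members (ties handled by mid-ranks within the enumeration);
#' otherwise the normal approximation with tie correction. Overlapping sets
#' are used as given.
#'
#' @param data a `mutational_data` data.frame.
#' @param setA,setB nonempty position vectors; effects must exist for all.
#' @param exact_max per-side size bound for the exact mode, default 8.
#' @return list with `U`, `p.value`, `method`.
#' @export
mannwhitney_effects <- function(data, setA, setB, exact_max = 8L) {
  if (length(setA) == 0L || length(setB) == 0L) stop("sets must be nonempty")
  ia <- match(setA, data$position); ib <- match(setB, data$position)
  if (anyNA(ia) || anyNA(ib)) stop("set contains positions without effect values")
  a <- data$effect[ia]; b <- data$effect[ib]
  mannwhitney_values(a, b, exact_max = exact_max)
}

#' Two-sided Mann-Whitney U test on raw samples
#'
#' Workhorse behind [mannwhitney_effects()]; exposed for direct use.
#'
#' @param a,b numeric samples.
#' @param exact_max per-side size bound for exact enumeration.
#' @return list with `U`, `p.value`, `method`.
#' @export
mannwhitney_values <- function(a, b, exact_max = 8L) {
  n1 <- length(a); n2 <- length(b)
  u <- .mw_u(a, b)
  if (n1 <= exact_max && n2 <= exact_max) {
    pool <- c(a, b)
    combs <- utils::combn(n1 + n2, n1)
    us <- apply(combs, 2L, function(idx) .mw_u(pool[idx], pool[-idx]))
    eps <- 1e-9
    p_low <- mean(us <= u + eps)
    p_high <- mean(us >= u - eps)
    p <- min(1, 2 * min(p_low, p_high))
    return(list(U = u, p.value = p, method = "exact"))
  }
  n <- n1 + n2
  ties <- table(c(a, b))
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(U = u, p.value = 1, method = "normal"))
  z <- (u - mu) / sqrt(sigma2)
  list(U = u, p.value = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

#' Sector-size sweep of the sector-versus-conservation comparison
#'
#' For each size k, forms the top-k set of the SCA top eigenvector and the
#' top-k conserved set, and compares their effect distributions with the
#' two-sided Mann-Whitney U test; also reports the overlap fraction
#' `|intersection| / k`.
#'
#' @param spec result of [sca_spectral()].
#' @param D conservation vector (same columns as the eigenvector).
#' @param data a `mutational_data`; positions are alignment columns unless a
#'   `residue_numbers` mapping is given.
#' @param sizes integer vector of set sizes within `[1, n]`.
#' @param residue_numbers optional mapping from column index to residue
#'   number used in `data` (default: columns are the positions).
#' @return data.frame with columns `size`, `p_mannwhitney`, `overlap`.
#' @export
sweep_sector_size <- function(spec, D, data, sizes,
                              residue_numbers = seq_along(D)) {
  n <- length(D)
  if (any(sizes < 1L | sizes > n)) stop(sprintf("sizes must lie in [1, %d]", n))
  v <- spec$vectors[, 1L]
  res <- lapply(sizes, function(k) {
    sca_set <- residue_numbers[order(-v, seq_len(n))[seq_len(k)]]
    cons_set <- residue_numbers[top_conserved_set(D, k)]
    mw <- mannwhitney_effects(data, sca_set, cons_set)
    data.frame(size = k, p_mannwhitney = mw$p.value,
               overlap = length(intersect(sca_set, cons_set)) / k)
  })
  do.call(rbind, res)
}

#' Linear regression of phenotypes on eigenvector components
#'
#' Ordinary least squares of a per-position phenotype on the components of the
#' top m eigenvectors at those positions, plus an intercept.
#'
#' @param phenotype numeric vector of per-position values.
#' @param spec result of [sca_spectral()] with at least m modes.
#' @param positions column indices of the scored positions (parallel to
#'   `phenotype`).
#' @param m number of eigenvectors to use; `m = 0` fits the intercept only.
#' @return list with `coefficients`, `fitted`, `r_squared`.
#' @export
regress_phenotypes_on_eigenvectors <- function(phenotype, spec, positions, m) {
  npts <- length(phenotype)
  if (length(positions) != npts) stop("phenotype and positions must be parallel")
  if (npts <= m + 1L) stop("underdetermined regression: need more positions than m + 1")
  if (m == 0L) {
    mu <- mean(phenotype)
    return(list(coefficients = c(intercept = mu),
                fitted = rep(mu, npts), r_squared = 0))
  }
  if (ncol(spec$vectors) < m) stop("spectral result holds fewer than m modes")
  X <- spec$vectors[positions, seq_len(m), drop = FALSE]
  colnames(X) <- paste0("v", seq_len(m))
  fit <- stats::lm(phenotype ~ X)
  list(coefficients = stats::coef(fit),
       fitted = stats::fitted(fit),
       r_squared = summary(fit)$r.squared)
}
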