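#' Run the sector-versus-conservation analysis pipeline
#'
#' Orchestrates the full analysis: gap-column filtering, frequencies,
#' conservation, SCA matrix and spectrum, sector extraction, and — when a
#' mutational dataset is supplied — the contingency/Fisher and Mann-Whitney
#' comparison of the sector against the equally sized conserved set. An
#' optional structure stage computes touching sets for insertion sites. All
#' numeric artifacts, a run manifest with parameters, and a summary report are
#' written under `outdir`.
#'
#' @param config either a path to a YAML config file or a named list. Fields:
#'   `alignment` (FASTA path) or `generator` (list: kind, N, n, profile/
#'   parameters, seed); `ref_id`; `effects` (path) or `effects_sim` (list:
#'   link omitted, noise_sd, functional_threshold, seed); `structure` (PDB
#'   path), `chain`, `insertion_sites`, `cutoff`; `gap_threshold` (default
#'   0.4); `sector_fraction` (default 0.25); `gap_mode`; `background`
#'   ("database" or "uniform"); `rule` and `threshold` for functional calls;
#'   `outdir` (required).
#' @return invisibly, a list with the main results (`sca`, `comparison`,
#'   `structure`, `manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("[config] file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  cfg <- config
  if (is.null(cfg[["outdir"]])) stop("[config] 'outdir' is required")
  dir.create(cfg[["outdir"]], showWarnings = FALSE, recursive = TRUE)
  gap_threshold <- cfg[["gap_threshold"]] %||% 0.4
  fraction <- cfg[["sector_fraction"]] %||% 0.25
  gap_mode <- cfg[["gap_mode"]] %||% "average_gap"
  background <- cfg[["background"]] %||% "database"

  log_msg <- function(stage, ...) message(sprintf("[%s] %s", stage, sprintf(...)))

  # --- alignment stage ------------------------------------------------------
  aln <- tryCatch({
    if (!is.null(cfg[["alignment"]])) {
      read_fasta_alignment(cfg[["alignment"]], reference_id = cfg[["ref_id"]])
    } else if (!is.null(cfg[["generator"]])) {
      g <- cfg[["generator"]]
      profile <- g[["profile"]] %||% heterogeneous_profile(g[["n"]])
      switch(g[["kind"]] %||% "independent",
             independent = sample_independent_alignment(g[["N"]], g[["n"]], profile, g[["seed"]]),
             planted_sector = sample_sector_alignment(g[["N"]], g[["n"]], profile,
                                                      g[["sector_positions"]],
                                                      g[["coupling"]], g[["seed"]]),
             star_phylogeny = sample_star_phylogeny_alignment(
               g[["N"]], g[["n"]], profile, g[["seed"]],
               n_ancestors = g[["n_ancestors"]] %||% 5L,
               mutation_rate = g[["mutation_rate"]] %||% 0.25),
             stop(sprintf("unknown generator kind '%s'", g[["kind"]])))
    } else stop("config must give 'alignment' or 'generator'")
  }, error = function(e) stop(sprintf("[alignment] %s", conditionMessage(e)), call. = FALSE))
  log_msg("alignment", "%d sequences x %d columns", nrow(aln$seqs), ncol(aln$seqs))

  aln <- tryCatch(filter_gap_columns(aln, gap_threshold),
                  error = function(e) stop(sprintf("[filter] %s", conditionMessage(e)), call. = FALSE))
  log_msg("filter", "%d columns retained (gap threshold %.2f)",
          ncol(aln$seqs), gap_threshold)

  # --- SCA stage ------------------------------------------------------------
  sca <- tryCatch(
    run_sca(aln, q_aa = aa_background(background), gap_mode = gap_mode,
            fraction = fraction),
    error = function(e) stop(sprintf("[sca] %s", conditionMessage(e)), call. = FALSE))
  n <- ncol(aln$seqs)
  residue_numbers <- if (!is.null(cfg[["ref_id"]])) {
    map_columns_to_reference(aln, cfg[["ref_id"]])
  } else seq_len(n)
  log_msg("sca", "sector of %d positions (fraction %.2f)", sca$sector$size, fraction)

  write_fasta_alignment(aln, file.path(cfg[["outdir"]], "alignment_filtered.fasta"))
  write_conservation(sca$D, file.path(cfg[["outdir"]], "conservation.tsv"),
                     residue_numbers = residue_numbers)
  utils::write.table(round(sca$C, 10), file.path(cfg[["outdir"]], "sca_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  eig <- data.frame(value = sca$spec$values)
  utils::write.table(cbind(eig, t(matrix(sca$spec$vectors,
                                         ncol = length(sca$spec$values)))),
                     file.path(cfg[["outdir"]], "eigenmodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  sector_df <- data.frame(column = sca$sector$positions,
                          residue = residue_numbers[sca$sector$positions],
                          score = sca$sector$scores[sca$sector$positions])
  utils::write.table(sector_df, file.path(cfg[["outdir"]], "sector.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- comparison stage -----------------------------------------------------
  comparison <- NULL
  data <- NULL
  if (!is.null(cfg[["effects"]])) {
    data <- tryCatch(read_mutational_data(cfg[["effects"]]),
                     error = function(e) stop(sprintf("[effects] %s", conditionMessage(e)), call. = FALSE))
    data <- call_functional_sites(data, cfg[["rule"]] %||% "effect_threshold",
                                  cfg[["threshold"]] %||% 1)
  } else if (!is.null(cfg[["effects_sim"]])) {
    es <- cfg[["effects_sim"]]
    data <- sample_mutational_effects(sca$D, noise_sd = es[["noise_sd"]] %||% 0.2,
                                      functional_threshold = es[["functional_threshold"]] %||% 1,
                                      seed = es[["seed"]] %||% 1L,
                                      positions = residue_numbers)
  }
  if (!is.null(data)) {
    comparison <- tryCatch({
      scored <- intersect(residue_numbers[!is.na(residue_numbers)], data$position)
      scored_cols <- which(residue_numbers %in% scored)
      k <- sca$sector$size
      v <- sca$sector$scores
      sca_cols <- scored_cols[order(-v[scored_cols])][seq_len(min(k, length(scored_cols)))]
      cons_cols <- scored_cols[order(-sca$D[scored_cols])][seq_len(min(k, length(scored_cols)))]
      sca_set <- residue_numbers[sca_cols]
      cons_set <- residue_numbers[cons_cols]
      tabA <- contingency(sca_set, data, scored)
      tabB <- contingency(cons_set, data, scored)
      mw <- mannwhitney_effects(data, sca_set, cons_set)
      list(sector_table = tabA, conserved_table = tabB,
           fisher_sector = fisher_one_tailed(tabA),
           fisher_conserved = fisher_one_tailed(tabB),
           chi2 = chi2_compare_tables(tabA, tabB),
           mannwhitney = mw,
           overlap = length(intersect(sca_set, cons_set)) / length(sca_set))
    }, error = function(e) stop(sprintf("[compare] %s", conditionMessage(e)), call. = FALSE))
    log_msg("compare", "Fisher p (sector) = %.3g; MW p (sector vs conserved) = %.3g",
            comparison$fisher_sector, comparison$mannwhitney$p.value)
  }

  # --- structure stage ------------------------------------------------------
  struct_res <- NULL
  if (!is.null(cfg[["structure"]])) {
    struct_res <- tryCatch({
      s <- read_structure(cfg[["structure"]], chain = cfg[["chain"]])
      out <- list()
      if (!is.null(cfg[["insertion_sites"]])) {
        sector_res <- residue_numbers[sca$sector$positions]
        sector_res <- sector_res[!is.na(sector_res)]
        out$touch <- sector_touch_counts(sector_res, cfg[["insertion_sites"]], s,
                                         cutoff = cfg[["cutoff"]] %||% 4.0)
      }
      out$center <- conservation_vs_center_distance(s, sca$D, residue_numbers)
      utils::write.table(out$center$table,
                         file.path(cfg[["outdir"]], "conservation_vs_distance.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out
    }, error = function(e) stop(sprintf("[structure] %s", conditionMessage(e)), call. = FALSE))
  }

  # --- manifest and summary -------------------------------------------------
  manifest <- list(parameters = list(gap_threshold = gap_threshold,
                                     sector_fraction = fraction,
                                     gap_mode = gap_mode,
                                     background = background),
                   config = cfg,
                   n_sequences = nrow(aln$seqs), n_columns = n)
  jsonlite::write_json(manifest, file.path(cfg[["outdir"]], "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  summary <- list(sector_size = sca$sector$size,
                  top_eigenvalue = sca$spec$values[1L],
                  r_topvec_sqrtdiag = topvec_diag_correlation(sca$C, sca$spec)$r_sqrt_diag)
  if (!is.null(comparison)) {
    summary$fisher_sector_p <- comparison$fisher_sector
    summary$fisher_conserved_p <- comparison$fisher_conserved
    summary$mannwhitney_p <- comparison$mannwhitney$p.value
    summary$overlap <- comparison$overlap
  }
  if (!is.null(struct_res) && !is.null(struct_res$touch))
    summary$sites_touched <- struct_res$touch$count
  jsonlite::write_json(summary, file.path(cfg[["outdir"]], "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(sca = sca, comparison = comparison, structure = struct_res,
                 manifest = manifest, summary = summary, alignment = aln))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
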