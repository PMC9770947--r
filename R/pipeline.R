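#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> identify (two-tier FDR + clustering) ->
#' quantify -> test -> profile -> variant filter as one reproducible run.
#' Every stage writes its tables under `out_dir` and the run closes with a
#' machine-readable `summary.json` carrying the record counts at each
#' filter stage, the seed and a hash of the configuration, plus a plain-
#' text `pipeline.log`.
#'
#' The identification stage mirrors the two-tier procedure: all target and
#' decoy PrSMs are pooled and filtered at the spectrum-level FDR, the
#' survivors (targets and decoys alike) are clustered into proteoforms
#' within `mass_tol` Da, and the cluster representatives are filtered at
#' the proteoform-level FDR. Quantification then sums fraction intensities
#' per replicate, matches proteoforms across runs, keeps complete cases,
#' normalizes (reference ratio, median centering, log2) and applies the
#' S0-moderated permutation test.
#'
#' @param out_dir output directory (created if needed).
#' @param sim a [sim_config()] describing the synthetic inputs, or `NULL`
#'   when `prsms` is given.
#' @param prsms optional path to an existing PrSM table (TSV); overrides
#'   simulation.
#' @param spectrum_fdr,proteoform_fdr the two FDR tiers (defaults 0.05 and
#'   0.01).
#' @param mass_tol clustering / cross-run matching window in Da.
#' @param s0,diff_fdr,n_permutations differential-test settings (defaults
#'   1, 0.05, 1000).
#' @param reference reference run for normalization (index or column name).
#' @return invisibly, a list with the summary (also written as JSON) and the
#'   principal in-memory objects (`proteoforms`, `quant`, `diff`).
#' @export
run_pipeline <- function(out_dir, sim = sim_config(), prsms = NULL,
                         spectrum_fdr = 0.05, proteoform_fdr = 0.01,
                         mass_tol = 2.2, s0 = 1, diff_fdr = 0.05,
                         n_permutations = 1000L, reference = 1L) {
  if (!is.null(prsms) && is.character(prsms) && !file.exists(prsms)) {
    stop("input PrSM table not found: ", prsms, call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  summary <- list()

  truth <- NULL
  frag <- NULL
  if (is.null(prsms)) {
    stage("simulate", {
      proteome <- simulate_reference_proteome(sim)
      truth <- simulate_truth_set(sim, proteome)
      tab <- simulate_prsm_tables(sim, truth)
      frag <- simulate_fragment_data(truth, sim)
      write_fasta(truth$proteome, file.path(out_dir, "proteome.fasta"))
      write_prsm_table(tab, file.path(out_dir, "prsms.tsv"))
      write.table(truth$registry, file.path(out_dir, "truth_registry.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      prsms <- tab
      note("simulate: %d truth proteoforms, %d PrSMs",
           nrow(truth$registry), nrow(tab))
    })
  } else if (is.character(prsms)) {
    prsms <- stage("read", read_prsm_table(prsms))
  }
  summary$n_prsms_input <- nrow(prsms)

  spec_pass <- stage("spectrum_fdr", {
    scored <- add_q_values(prsms)
    scored[scored$q_value <= spectrum_fdr, , drop = FALSE]
  })
  note("spectrum-level FDR %.2g: %d of %d PrSMs retained (%d decoys)",
       spectrum_fdr, nrow(spec_pass), nrow(prsms), sum(spec_pass$is_decoy))
  summary$n_prsms_spectrum_fdr <- nrow(spec_pass)

  proteoforms <- stage("cluster", {
    cl <- cluster_prsms(spec_pass, mass_tol = mass_tol)
    reps <- representative_set(cl)
    write.table(reps, file.path(out_dir, "clusters.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    reps
  })
  note("clustering at %.1f Da: %d clusters", mass_tol, nrow(proteoforms))
  summary$n_clusters <- nrow(proteoforms)

  final <- stage("proteoform_fdr", filter_at_fdr(proteoforms, proteoform_fdr))
  write.table(final, file.path(out_dir, "proteoforms.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  note("proteoform-level FDR %.2g: %d proteoforms reported",
       proteoform_fdr, nrow(final))
  summary$n_proteoforms <- nrow(final)

  qm <- diff <- NULL
  quant_input <- spec_pass[!spec_pass$is_decoy, , drop = FALSE]
  n_runs <- nrow(unique(quant_input[, c("condition", "replicate")]))
  if (n_runs >= 2L) {
    qm <- stage("quantify", {
      prof <- replicate_profiles(quant_input, mass_tol = mass_tol)
      m <- match_across_runs(prof, mass_tol = mass_tol)
      summary$n_quant_rows <- nrow(m$abundance)
      m <- complete_case_filter(m)
      summary$n_quant_complete <- nrow(m$abundance)
      norm <- normalize_quant(m, reference = reference)
      write.table(cbind(norm$rows, norm$abundance),
                  file.path(out_dir, "quant_log2.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      norm
    })
    note("quantification: %d complete-case proteoforms across %d runs",
         nrow(qm$abundance), ncol(qm$abundance))
    if (length(unique(qm$design$condition)) == 2L &&
        all(table(qm$design$condition) >= 2L) && nrow(qm$abundance) >= 2L) {
      diff <- stage("test", {
        res <- permutation_fdr(qm, s0 = s0, fdr = diff_fdr,
                               n_permutations = n_permutations,
                               seed = if (is.null(sim)) 1L else sim$seed)
        write.table(res, file.path(out_dir, "diff_results.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        write.table(volcano_table(res), file.path(out_dir, "volcano.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        res
      })
      note("differential test (s0=%.2g, FDR %.2g): %d significant of %d",
           s0, diff_fdr, sum(diff$significant), nrow(diff))
      summary$n_significant <- sum(diff$significant)
    }
  }

  stage("profile", {
    parsed <- lapply(final$proteoform[!is.na(final$proteoform)],
                     function(s) tryCatch(parse_proteoform(s),
                                          error = function(e) NULL))
    parsed <- Filter(Negate(is.null), parsed)
    census <- ptm_census(parsed)
    write.table(census, file.path(out_dir, "ptm_census.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    summary$n_ptm_categorized <- sum(
      census$count[!census$category %in% c("unassigned", "unmodified")])
  })

  if (!is.null(truth) && !is.null(frag) && nrow(frag$verdicts)) {
    stage("saav", {
      reg <- truth$registry[!is.na(truth$registry$saav_core), , drop = FALSE]
      verdicts <- vapply(seq_len(nrow(reg)), function(i) {
        p <- parse_proteoform(reg$proteoform[i])
        theo <- theoretical_fragments(p$core_sequence, p$named_mods)
        obs <- frag$observed$mass[frag$observed$proteoform_id ==
                                    reg$proteoform_id[i]]
        interval <- if (is.na(reg$shift_start[i])) NULL else
          c(reg$shift_start[i], reg$shift_end[i])
        saav_confidence_filter(theo, obs, reg$saav_core[i],
                               interval)$confident
      }, logical(1))
      out <- data.frame(proteoform_id = reg$proteoform_id,
                        confident = verdicts)
      write.table(out, file.path(out_dir, "saav_verdicts.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      summary$n_saav_confident <- sum(verdicts)
    })
  }

  summary$seed <- if (is.null(sim)) NA else sim$seed
  summary$config_hash <- local({
    tf <- tempfile()
    on.exit(unlink(tf))
    saveRDS(list(sim = unclass(sim), spectrum_fdr = spectrum_fdr,
                 proteoform_fdr = proteoform_fdr, mass_tol = mass_tol,
                 s0 = s0, diff_fdr = diff_fdr,
                 n_permutations = n_permutations, reference = reference),
            tf, version = 2, compress = FALSE)
    unname(tools::md5sum(tf))
  })
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, log_path)
  invisible(list(summary = summary, proteoforms = final, quant = qm,
                 diff = diff))
}
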