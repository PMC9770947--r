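#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the ground-truthed simulator. The defaults emulate
#' the statistical structure the downstream analysis assumes: a two-state
#' design with three technical replicates per state, six fractions per
#' replicate, true-hit E-values well separated from a shared
#' false-target/decoy E-value distribution (the exchangeability that makes
#' target-decoy FDR valid), ppm-scale precursor mass noise with occasional
#' +/- 1.00235 Da isotopologue errors, unimodal per-fraction intensity
#' profiles under a log-normal run effect, intensity-dependent (logistic)
#' missingness, spiked log2 fold changes, and SAAV proteoforms with partial
#' fragment coverage. `seed` fixes all randomness end to end: the same
#' configuration always yields identical outputs.
#'
#' @param n_proteins number of target proteins (an equal-size shuffled decoy
#'   set is generated alongside).
#' @param proteoforms_per_protein mean extra proteoforms per protein; each
#'   protein carries `1 + Poisson(proteoforms_per_protein)` proteoforms.
#' @param protein_length_range residue-length range for simulated proteins.
#' @param n_conditions,n_replicates,n_fractions the run design.
#' @param true_hit_fraction probability that a (proteoform, run) slot emits a
#'   true PrSM attempt rather than a noise record (noise splits evenly
#'   between false targets and decoys).
#' @param e_value_params list with `true_log10_range` and `null_log10_range`:
#'   E-values are drawn log-uniform over these ranges for true hits and for
#'   the shared false-target/decoy distribution respectively.
#' @param mass_error_ppm_sd SD of the relative precursor mass error, ppm.
#' @param isotope_error_prob probability of an added +/- 1.00235 Da
#'   deconvolution error (averagine isotope spacing).
#' @param intensity_log2_mean_range central ~95% range of the per-proteoform
#'   base log2 abundance (mean at the midpoint, SD a quarter of the width).
#' @param intensity_log2_sd SD of the log2-scale run effect.
#' @param detect_logistic_params `c(midpoint, slope)` of the detection
#'   probability as a logistic function of log2 fraction intensity.
#' @param n_differential number of proteoforms with a spiked between-
#'   condition fold change.
#' @param fold_changes log2 fold changes to sample spikes from (applied to
#'   condition 2).
#' @param n_saav_proteoforms number of proteoforms carrying a single amino
#'   acid variant.
#' @param fragment_coverage_prob retention probability per theoretical
#'   fragment when emitting observed fragment lists.
#' @param shift_prob probability that a proteoform carries an unexpected
#'   mass shift.
#' @param min_mass_separation minimum mass gap (Da) enforced between
#'   proteoforms of one protein, so that proteoform identity is
#'   well-defined under the 2.2-Da clustering window.
#' @param seed integer seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 100L,
                       proteoforms_per_protein = 1.0,
                       protein_length_range = c(60L, 300L),
                       n_conditions = 2L,
                       n_replicates = 3L,
                       n_fractions = 6L,
                       true_hit_fraction = 0.85,
                       e_value_params = list(true_log10_range = c(-12, -5),
                                             null_log10_range = c(-4, 1)),
                       mass_error_ppm_sd = 2,
                       isotope_error_prob = 0.02,
                       intensity_log2_mean_range = c(20, 30),
                       intensity_log2_sd = 0.5,
                       detect_logistic_params = c(midpoint = 16, slope = 1),
                       n_differential = 10L,
                       fold_changes = c(-2, -1, 1, 2),
                       n_saav_proteoforms = 5L,
                       fragment_coverage_prob = 0.7,
                       shift_prob = 0.2,
                       min_mass_separation = 5,
                       seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              proteoforms_per_protein = proteoforms_per_protein,
              protein_length_range = as.integer(protein_length_range),
              n_conditions = as.integer(n_conditions),
              n_replicates = as.integer(n_replicates),
              n_fractions = as.integer(n_fractions),
              true_hit_fraction = true_hit_fraction,
              e_value_params = e_value_params,
              mass_error_ppm_sd = mass_error_ppm_sd,
              isotope_error_prob = isotope_error_prob,
              intensity_log2_mean_range = intensity_log2_mean_range,
              intensity_log2_sd = intensity_log2_sd,
              detect_logistic_params = detect_logistic_params,
              n_differential = as.integer(n_differential),
              fold_changes = fold_changes,
              n_saav_proteoforms = as.integer(n_saav_proteoforms),
              fragment_coverage_prob = fragment_coverage_prob,
              shift_prob = shift_prob,
              min_mass_separation = min_mass_separation,
              seed = as.integer(seed))
  probs <- c(cfg$true_hit_fraction, cfg$isotope_error_prob,
             cfg$fragment_coverage_prob, cfg$shift_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  counts <- c(cfg$n_proteins, cfg$n_conditions, cfg$n_replicates,
              cfg$n_fractions)
  if (any(counts < 1L)) stop("counts must be positive", call. = FALSE)
  if (cfg$n_differential < 0L || cfg$n_saav_proteoforms < 0L) {
    stop("counts must be non-negative", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a reference proteome with companion decoys
#'
#' Random protein sequences over the 20 standard amino acids, plus one
#' shuffled decoy per target under a `"DECOY_"`-prefixed accession.
#' Deterministic under the configuration seed.
#'
#' @param cfg a [sim_config()].
#' @return named character vector of `2 * n_proteins` sequences (targets
#'   first).
#' @export
simulate_reference_proteome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_local_seed(.module_seed(cfg$seed, 1L), {
    aa <- names(AA_MONO)[names(AA_MONO) != "I"]  # L/I isobaric; keep L
    lens <- sample(seq(cfg$protein_length_range[1],
                       cfg$protein_length_range[2]),
                   cfg$n_proteins, replace = TRUE)
    targets <- vapply(lens, function(n)
      paste(sample(aa, n, replace = TRUE), collapse = ""), "")
    names(targets) <- sprintf("PROT%04d", seq_len(cfg$n_proteins))
    decoys <- vapply(targets, function(s)
      paste(sample(strsplit(s, "")[[1]]), collapse = ""), "")
    names(decoys) <- paste0(DECOY_PREFIX, names(targets))
    c(targets, decoys)
  })
}

# build one truth proteoform record; returns NULL on an unusable draw
.draw_proteoform <- function(acc, seq, cfg) {
  len <- nchar(seq)
  if (stats::runif(1) < 0.6) {
    start <- sample(1:2, 1L); end <- len
  } else {
    start <- sample(seq_len(max(1L, len - 30L)), 1L)
    end <- sample(seq(min(start + 19L, len), len), 1L)
  }
  core <- substr(seq, start, end)
  core_len <- nchar(core)
  if (core_len < 20L) return(NULL)
  mods <- data.frame(start = integer(0), end = integer(0),
                     name = character(0), mass = numeric(0),
                     stringsAsFactors = FALSE)
  if (stats::runif(1) < 0.3) {
    mods <- data.frame(start = 1L, end = 1L, name = "acetyl",
                       mass = MOD_MONO[["acetyl"]], stringsAsFactors = FALSE)
  }
  shifts <- data.frame(start = integer(0), end = integer(0),
                       mass = numeric(0), annotation = character(0),
                       stringsAsFactors = FALSE)
  if (stats::runif(1) < cfg$shift_prob) {
    w <- min(10L, core_len - 6L)
    a <- sample(seq(3L, core_len - w), 1L)
    shifts <- data.frame(start = a, end = a + w - 1L,
                         mass = sample(c(79.96633, 15.99491, 159.93266), 1L),
                         annotation = "unknown", stringsAsFactors = FALSE)
  }
  list(acc = acc, start = start, end = end, core = core, mods = mods,
       shifts = shifts, protein_len = len)
}

#' Simulate the proteoform truth registry
#'
#' Draws `1 + Poisson(proteoforms_per_protein)` proteoforms per protein —
#' intact or truncated spans, optionally N-terminally acetylated, optionally
#' carrying one localized unexpected mass shift — assigns per-condition true
#' log2 abundances with `n_differential` spiked fold changes on condition 2,
#' and converts `n_saav_proteoforms` of them into single-substitution
#' variant proteoforms under variant accessions. Within each protein,
#' proteoform masses are kept at least `min_mass_separation` Da apart so
#' that the truth registry is recoverable by mass clustering.
#'
#' @param cfg a [sim_config()].
#' @param proteome result of [simulate_reference_proteome()] (targets and
#'   decoys).
#' @return list of class `truth_set` with elements `registry` (data.frame),
#'   `proteome` (the input, plus variant entries), `variants` (variant
#'   table) and `cfg`.
#' @export
simulate_truth_set <- function(cfg, proteome) {
  stopifnot(inherits(cfg, "sim_config"))
  targets <- proteome[!startsWith(names(proteome), DECOY_PREFIX)]
  with_local_seed(.module_seed(cfg$seed, 2L), {
    recs <- list()
    for (i in seq_along(targets)) {
      acc <- names(targets)[i]
      k <- 1L + stats::rpois(1L, cfg$proteoforms_per_protein)
      masses <- numeric(0)
      for (j in seq_len(k)) {
        for (attempt in 1:20) {
          r <- .draw_proteoform(acc, targets[[i]], cfg)
          if (is.null(r)) next
          p <- structure(list(prefix_residue = NA_character_,
                              suffix_residue = NA_character_,
                              core_sequence = r$core,
                              named_mods = r$mods,
                              unexpected_shifts = r$shifts),
                         class = "parsed_proteoform")
          m <- proteoform_mass(p, fixed_cys = TRUE)
          if (!length(masses) ||
              min(abs(masses - m)) >= cfg$min_mass_separation) {
            masses <- c(masses, m)
            r$mass <- m
            recs[[length(recs) + 1L]] <- r
            break
          }
        }
      }
    }
    n <- length(recs)
    # SAAV proteoforms: substitute one residue outside any shift interval
    saav_idx <- if (cfg$n_saav_proteoforms > 0L)
      sample(n, min(cfg$n_saav_proteoforms, n)) else integer(0)
    variants <- list()
    for (i in saav_idx) {
      r <- recs[[i]]
      core_len <- nchar(r$core)
      cand <- setdiff(seq_len(core_len),
                      if (nrow(r$shifts)) seq(r$shifts$start, r$shifts$end)
                      else integer(0))
      pos <- sample(cand, 1L)
      ref <- substr(r$core, pos, pos)
      alt <- sample(setdiff(names(AA_MONO)[names(AA_MONO) != "I"], ref), 1L)
      substr(r$core, pos, pos) <- alt
      prot_pos <- r$start + pos - 1L
      r$saav_core <- pos
      r$saav_protein <- prot_pos
      r$saav_ref <- ref
      r$saav_alt <- alt
      variants[[length(variants) + 1L]] <- data.frame(
        protein_accession = r$acc, position = prot_pos, ref_aa = ref,
        alt_aa = alt, stringsAsFactors = FALSE)
      r$acc <- sprintf("%s_%s%d%s", r$acc, ref, prot_pos, alt)
      r$mass <- r$mass - AA_MONO[[ref]] + AA_MONO[[alt]]
      recs[[i]] <- r
    }
    variants <- if (length(variants)) do.call(rbind, variants) else
      data.frame(protein_accession = character(0), position = integer(0),
                 ref_aa = character(0), alt_aa = character(0))

    base <- stats::rnorm(n, mean(cfg$intensity_log2_mean_range),
                         diff(range(cfg$intensity_log2_mean_range)) / 4)
    diff_idx <- if (cfg$n_differential > 0L)
      sample(n, min(cfg$n_differential, n)) else integer(0)
    delta <- numeric(n)
    delta[diff_idx] <- sample(cfg$fold_changes, length(diff_idx),
                              replace = TRUE)
    peak <- sample(seq_len(cfg$n_fractions), n, replace = TRUE)

    registry <- data.frame(
      proteoform_id = sprintf("PT%05d", seq_len(n)),
      protein_accession = vapply(recs, `[[`, "", "acc"),
      start = vapply(recs, `[[`, 1L, "start"),
      end = vapply(recs, `[[`, 1L, "end"),
      protein_len = vapply(recs, `[[`, 1L, "protein_len"),
      proteoform = vapply(recs, function(r) {
        p <- structure(list(prefix_residue = NA_character_,
                            suffix_residue = NA_character_,
                            core_sequence = r$core, named_mods = r$mods,
                            unexpected_shifts = r$shifts),
                       class = "parsed_proteoform")
        format_proteoform(p)
      }, ""),
      mass = vapply(recs, `[[`, 1, "mass"),
      shift_mass = vapply(recs, function(r)
        if (nrow(r$shifts)) r$shifts$mass else NA_real_, 1),
      shift_start = vapply(recs, function(r)
        if (nrow(r$shifts)) r$shifts$start else NA_integer_, 1L),
      shift_end = vapply(recs, function(r)
        if (nrow(r$shifts)) r$shifts$end else NA_integer_, 1L),
      saav_core = vapply(recs, function(r)
        if (!is.null(r$saav_core)) r$saav_core else NA_integer_, 1L),
      saav_protein = vapply(recs, function(r)
        if (!is.null(r$saav_protein)) r$saav_protein else NA_integer_, 1L),
      saav_ref = vapply(recs, function(r)
        if (!is.null(r$saav_ref)) r$saav_ref else NA_character_, ""),
      saav_alt = vapply(recs, function(r)
        if (!is.null(r$saav_alt)) r$saav_alt else NA_character_, ""),
      log2_abund_cond1 = base,
      log2_abund_cond2 = base + delta,
      log2_fc_true = delta,
      differential = seq_len(n) %in% diff_idx,
      peak_fraction = peak,
      stringsAsFactors = FALSE
    )
    variant_seqs <- apply_variants(
      proteome[!startsWith(names(proteome), DECOY_PREFIX)], variants)
    full <- c(variant_seqs,
              proteome[startsWith(names(proteome), DECOY_PREFIX)])
    structure(list(registry = registry, proteome = full,
                   variants = variants, cfg = cfg),
              class = "truth_set")
  })
}

# log2 fraction weights of a unimodal profile centered on `peak`
.fraction_profile <- function(peak, n_fractions, width = 1.5) {
  w <- exp(-(seq_len(n_fractions) - peak)^2 / (2 * width^2))
  w / sum(w)
}

#' Simulate per-run PrSM tables with truth labels
#'
#' For every (proteoform, condition, replicate, fraction) slot: with
#' probability `true_hit_fraction` a true PrSM attempt is made — the
#' fraction-level intensity follows the proteoform's unimodal fraction
#' profile scaled by a log-normal run effect, and the record is emitted only
#' if a logistic detection draw on log2 intensity succeeds; the precursor
#' mass is the truth mass plus Normal ppm noise plus, with probability
#' `isotope_error_prob`, a +/- 1.00235 Da isotopologue error, and the
#' E-value is drawn log-uniform over the low (true) range. Otherwise the
#' slot emits a noise record, equally likely a false target or a decoy,
#' with E-value from the single shared high (null) distribution — the
#' exchangeability under which decoy counts estimate false-target counts.
#'
#' @param cfg a [sim_config()].
#' @param truth a [simulate_truth_set()] result generated from `cfg`.
#' @return data.frame of PrSM records (all runs merged; `condition`,
#'   `replicate`, `fraction` give the run structure) with truth columns
#'   `truth` (`"true"`, `"false_target"`, `"decoy"`) and `proteoform_id`.
#' @export
simulate_prsm_tables <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "truth_set"))
  reg <- truth$registry
  n <- nrow(reg)
  accs <- names(truth$proteome)
  target_accs <- accs[!startsWith(accs, DECOY_PREFIX)]
  decoy_accs <- accs[startsWith(accs, DECOY_PREFIX)]
  mid <- cfg$detect_logistic_params[[1]]
  slope <- cfg$detect_logistic_params[[2]]
  mass_range <- range(reg$mass)
  profiles <- t(vapply(reg$peak_fraction, .fraction_profile,
                       numeric(cfg$n_fractions),
                       n_fractions = cfg$n_fractions))
  with_local_seed(.module_seed(cfg$seed, 3L), {
    parts <- list()
    for (cond_i in seq_len(cfg$n_conditions)) {
      cond <- sprintf("COND%d", cond_i)
      la <- if (cond_i == 1L) reg$log2_abund_cond1 else reg$log2_abund_cond2
      for (rep_ in seq_len(cfg$n_replicates)) {
        run_eff <- stats::rnorm(n, 0, cfg$intensity_log2_sd)
        li <- matrix(la + run_eff, n, cfg$n_fractions) + log2(profiles)
        slot_true <- matrix(stats::runif(n * cfg$n_fractions) <
                              cfg$true_hit_fraction, n)
        detected <- matrix(stats::runif(n * cfg$n_fractions), n) <
          stats::plogis(slope * (li - mid))

        idx <- which(slot_true & detected, arr.ind = TRUE)
        k <- nrow(idx)
        true_df <- if (k) {
          i <- idx[, 1]
          m <- reg$mass[i] *
            (1 + stats::rnorm(k, 0, cfg$mass_error_ppm_sd * 1e-6))
          iso <- stats::runif(k) < cfg$isotope_error_prob
          m <- m + iso * sample(c(-1, 1), k, replace = TRUE) * ISOTOPE_DA
          data.frame(
            condition = cond, replicate = rep_, fraction = idx[, 2],
            protein_accession = reg$protein_accession[i],
            proteoform = reg$proteoform[i],
            start_pos = reg$start[i], end_pos = reg$end[i],
            precursor_mass = m,
            e_value = 10^stats::runif(
              k, cfg$e_value_params$true_log10_range[1],
              cfg$e_value_params$true_log10_range[2]),
            intensity = 2^li[idx],
            charge = sample(5:20, k, replace = TRUE),
            migration_time = stats::runif(k, 10, 60),
            is_decoy = FALSE, truth = "true",
            proteoform_id = reg$proteoform_id[i],
            stringsAsFactors = FALSE)
        }
        nidx <- which(!slot_true, arr.ind = TRUE)
        k2 <- nrow(nidx)
        noise_df <- if (k2) {
          dec <- stats::runif(k2) < 0.5
          acc <- character(k2)
          acc[dec] <- sample(decoy_accs, sum(dec), replace = TRUE)
          acc[!dec] <- sample(target_accs, sum(!dec), replace = TRUE)
          seqs <- unname(truth$proteome[acc])
          len <- nchar(seqs)
          w <- pmin(len, 30L)
          st <- floor(stats::runif(k2) * (len - w + 1)) + 1L
          data.frame(
            condition = cond, replicate = rep_, fraction = nidx[, 2],
            protein_accession = acc,
            proteoform = paste0(".", substr(seqs, st, st + w - 1L), "."),
            start_pos = st, end_pos = st + w - 1L,
            precursor_mass = stats::runif(k2, mass_range[1], mass_range[2]),
            e_value = 10^stats::runif(
              k2, cfg$e_value_params$null_log10_range[1],
              cfg$e_value_params$null_log10_range[2]),
            intensity = 2^stats::rnorm(k2, mid + 1, 1.5),
            charge = sample(5:20, k2, replace = TRUE),
            migration_time = stats::runif(k2, 10, 60),
            is_decoy = dec, truth = ifelse(dec, "decoy", "false_target"),
            proteoform_id = NA_character_, stringsAsFactors = FALSE)
        }
        parts[[length(parts) + 1L]] <- rbind(true_df, noise_df)
      }
    }
    out <- do.call(rbind, parts)
    out <- cbind(spectrum_id = sprintf("S%07d", seq_len(nrow(out))), out,
                 stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Simulate observed fragment lists for SAAV proteoforms
#'
#' For each variant proteoform in the truth registry, the theoretical b/y
#' fragments of its (variant) core sequence are computed, each retained with
#' probability `fragment_coverage_prob` and jittered by a relative error
#' drawn uniformly within +/- 14.9 ppm (strictly inside the 15-ppm matching
#' tolerance, so retained fragments always re-match). The ground-truth
#' flanking-ion count per SAAV site — the number of emitted fragments whose
#' cleavage lies between the site and the nearer edge of the unexpected
#' shift interval — and the resulting confidence verdict are recorded.
#'
#' @param truth a [simulate_truth_set()] result.
#' @param cfg the same [sim_config()].
#' @return list with `observed` (data.frame `proteoform_id`, `mass`),
#'   `flanking` (data.frame `proteoform_id`, `site`, `flanking_count`) and
#'   `verdicts` (data.frame `proteoform_id`, `confident`).
#' @export
simulate_fragment_data <- function(truth, cfg) {
  stopifnot(inherits(truth, "truth_set"), inherits(cfg, "sim_config"))
  reg <- truth$registry[!is.na(truth$registry$saav_core), , drop = FALSE]
  with_local_seed(.module_seed(cfg$seed, 4L), {
    obs <- list(); flank <- list(); verd <- list()
    for (i in seq_len(nrow(reg))) {
      p <- parse_proteoform(reg$proteoform[i])
      theo <- theoretical_fragments(p$core_sequence, p$named_mods)
      keep <- stats::runif(nrow(theo)) < cfg$fragment_coverage_prob
      emitted <- theo[keep, , drop = FALSE]
      jitter <- stats::runif(nrow(emitted), -14.9, 14.9) * 1e-6
      obs[[i]] <- data.frame(
        proteoform_id = rep(reg$proteoform_id[i], nrow(emitted)),
        mass = emitted$mass * (1 + jitter), stringsAsFactors = FALSE)
      site <- reg$saav_core[i]
      if (is.na(reg$shift_start[i])) {
        cnt <- NA_integer_
        confident <- TRUE
      } else {
        a <- reg$shift_start[i]; b <- reg$shift_end[i]
        rng <- if (site < a) seq(site, a - 1L)
        else if (site > b) seq(b, site - 1L) else integer(0)
        cnt <- sum(emitted$cleavage %in% rng)
        confident <- cnt >= 3L
      }
      flank[[i]] <- data.frame(proteoform_id = reg$proteoform_id[i],
                               site = site, flanking_count = cnt,
                               stringsAsFactors = FALSE)
      verd[[i]] <- data.frame(proteoform_id = reg$proteoform_id[i],
                              confident = confident, stringsAsFactors = FALSE)
    }
    list(observed = if (length(obs)) do.call(rbind, obs) else
           data.frame(proteoform_id = character(0), mass = numeric(0)),
         flanking = if (length(flank)) do.call(rbind, flank) else
           data.frame(proteoform_id = character(0), site = integer(0),
                      flanking_count = integer(0)),
         verdicts = if (length(verd)) do.call(rbind, verd) else
           data.frame(proteoform_id = character(0), confident = logical(0)))
  })
}
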