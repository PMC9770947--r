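test_that("fraction summation follows the stated conventions", {
  rec <- data.frame(cluster_id = "C1", fraction = 1:6,
                    intensity = c(1, 2, 3, 0, 0, 0))
  expect_equal(aggregate_fractions(rec)$abundance, 6)

  rec$intensity <- NA_real_
  expect_true(is.na(aggregate_fractions(rec)$abundance))

  rec <- data.frame(cluster_id = "C1", fraction = 3, intensity = 5)
  expect_equal(aggregate_fractions(rec)$abundance, 5)

  # duplicates within a fraction resolve to the maximum
  rec <- data.frame(cluster_id = "C1", fraction = c(1, 1, 2),
                    intensity = c(10, 40, 5))
  expect_equal(aggregate_fractions(rec)$abundance, 45)

  rec$intensity[1] <- -1
  expect_error(aggregate_fractions(rec), "negative")
})

make_profiles <- function(masses, abund, conds, reps,
                          acc = "P1", e = NULL) {
  n <- length(masses)
  data.frame(condition = conds, replicate = reps,
             spectrum_id = sprintf("R%03d", seq_len(n)),
             protein_accession = rep(acc, length.out = n),
             precursor_mass = masses,
             e_value = if (is.null(e)) 10^-(seq_len(n) + 3) else e,
             abundance = abund, stringsAsFactors = FALSE)
}

test_that("cross-run matching groups by protein and mass window", {
  # one proteoform seen in all six runs: one row, six cells
  prof <- make_profiles(rep(12000, 6) + rnorm(6, 0, 0.01),
                        abund = 101:106,
                        conds = rep(c("A", "B"), each = 3),
                        reps = rep(1:3, 2))
  qm <- match_across_runs(prof)
  expect_equal(dim(qm), c(1L, 6L))
  expect_equal(sort(as.vector(qm$abundance)), 101:106)

  # two proteoforms 10 Da apart: two rows
  prof2 <- make_profiles(c(12000, 12010), abund = c(1, 2),
                         conds = c("A", "A"), reps = c(1, 2))
  expect_equal(nrow(match_across_runs(prof2)$abundance), 2L)

  # two in-tolerance members from one run: the larger abundance wins
  prof3 <- make_profiles(c(12000, 12001), abund = c(2000, 1500),
                         conds = c("A", "A"), reps = c(1, 1))
  expect_equal(as.vector(match_across_runs(prof3)$abundance), 2000)
})

test_that("complete-case filter keeps only fully observed rows", {
  ab <- rbind(c(1, 2, 3, 4, 5, 6), c(1, NA, 3, 4, 5, 6))
  qm <- quant_matrix(ab, rows = data.frame(protein_accession = c("P1", "P2"),
                                           precursor_mass = c(1, 2)),
                     design = data.frame(condition = rep(c("A", "B"), each = 3),
                                         replicate = rep(1:3, 2)))
  expect_equal(nrow(complete_case_filter(qm)$abundance), 1L)
  empty <- quant_matrix(ab[0, , drop = FALSE],
                        rows = data.frame(protein_accession = character(0),
                                          precursor_mass = numeric(0)),
                        design = qm$design)
  expect_equal(nrow(complete_case_filter(empty)$abundance), 0L)
})

ref_qm <- function(ab) {
  quant_matrix(ab,
               rows = data.frame(protein_accession = paste0("P", seq_len(nrow(ab))),
                                 precursor_mass = seq_len(nrow(ab))),
               design = data.frame(condition = rep(c("A", "B"), each = 3),
                                   replicate = rep(1:3, 2)))
}

test_that("normalization: reference ratio, unit column medians, log2", {
  set.seed(5)
  base <- 2^matrix(rnorm(60, 20, 2), 10, 6)
  # all columns identical to the reference: all-zero log2 matrix
  same <- ref_qm(matrix(base[, 1], 10, 6))
  expect_true(all(normalize_quant(same)$abundance == 0))

  # a column at twice the reference collapses to zero after median centering
  ab <- matrix(base[, 1], 10, 6)
  ab[, 3] <- 2 * ab[, 1]
  expect_true(all(abs(normalize_quant(ref_qm(ab))$abundance[, 3]) < 1e-12))

  # post-condition: every column median of the pre-log ratio matrix is 1
  norm <- normalize_quant(ref_qm(base))
  expect_equal(unname(apply(2^norm$abundance, 2, median)), rep(1, 6))

  # zero reference cell: row dropped with a warning
  bad <- base; bad[4, 1] <- 0
  expect_warning(out <- normalize_quant(ref_qm(bad)), "dropped")
  expect_equal(nrow(out$abundance), 9L)
})

test_that("normalization is scale-equivariant in every input column", {
  set.seed(6)
  base <- 2^matrix(rnorm(48, 18, 1.5), 8, 6)
  ref <- normalize_quant(ref_qm(base))$abundance
  for (j in c(1, 4)) {
    scaled <- base
    scaled[, j] <- scaled[, j] * 7.3
    expect_equal(normalize_quant(ref_qm(scaled))$abundance, ref,
                 tolerance = 1e-12)
  }
})

test_that("spiked log2 fold changes are recovered through the full quant chain", {
  errs <- c()
  for (seed in 1:20) {
    cfg <- sim_config(n_proteins = 25L, proteoforms_per_protein = 0.5,
                      true_hit_fraction = 1, isotope_error_prob = 0,
                      detect_logistic_params = c(midpoint = -50, slope = 1),
                      n_differential = 6L, fold_changes = c(-2, -1, 1, 2),
                      n_saav_proteoforms = 0L, seed = seed)
    truth <- simulate_truth_set(cfg, simulate_reference_proteome(cfg))
    tab <- simulate_prsm_tables(cfg, truth)
    qm <- complete_case_filter(match_across_runs(replicate_profiles(tab)))
    norm <- normalize_quant(qm)
    m <- norm$abundance
    fc <- rowMeans(m[, 1:3, drop = FALSE]) - rowMeans(m[, 4:6, drop = FALSE])
    # map quant rows to truth by protein + mass
    reg <- truth$registry
    hit <- vapply(seq_len(nrow(norm$rows)), function(i) {
      j <- which(reg$protein_accession == norm$rows$protein_accession[i] &
                   abs(reg$mass - norm$rows$precursor_mass[i]) <= 2.2)
      if (length(j) == 1L) j else NA_integer_
    }, 1L)
    ok <- !is.na(hit) & reg$differential[hit]
    # condition 1 minus condition 2, truth spikes condition 2 by delta
    errs <- c(errs, fc[ok] - (-reg$log2_fc_true[hit[ok]]))
  }
  expect_gt(length(errs), 40)
  se <- sd(errs) / sqrt(length(errs))
  expect_lt(abs(mean(errs)), max(3 * se, 0.05))
})

test_that("reproducibility metrics: correlations and CVs behave as defined", {
  ab <- matrix(rep(2^c(10, 11, 12, 13), 3), 4, 3)
  qm <- quant_matrix(ab, rows = data.frame(protein_accession = paste0("P", 1:4),
                                           precursor_mass = 1:4),
                     design = data.frame(condition = c("A", "A", "A"),
                                         replicate = 1:3))
  met <- reproducibility_metrics(qm)
  expect_true(all(met$pearson == 1))
  expect_equal(unname(met$cv[, "A"]), rep(0, 4))

  # a negated column on the log2 scale anti-correlates exactly
  lm2 <- cbind(c(-1, 0, 2, 3), -c(-1, 0, 2, 3))
  qml <- quant_matrix(lm2, rows = data.frame(protein_accession = paste0("P", 1:4),
                                             precursor_mass = 1:4),
                      design = data.frame(condition = c("A", "A"),
                                          replicate = 1:2), log2 = TRUE)
  expect_equal(reproducibility_metrics(qml)$pearson[1, 2], -1)

  # constant column: undefined correlation reported as missing
  con <- quant_matrix(cbind(c(1, 1, 1, 1), c(1, 2, 3, 4)),
                      rows = data.frame(protein_accession = paste0("P", 1:4),
                                        precursor_mass = 1:4),
                      design = data.frame(condition = c("A", "A"),
                                          replicate = 1:2), log2 = TRUE)
  expect_true(is.na(reproducibility_metrics(con)$pearson[1, 2]))
})
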