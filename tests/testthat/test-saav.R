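test_that("variant entries differ from the reference at exactly one position", {
  seqs <- c(P1 = paste(rep("ACDEFGHIKL", 10), collapse = ""))
  v <- data.frame(protein_accession = "P1", position = 72L,
                  ref_aa = "C", alt_aa = "R")
  db <- apply_variants(seqs, v)
  expect_length(db, 2L)
  expect_true("P1_C72R" %in% names(db))
  diff_pos <- which(strsplit(db[["P1"]], "")[[1]] !=
                      strsplit(db[["P1_C72R"]], "")[[1]])
  expect_equal(diff_pos, 72L)
  expect_equal(substr(db[["P1_C72R"]], 72, 72), "R")

  expect_identical(apply_variants(seqs, v[0, ]), seqs)

  # two variants on one protein yield two separate single-variant entries
  v2 <- rbind(v, data.frame(protein_accession = "P1", position = 3L,
                            ref_aa = "D", alt_aa = "N"))
  db2 <- apply_variants(seqs, v2)
  expect_length(db2, 3L)
  expect_equal(substr(db2[["P1_D3N"]], 72, 72), "C")

  bad <- data.frame(protein_accession = "P1", position = 72L,
                    ref_aa = "W", alt_aa = "R")
  expect_error(apply_variants(seqs, bad), "W72R")
})

test_that("b/y fragment masses: hand sums, cardinality and fixed cysteine mod", {
  fr <- theoretical_fragments("GG")
  expect_equal(fr$mass[fr$ion == "b" & fr$index == 1], 57.02146)
  expect_equal(fr$mass[fr$ion == "y" & fr$index == 1], 75.032025,
               tolerance = 1e-6)

  s <- "ACDEFGHIKLMNPQRSTVWY"
  fr <- theoretical_fragments(s)
  expect_equal(nrow(fr), 2 * (nchar(s) - 1))

  # every fragment containing the cysteine carries +57.02146
  with_c <- theoretical_fragments("ACG")
  no_c <- theoretical_fragments("AAG")
  b2_delta <- with_c$mass[with_c$ion == "b" & with_c$index == 2] -
    no_c$mass[no_c$ion == "b" & no_c$index == 2]
  expect_equal(b2_delta, 103.00919 + 57.02146 - 71.03711, tolerance = 1e-6)
  expect_error(theoretical_fragments("AXZ"), "unknown residue")
})

test_that("complementary fragments reconstruct the precursor mass exactly", {
  set.seed(59)
  aa <- names(AA_MONO)
  for (i in 1:10) {
    s <- paste(sample(aa, sample(8:30, 1), replace = TRUE), collapse = "")
    fr <- theoretical_fragments(s, fixed_cys = FALSE)
    n <- nchar(s)
    M <- sum(AA_MONO[strsplit(s, "")[[1]]]) + 18.010565
    b <- fr$mass[fr$ion == "b"][order(fr$index[fr$ion == "b"])]
    y <- fr$mass[fr$ion == "y"][order(fr$index[fr$ion == "y"])]
    for (k in seq_len(n - 1)) {
      expect_equal(b[k] + y[n - k], M, tolerance = 1e-9)
    }
  }
})

test_that("localized modifications are added only to fragments containing their span", {
  mods <- data.frame(start = 3L, end = 4L, mass = 79.96633)
  fr <- theoretical_fragments("AAAAAA", named_mods = mods)
  b <- fr[fr$ion == "b", ]
  expect_equal(b$mass[b$index == 2] - 2 * 71.03711, 0, tolerance = 1e-6)
  expect_equal(b$mass[b$index == 4] - 4 * 71.03711, 79.96633,
               tolerance = 1e-6)
  y <- fr[fr$ion == "y", ]
  # y_2 spans residues 5..6: unmodified; y_4 spans 3..6: modified
  expect_equal(y$mass[y$index == 2] - (2 * 71.03711 + 18.010565), 0,
               tolerance = 1e-6)
  expect_equal(y$mass[y$index == 4] - (4 * 71.03711 + 18.010565), 79.96633,
               tolerance = 1e-6)
})

test_that("ppm matching is symmetric and finds jittered fragments", {
  fr <- theoretical_fragments("ACDEFGHIKLMNPQRSTVWY")
  obs <- fr$mass * (1 + runif(nrow(fr), -14.9e-6, 14.9e-6))
  expect_true(all(match_fragments(fr, obs, tol_ppm = 15)))
  expect_false(any(match_fragments(fr, obs * (1 + 1e-4), tol_ppm = 15)))
  expect_error(match_fragments(fr, obs, tol_ppm = 0), "tol_ppm")
})

test_that("the flanking-ion threshold separates confident from tentative SAAV calls", {
  s <- paste(rep("ADGKLNPQRSTV", 3), collapse = "")  # 36 residues
  fr <- theoretical_fragments(s)
  site <- 5L; interval <- c(15L, 20L)
  flanking <- fr[fr$cleavage >= site & fr$cleavage < interval[1], ]

  # no unexpected shift: confident regardless of fragment evidence
  out <- saav_confidence_filter(fr, numeric(0), site, NULL)
  expect_true(out$confident)
  expect_true(is.na(out$flanking_counts[[1]]))

  # exactly two flanking matches with a shift present: not confident
  out2 <- saav_confidence_filter(fr, flanking$mass[1:2], site, interval)
  expect_false(out2$confident)
  expect_equal(unname(out2$flanking_counts), 2L)

  # three flanking matches: confident
  out3 <- saav_confidence_filter(fr, flanking$mass[1:3], site, interval)
  expect_true(out3$confident)

  # matches outside the site-shift corridor do not count
  outside <- fr[fr$cleavage >= interval[2], ]
  out4 <- saav_confidence_filter(fr, outside$mass[1:5], site, interval)
  expect_false(out4$confident)
  expect_equal(unname(out4$flanking_counts), 0L)

  # a site inside the shift interval has no flanking corridor at all
  out5 <- saav_confidence_filter(fr, fr$mass, 17L, interval)
  expect_false(out5$confident)
})

test_that("b and y species at one cleavage count individually", {
  s <- paste(rep("ADGKLNPQRSTV", 3), collapse = "")
  fr <- theoretical_fragments(s)
  site <- 5L; interval <- c(15L, 20L)
  # both ion species at cleavages 5, 6: four ions from two cleavage sites
  two_cleavages <- fr[fr$cleavage %in% c(5L, 6L), ]
  expect_equal(nrow(two_cleavages), 4L)
  out <- saav_confidence_filter(fr, two_cleavages$mass, site, interval)
  expect_equal(unname(out$flanking_counts), 4L)
  expect_true(out$confident)
})

test_that("simulated fragment data round-trips: recount matches recorded truth", {
  cfg <- small_cfg(seed = 29, fragment_coverage_prob = 0.5)
  truth <- simulate_truth_set(cfg, simulate_reference_proteome(cfg))
  frag <- simulate_fragment_data(truth, cfg)
  reg <- truth$registry[!is.na(truth$registry$saav_core), ]
  expect_equal(nrow(frag$verdicts), nrow(reg))
  for (i in seq_len(nrow(reg))) {
    p <- parse_proteoform(reg$proteoform[i])
    theo <- theoretical_fragments(p$core_sequence, p$named_mods)
    obs <- frag$observed$mass[frag$observed$proteoform_id ==
                                reg$proteoform_id[i]]
    if (is.na(reg$shift_start[i])) {
      expect_true(frag$verdicts$confident[i])
      next
    }
    # independent recount: match emitted masses back at 15 ppm and count
    # cleavages strictly between the site and the nearer shift boundary
    matched <- theo[match_fragments(theo, obs, 15), ]
    a <- reg$shift_start[i]; b <- reg$shift_end[i]; p0 <- reg$saav_core[i]
    rng <- if (p0 < a) p0:(a - 1) else if (p0 > b) b:(p0 - 1) else integer(0)
    cnt <- sum(matched$cleavage %in% rng)
    expect_equal(frag$flanking$flanking_count[i], cnt)
    expect_equal(frag$verdicts$confident[i], cnt >= 3)
  }
})

test_that("fragment coverage bounds: all retained at 1, none at 0", {
  cfg1 <- small_cfg(seed = 37, fragment_coverage_prob = 1)
  truth <- simulate_truth_set(cfg1, simulate_reference_proteome(cfg1))
  frag1 <- simulate_fragment_data(truth, cfg1)
  reg <- truth$registry[!is.na(truth$registry$saav_core), ]
  n_theo <- sum(vapply(reg$proteoform, function(s)
    2L * (nchar(parse_proteoform(s)$core_sequence) - 1L), 1L))
  expect_equal(nrow(frag1$observed), n_theo)
  # with full coverage and sub-tolerance jitter, everything re-matches
  for (i in seq_len(nrow(reg))) {
    p <- parse_proteoform(reg$proteoform[i])
    theo <- theoretical_fragments(p$core_sequence, p$named_mods)
    obs <- frag1$observed$mass[frag1$observed$proteoform_id ==
                                 reg$proteoform_id[i]]
    expect_true(all(match_fragments(theo, obs, 15)))
  }

  cfg0 <- small_cfg(seed = 37, fragment_coverage_prob = 0)
  frag0 <- simulate_fragment_data(truth, cfg0)
  expect_equal(nrow(frag0$observed), 0L)
})
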