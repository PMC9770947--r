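test_that("proteoform grammar parses flanks, named mods and shifts", {
  p <- parse_proteoform("A.GGK.R")
  expect_equal(p$prefix_residue, "A")
  expect_equal(p$suffix_residue, "R")
  expect_equal(p$core_sequence, "GGK")
  expect_equal(nrow(p$named_mods), 0L)
  expect_equal(nrow(p$unexpected_shifts), 0L)

  p <- parse_proteoform("M.(A)[acetyl]ASAK.S")
  expect_equal(p$core_sequence, "AASAK")
  expect_equal(p$named_mods$name, "acetyl")
  expect_equal(p$named_mods$start, 1L)
  expect_equal(p$named_mods$end, 1L)
  expect_equal(p$named_mods$mass, 42.01057)

  # shift group with span coordinates on the core
  p <- parse_proteoform("M.AB(CDE) (mass shift: 96 Da, phospho and oxidation)FG.K")
  expect_equal(p$core_sequence, "ABCDEFG")
  expect_equal(p$unexpected_shifts$start, 3L)
  expect_equal(p$unexpected_shifts$end, 5L)
  expect_equal(p$unexpected_shifts$mass, 96)
})

test_that("published-style proteoform strings parse as printed", {
  tab <- read.delim(system.file("extdata", "selected_proteoforms.tsv",
                                package = "proteoforma"))
  # the MARK2 proteoform: exactly one acetyl plus one 96-Da shift
  mark2 <- parse_proteoform(tab$proteoform[tab$gene == "MARK2"])
  expect_equal(nrow(mark2$named_mods), 1L)
  expect_equal(mark2$named_mods$name, "acetyl")
  expect_equal(nrow(mark2$unexpected_shifts), 1L)
  expect_equal(mark2$unexpected_shifts$mass, 96)
  # loose "(C) (carbamidomethylation)" typography is accepted as a named mod
  eif <- parse_proteoform(tab$proteoform[5])
  expect_equal(sum(grepl("carbamidomethyl", eif$named_mods$name)), 2L)
  expect_equal(eif$unexpected_shifts$mass, 81)
  # every bundled string parses
  expect_length(lapply(tab$proteoform, parse_proteoform), nrow(tab))
})

test_that("parse and format are mutual inverses on random proteoforms", {
  set.seed(21)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:40) {
    n <- sample(10:60, 1)
    core <- paste(sample(aa, n, replace = TRUE), collapse = "")
    mods <- data.frame(start = integer(0), end = integer(0),
                       name = character(0), mass = numeric(0),
                       stringsAsFactors = FALSE)
    shifts <- data.frame(start = integer(0), end = integer(0),
                         mass = numeric(0), annotation = character(0),
                         stringsAsFactors = FALSE)
    if (runif(1) < 0.5) {
      mods <- data.frame(start = 1L, end = 1L, name = "acetyl",
                         mass = 42.01057, stringsAsFactors = FALSE)
    }
    if (runif(1) < 0.5 && n >= 12) {
      a <- sample(3:(n - 6), 1)
      shifts <- data.frame(start = a, end = a + 3L,
                           mass = round(runif(1, 10, 300), 5),
                           annotation = "unknown", stringsAsFactors = FALSE)
    }
    p <- structure(list(
      prefix_residue = if (runif(1) < 0.5) sample(aa, 1) else NA_character_,
      suffix_residue = if (runif(1) < 0.5) sample(aa, 1) else NA_character_,
      core_sequence = core, named_mods = mods, unexpected_shifts = shifts),
      class = "parsed_proteoform")
    expect_identical(parse_proteoform(format_proteoform(p)), p)
  }
})

test_that("parser rejects malformed strings with positions", {
  expect_error(parse_proteoform("M.AB(CD.K"), "unbalanced")
  expect_error(parse_proteoform("M.AB(CD)EF.K"), "annotation")
  expect_error(parse_proteoform("M.AB1CD.K"), "unexpected character")
  expect_error(
    parse_proteoform(
      "M.(A) (mass shift: 5 Da, x)B(C) (mass shift: 6 Da, y)D.K"),
    "unexpected mass shifts")
})

test_that("PrSM table round-trips and rejects bad rows", {
  cfg <- small_cfg(seed = 3)
  truth <- simulate_truth_set(cfg, simulate_reference_proteome(cfg))
  tab <- simulate_prsm_tables(cfg, truth)[1:50, ]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_prsm_table(tab, path)
  back <- read_prsm_table(path)
  expect_equal(back[names(back) != "truth"],
               tab[!names(tab) %in% c("truth", "proteoform_id")],
               tolerance = 1e-12)

  # empty table with header
  writeLines(paste(c("spectrum_id", "condition", "replicate", "fraction",
                     "protein_accession", "proteoform", "start_pos",
                     "end_pos", "precursor_mass", "e_value", "intensity",
                     "charge", "migration_time"), collapse = "\t"), path)
  expect_equal(nrow(read_prsm_table(path)), 0L)

  # zero E-value rejected with a count
  bad <- tab[1:2, ]
  bad$e_value[1] <- 0
  write_prsm_table(bad, path)
  expect_message(got <- read_prsm_table(path), "rejected")
  expect_equal(nrow(got), 1L)

  # missing mandatory column named in the error
  write.table(tab[, setdiff(names(tab), "e_value")], path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_error(read_prsm_table(path), "e_value")
})

test_that("core length agrees with start/end coordinates in simulated truth", {
  cfg <- small_cfg(seed = 5)
  truth <- simulate_truth_set(cfg, simulate_reference_proteome(cfg))
  reg <- truth$registry
  cores <- vapply(reg$proteoform,
                  function(s) nchar(parse_proteoform(s)$core_sequence), 1L)
  expect_equal(unname(cores), reg$end - reg$start + 1L)
})

test_that("FASTA round-trips through Biostrings with decoy prefixes intact", {
  cfg <- small_cfg(seed = 2)
  pro <- simulate_reference_proteome(cfg)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(pro, path)
  back <- read_fasta(path)
  expect_identical(back, pro)
  expect_equal(sum(startsWith(names(back), "DECOY_")), cfg$n_proteins)
})
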