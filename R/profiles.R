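#' Pairwise proteoform overlap matrix
#'
#' For named proteoform-key sets (typically the proteoforms identified in
#' each run or condition, canonicalized so the same proteoform carries the
#' same key everywhere), the overlap of set A (x axis) against set B (y
#' axis) is the number of shared proteoforms divided by the total number of
#' proteoforms identified in B. The matrix is asymmetric in general and its
#' diagonal is 1 for non-empty sets.
#'
#' @param sets named list of character vectors of proteoform keys.
#' @return numeric matrix with y-axis sets as rows and x-axis sets as
#'   columns; cells are ratios in \[0, 1\], `NA` where the denominator set
#'   is empty.
#' @export
overlap_matrix <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  labs <- names(sets)
  m <- matrix(NA_real_, length(labs), length(labs),
              dimnames = list(y = labs, x = labs))
  for (b in labs) {
    if (length(sets[[b]]) == 0L) next
    for (a in labs) {
      m[b, a] <- length(intersect(unique(sets[[a]]), unique(sets[[b]]))) /
        length(unique(sets[[b]]))
    }
  }
  m
}

# census bins: monoisotopic centers of the nominal mass-shift categories
PTM_BINS <- data.frame(
  category = c("N-terminal acetylation/trimethylation (+42)",
               "phosphorylation (+80)",
               "double phosphorylation (+160)",
               "methylation (+14)",
               "oxidation (+16)",
               "acetylation + phosphorylation (+122)",
               "phosphorylation + oxidation (+96)",
               "acetylation/trimethylation + oxidation (+58)"),
  center = c(42.01057, 79.96633, 159.93266, 14.01565, 15.99491,
             121.97690, 95.96124, 58.00548),
  nterm = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
  stringsAsFactors = FALSE
)

#' PTM census over parsed proteoforms
#'
#' Assigns each modified proteoform to at most one nominal mass-shift
#' category by the total modification mass it carries — the sum of its named
#' modification masses and unexpected shifts. Carbamidomethylation, a fixed
#' search modification rather than a biological PTM, is excluded from the
#' total. The categories are the nominal bins used for proteoform-level PTM
#' profiling: +42 (N-terminal acetylation, isobaric with trimethylation at
#' this resolution), +80 and +160 (single/double phosphorylation), +14
#' (methylation), +16 (oxidation), and the combination bins +122
#' (acetyl + phospho), +96 (phospho + oxidation) and +58 (acetyl/trimethyl +
#' oxidation). A proteoform is assigned to the nearest bin center within
#' `tol` Da; the +42 bin additionally requires a modification span that
#' includes core position 1 (N-terminus). Modified proteoforms that fit no
#' bin are counted as unassigned; unmodified proteoforms are tallied
#' separately.
#'
#' @param proteoforms list of [parse_proteoform()] results.
#' @param tol bin half-width in Da; must be positive (default 1.5 —
#'   proteoform-level deconvolution errors make shift annotations nominal).
#' @return data.frame with `category` and `count`, including `unassigned`
#'   and `unmodified` rows; the tolerance is attached as attribute `tol`.
#' @export
ptm_census <- function(proteoforms, tol = 1.5) {
  if (!is.numeric(tol) || length(tol) != 1L || tol <= 0) {
    stop("tol must be a single positive number", call. = FALSE)
  }
  counts <- stats::setNames(integer(nrow(PTM_BINS)), PTM_BINS$category)
  unassigned <- 0L; unmodified <- 0L
  for (p in proteoforms) {
    stopifnot(inherits(p, "parsed_proteoform"))
    mods <- p$named_mods[!grepl("^carbamidomethyl", p$named_mods$name,
                                ignore.case = TRUE), , drop = FALSE]
    total <- sum(mods$mass, na.rm = TRUE) + sum(p$unexpected_shifts$mass)
    if (abs(total) < .Machine$double.eps^0.5 &&
        nrow(mods) == 0L && nrow(p$unexpected_shifts) == 0L) {
      unmodified <- unmodified + 1L
      next
    }
    dists <- abs(total - PTM_BINS$center)
    ok <- dists <= tol
    if (!any(ok)) { unassigned <- unassigned + 1L; next }
    best <- which.min(replace(dists, !ok, Inf))
    if (PTM_BINS$nterm[best]) {
      spans_nterm <- any(mods$start == 1L) ||
        any(p$unexpected_shifts$start == 1L)
      if (!spans_nterm) { unassigned <- unassigned + 1L; next }
    }
    counts[best] <- counts[best] + 1L
  }
  out <- rbind(
    data.frame(category = PTM_BINS$category, count = as.integer(counts),
               stringsAsFactors = FALSE),
    data.frame(category = c("unassigned", "unmodified"),
               count = c(unassigned, unmodified), stringsAsFactors = FALSE)
  )
  attr(out, "tol") <- tol
  out
}

#' Proteoform family summary for one gene
#'
#' Summarizes the proteoforms of a single gene: the histogram of start
#' positions, each proteoform's share of the family's PrSM count (a rough
#' relative-abundance estimate), and the intact/truncated split. A
#' proteoform is called intact when it covers the full mature sequence:
#' start position at most `intact_start_max` (2 by default, allowing
#' N-terminal methionine removal) and end position equal to the protein
#' length.
#'
#' @param proteoforms data.frame with `start_pos`, `end_pos`, `prsm_count`
#'   and optionally a `key` column.
#' @param protein_length length of the reference protein in residues.
#' @param intact_start_max largest start position still counted as intact.
#' @return list with `start_counts` (named integer vector over observed
#'   start positions), `shares` (per-proteoform PrSM share, same order as
#'   input), `intact` (logical vector), and `n` (number of proteoforms).
#'   Empty input yields an empty summary.
#' @export
family_summary <- function(proteoforms, protein_length,
                           intact_start_max = 2L) {
  stopifnot(is.data.frame(proteoforms))
  if (nrow(proteoforms) == 0L) {
    return(list(start_counts = integer(0), shares = numeric(0),
                intact = logical(0), n = 0L))
  }
  stopifnot(all(c("start_pos", "end_pos", "prsm_count") %in%
                  names(proteoforms)))
  tab <- table(proteoforms$start_pos)
  start_counts <- stats::setNames(as.integer(tab), names(tab))
  total <- sum(proteoforms$prsm_count)
  shares <- if (total > 0) proteoforms$prsm_count / total else
    rep(NA_real_, nrow(proteoforms))
  intact <- proteoforms$start_pos <= intact_start_max &
    proteoforms$end_pos == protein_length
  list(start_counts = start_counts, shares = shares, intact = intact,
       n = nrow(proteoforms))
}

#' Mean and sample standard deviation
#'
#' The mean +/- SD summary used throughout reporting; the SD uses the n-1
#' denominator and is `NA` for a single value.
#'
#' @param values numeric vector; must be non-empty.
#' @return list with `mean` and `sd`.
#' @export
mean_sd <- function(values) {
  if (!is.numeric(values) || length(values) == 0L) {
    stop("values must be a non-empty numeric vector", call. = FALSE)
  }
  list(mean = mean(values),
       sd = if (length(values) >= 2L) stats::sd(values) else NA_real_)
}
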