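#' Construct a quant_matrix
#'
#' Container for the proteoform x run abundance table used by the label-free
#' quantification stages: an abundance matrix (rows are proteoforms keyed by
#' protein and cluster mass, columns are condition x replicate runs), row
#' metadata, and the design table.
#'
#' @param abundance numeric matrix, proteoforms x runs; `NA` marks a
#'   proteoform not measured in a run.
#' @param rows data.frame of row metadata (at least `protein_accession` and
#'   `precursor_mass`), one row per matrix row.
#' @param design data.frame with `condition` and `replicate`, one row per
#'   matrix column.
#' @param log2 whether the cells are log2-transformed ratios (set by
#'   [normalize_quant()]).
#' @return an object of class `quant_matrix`.
#' @export
quant_matrix <- function(abundance, rows, design, log2 = FALSE) {
  stopifnot(is.matrix(abundance), nrow(rows) == nrow(abundance),
            nrow(design) == ncol(abundance),
            all(c("condition", "replicate") %in% names(design)))
  if (!log2 && any(abundance < 0, na.rm = TRUE)) {
    stop("abundances must be non-negative", call. = FALSE)
  }
  colnames(abundance) <- paste(design$condition, design$replicate, sep = "_")
  structure(list(abundance = abundance, rows = rows, design = design,
                 log2 = log2), class = "quant_matrix")
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("quant_matrix: %d proteoforms x %d runs (%s)\n",
              nrow(x$abundance), ncol(x$abundance),
              if (x$log2) "log2 ratios" else "raw abundances"))
  cat("runs:", paste(colnames(x$abundance), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.quant_matrix <- function(x) dim(x$abundance)

#' @export
as.matrix.quant_matrix <- function(x, ...) x$abundance

#' Sum fraction-level intensities into per-replicate abundances
#'
#' The abundance of a proteoform in one replicate is the sum of its feature
#' intensities over the fractions of that replicate. Within one fraction,
#' duplicate records of the same proteoform are resolved by the maximum
#' intensity (conservative against double counting). Fractions in which the
#' proteoform was not observed contribute zero; a proteoform with no
#' measured intensity in any fraction gets a missing abundance (`NA`, not
#' 0).
#'
#' @param records data.frame of PrSM records for a single condition x
#'   replicate (all fractions), carrying a proteoform key column and
#'   `fraction`, `intensity` columns.
#' @param key name of the proteoform key column (default `"cluster_id"`).
#' @return data.frame with the key column and `abundance`.
#' @export
aggregate_fractions <- function(records, key = "cluster_id") {
  stopifnot(is.data.frame(records),
            all(c(key, "fraction", "intensity") %in% names(records)))
  if (any(records$intensity < 0, na.rm = TRUE)) {
    stop("negative intensities are not allowed", call. = FALSE)
  }
  keys <- unique(records[[key]])
  ab <- vapply(keys, function(k) {
    sub <- records[records[[key]] == k, , drop = FALSE]
    per_frac <- tapply(sub$intensity, sub$fraction,
                       function(v) if (all(is.na(v))) NA_real_ else
                         max(v, na.rm = TRUE))
    if (all(is.na(per_frac))) NA_real_ else sum(per_frac, na.rm = TRUE)
  }, numeric(1))
  out <- data.frame(key = keys, abundance = unname(ab),
                    stringsAsFactors = FALSE)
  names(out)[1] <- key
  out
}

#' Per-replicate proteoform profiles
#'
#' Clusters the PrSMs of each condition x replicate independently (same
#' protein, `mass_tol` window, greedy best-E-value seeding) and sums
#' fraction intensities with [aggregate_fractions()], yielding one proteoform
#' list with abundances per replicate — the inputs to cross-run matching.
#'
#' @param prsms merged PrSM records (post spectrum-level FDR, targets).
#' @param mass_tol clustering window in Da.
#' @return data.frame with `condition`, `replicate`, representative
#'   `spectrum_id`, `protein_accession`, `precursor_mass`, `e_value`,
#'   `abundance`.
#' @export
replicate_profiles <- function(prsms, mass_tol = 2.2) {
  runs <- unique(prsms[, c("condition", "replicate")])
  runs <- runs[order(runs$condition, runs$replicate), , drop = FALSE]
  out <- lapply(seq_len(nrow(runs)), function(i) {
    sub <- prsms[prsms$condition == runs$condition[i] &
                   prsms$replicate == runs$replicate[i], , drop = FALSE]
    cl <- cluster_prsms(sub, mass_tol = mass_tol)
    asg <- cluster_assignment(cl)
    sub$cluster_id <- asg$cluster_id[match(sub$spectrum_id, asg$spectrum_id)]
    ab <- aggregate_fractions(sub, key = "cluster_id")
    rep_df <- representative_set(cl)
    rep_df$abundance <- ab$abundance[match(rep_df$cluster_id, ab$cluster_id)]
    cbind(condition = runs$condition[i], replicate = runs$replicate[i],
          rep_df[, c("spectrum_id", "protein_accession", "precursor_mass",
                     "e_value", "abundance")],
          stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Match proteoforms across runs into a quantification matrix
#'
#' Re-clusters the union of per-replicate proteoform representatives (same
#' protein, `mass_tol` Da, greedy best-E-value seeding) so that the same
#' proteoform observed in different replicates lands in one matrix row. Each
#' run contributes at most one abundance per row; if several of its
#' representatives fall in the same union cluster, the largest abundance is
#' used.
#'
#' @param profiles result of [replicate_profiles()].
#' @param mass_tol matching window in Da (default: the same 2.2 Da used for
#'   PrSM clustering).
#' @return a [quant_matrix()] of raw abundances.
#' @export
match_across_runs <- function(profiles, mass_tol = 2.2) {
  stopifnot(is.data.frame(profiles),
            all(c("condition", "replicate", "spectrum_id",
                  "protein_accession", "precursor_mass", "e_value",
                  "abundance") %in% names(profiles)))
  profiles$is_decoy <- rep(FALSE, nrow(profiles))
  cl <- cluster_prsms(profiles, mass_tol = mass_tol)
  asg <- cluster_assignment(cl)
  profiles$row_key <- asg$cluster_id[match(profiles$spectrum_id,
                                           asg$spectrum_id)]
  design <- unique(profiles[, c("condition", "replicate")])
  design <- design[order(design$condition, design$replicate), , drop = FALSE]
  rownames(design) <- NULL
  ab <- matrix(NA_real_, nrow = nrow(cl), ncol = nrow(design))
  for (j in seq_len(nrow(design))) {
    sub <- profiles[profiles$condition == design$condition[j] &
                      profiles$replicate == design$replicate[j], ,
                    drop = FALSE]
    cell <- tapply(sub$abundance, factor(sub$row_key, levels = cl$cluster_id),
                   function(v) if (all(is.na(v))) NA_real_ else
                     max(v, na.rm = TRUE))
    ab[, j] <- as.numeric(cell)
  }
  rows <- as.data.frame(cl)[, c("cluster_id", "protein_accession",
                                "precursor_mass", "e_value", "proteoform",
                                "n_prsms")]
  rownames(rows) <- NULL
  quant_matrix(ab, rows = rows, design = design)
}

#' Keep proteoforms measured in every run
#'
#' Retains matrix rows with no missing cells — the "measured intensities in
#' all samples" filter applied before normalization and testing.
#'
#' @param qm a [quant_matrix()].
#' @return the filtered `quant_matrix`.
#' @export
complete_case_filter <- function(qm) {
  stopifnot(inherits(qm, "quant_matrix"))
  keep <- rowSums(is.na(qm$abundance)) == 0L
  quant_matrix(qm$abundance[keep, , drop = FALSE],
               qm$rows[keep, , drop = FALSE], qm$design, log2 = qm$log2)
}

#' Reference-ratio and median normalization with log2 transform
#'
#' Three steps, in order: (1) every cell is divided by the same-row cell of
#' the reference run, converting intensities to ratios; (2) every column is
#' divided by its median so that ratios center at 1 (the median of an
#' even-length column is the mean of the central order statistics); (3) all
#' cells are log2-transformed. After step 2 every column of the pre-log
#' ratio matrix has median exactly 1. Rows whose reference cell is zero are
#' dropped with a warning. The input must be complete-case (no missing
#' cells).
#'
#' @param qm a complete-case [quant_matrix()] of raw abundances.
#' @param reference column to normalize against: an index or a column name
#'   such as `"SW480_1"`; defaults to the first run of the first condition.
#' @return a `quant_matrix` of log2 ratios (`log2 = TRUE`).
#' @export
normalize_quant <- function(qm, reference = 1L) {
  stopifnot(inherits(qm, "quant_matrix"), !qm$log2)
  ab <- qm$abundance
  if (any(is.na(ab))) {
    stop("normalize_quant requires a complete-case matrix; apply complete_case_filter first",
         call. = FALSE)
  }
  if (is.character(reference)) {
    reference <- match(reference, colnames(ab))
    if (is.na(reference)) stop("reference run not found", call. = FALSE)
  }
  ref <- ab[, reference]
  drop <- ref == 0
  if (any(drop)) {
    warning(sum(drop), " row(s) dropped: zero abundance in the reference run")
    ab <- ab[!drop, , drop = FALSE]
    ref <- ref[!drop]
  }
  rows <- qm$rows[!drop, , drop = FALSE]
  ratio <- ab / ref
  med <- apply(ratio, 2L, stats::median)
  ratio <- sweep(ratio, 2L, med, "/")
  quant_matrix(log2(ratio), rows = rows, design = qm$design, log2 = TRUE)
}

#' Replicate reproducibility metrics
#'
#' Pairwise Pearson correlations between runs on the log2 abundance scale,
#' and per-proteoform coefficients of variation (sample SD divided by mean,
#' on the raw abundance scale) within each condition. Correlations involving
#' a constant column are reported as `NA`.
#'
#' @param qm a [quant_matrix()] of raw abundances.
#' @return list with `pearson` (run x run matrix, computed on log2
#'   abundances, complete pairwise observations) and `cv` (proteoform x
#'   condition matrix).
#' @export
reproducibility_metrics <- function(qm) {
  stopifnot(inherits(qm, "quant_matrix"))
  if (ncol(qm$abundance) < 2L) stop("need at least two runs", call. = FALSE)
  la <- if (qm$log2) qm$abundance else log2(qm$abundance)
  la[is.infinite(la)] <- NA
  pearson <- suppressWarnings(
    stats::cor(la, use = "pairwise.complete.obs", method = "pearson"))
  pearson[!is.finite(pearson)] <- NA
  conds <- unique(qm$design$condition)
  raw <- if (qm$log2) 2^qm$abundance else qm$abundance
  cv <- sapply(conds, function(cc) {
    sub <- raw[, qm$design$condition == cc, drop = FALSE]
    apply(sub, 1L, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2L || mean(v) == 0) NA_real_ else
        stats::sd(v) / mean(v)
    })
  })
  cv <- matrix(cv, nrow = nrow(raw), dimnames = list(NULL, conds))
  list(pearson = pearson, cv = cv)
}
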