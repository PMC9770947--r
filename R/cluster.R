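#' Cluster PrSMs into proteoforms
#'
#' Merges spectrum-level identifications from all runs into proteoform
#' clusters: PrSMs belong to the same cluster when they match the same
#' protein and their neutral precursor masses differ by at most `mass_tol`
#' Da (default 2.2 Da, a window wide enough to absorb +/-1 and +/-2 Da
#' isotopologue errors from spectral deconvolution).
#'
#' Within each protein the algorithm is greedy best-score seeding: the
#' unassigned PrSM with the lowest E-value (ties broken by lexicographic
#' `spectrum_id`) seeds a cluster and collects every unassigned PrSM of that
#' protein within `mass_tol` of the seed mass. The seed is therefore the
#' cluster representative, every member is within `mass_tol` of it exactly,
#' and the result is independent of input row order. Target and decoy PrSMs
#' are clustered by the identical procedure (their accessions never mix), so
#' decoy clusters remain valid for proteoform-level target-decoy FDR.
#'
#' @param prsms data.frame of PrSM records (normally already filtered at the
#'   spectrum-level FDR); must have `spectrum_id`, `protein_accession`,
#'   `precursor_mass`, `e_value`, `is_decoy`.
#' @param mass_tol clustering window in Da; must be positive.
#' @return a data.frame of class `proteoform_clusters`, one row per cluster:
#'   `cluster_id`, `protein_accession`, `is_decoy`, representative
#'   `spectrum_id` / `e_value` / `precursor_mass` / `proteoform`,
#'   `n_prsms`, `n_runs`, and a `members` list-column of member spectrum
#'   ids.
#' @export
cluster_prsms <- function(prsms, mass_tol = 2.2) {
  stopifnot(is.data.frame(prsms))
  if (!is.numeric(mass_tol) || length(mass_tol) != 1L || mass_tol <= 0) {
    stop("mass_tol must be a single positive number", call. = FALSE)
  }
  need <- c("spectrum_id", "protein_accession", "precursor_mass", "e_value",
            "is_decoy")
  stopifnot(all(need %in% names(prsms)))
  if (anyDuplicated(prsms$spectrum_id)) {
    stop("spectrum_id values must be unique across the merged PrSM set",
         call. = FALSE)
  }
  has_pf <- "proteoform" %in% names(prsms)
  has_run <- all(c("condition", "replicate", "fraction") %in% names(prsms))

  out <- list()
  for (acc in sort(unique(prsms$protein_accession))) {
    sub <- prsms[prsms$protein_accession == acc, , drop = FALSE]
    sub <- sub[order(sub$e_value, sub$spectrum_id), , drop = FALSE]
    unassigned <- rep(TRUE, nrow(sub))
    while (any(unassigned)) {
      seed <- which(unassigned)[1L]
      take <- unassigned &
        abs(sub$precursor_mass - sub$precursor_mass[seed]) <= mass_tol
      members <- sub[take, , drop = FALSE]
      unassigned[take] <- FALSE
      out[[length(out) + 1L]] <- data.frame(
        protein_accession = acc,
        is_decoy = sub$is_decoy[seed],
        spectrum_id = sub$spectrum_id[seed],
        e_value = sub$e_value[seed],
        precursor_mass = sub$precursor_mass[seed],
        proteoform = if (has_pf) sub$proteoform[seed] else NA_character_,
        n_prsms = nrow(members),
        n_runs = if (has_run) {
          nrow(unique(members[, c("condition", "replicate", "fraction")]))
        } else NA_integer_,
        stringsAsFactors = FALSE
      )
      attr(out[[length(out)]], "members") <- members$spectrum_id
    }
  }
  if (!length(out)) {
    res <- data.frame(cluster_id = character(0), protein_accession = character(0),
                      is_decoy = logical(0), spectrum_id = character(0),
                      e_value = numeric(0), precursor_mass = numeric(0),
                      proteoform = character(0), n_prsms = integer(0),
                      n_runs = integer(0), stringsAsFactors = FALSE)
    res$members <- list()
    class(res) <- c("proteoform_clusters", "data.frame")
    return(res)
  }
  members <- lapply(out, attr, "members")
  res <- do.call(rbind, out)
  ord <- order(res$protein_accession, res$e_value, res$spectrum_id)
  res <- res[ord, , drop = FALSE]
  res$members <- lapply(members[ord], sort)
  res <- cbind(cluster_id = sprintf("PF%06d", seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("proteoform_clusters", "data.frame")
  res
}

#' Map PrSMs to their cluster
#'
#' @param clusters result of [cluster_prsms()].
#' @return data.frame with `spectrum_id` and `cluster_id`.
#' @export
cluster_assignment <- function(clusters) {
  stopifnot(inherits(clusters, "proteoform_clusters"))
  data.frame(
    spectrum_id = unlist(clusters$members, use.names = FALSE),
    cluster_id = rep(clusters$cluster_id, lengths(clusters$members)),
    stringsAsFactors = FALSE
  )
}

#' Representative proteoforms of a cluster set
#'
#' One scored item per cluster — the member with the best (minimum) E-value,
#' whose proteoform is reported as the representative of the cluster — ready
#' for proteoform-level FDR filtering with [filter_at_fdr()]. Decoy status is
#' inherited from the cluster.
#'
#' @param clusters result of [cluster_prsms()].
#' @return plain data.frame with one row per cluster (no `members` column).
#' @export
representative_set <- function(clusters) {
  stopifnot(inherits(clusters, "proteoform_clusters"))
  out <- as.data.frame(clusters)[, c("cluster_id", "protein_accession",
                                     "is_decoy", "spectrum_id", "e_value",
                                     "precursor_mass", "proteoform",
                                     "n_prsms", "n_runs")]
  rownames(out) <- NULL
  out
}
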