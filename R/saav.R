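#' Generate variant protein entries
#'
#' Expands a reference protein collection with one additional entry per
#' single amino acid variant: the substituted sequence under an accession
#' suffixed with the variant (e.g. `"P04637_P72R"`). Reference entries are
#' retained, so the result can serve as a sample-specific search database.
#' Every variant is validated against the reference sequence; a mismatch
#' between the stated reference residue and the sequence is an error.
#'
#' @param seqs named character vector of reference sequences.
#' @param variants data.frame with `protein_accession`, `position` (1-based),
#'   `ref_aa`, `alt_aa` (see [read_variant_table()]). Rows whose `ref_aa` or
#'   `alt_aa` is not a single standard residue (e.g. indel notation) are
#'   skipped with a message; only substitutions generate entries.
#' @return named character vector: reference entries followed by variant
#'   entries.
#' @export
apply_variants <- function(seqs, variants) {
  stopifnot(is.character(seqs), !is.null(names(seqs)),
            is.data.frame(variants))
  if (nrow(variants) == 0L) return(seqs)
  need <- c("protein_accession", "position", "ref_aa", "alt_aa")
  stopifnot(all(need %in% names(variants)))
  single <- grepl("^[A-Z]$", variants$ref_aa) &
    grepl("^[A-Z]$", variants$alt_aa)
  if (any(!single)) {
    message(sum(!single), " non-substitution variant(s) skipped")
    variants <- variants[single, , drop = FALSE]
  }
  bad <- character(0)
  out <- character(0)
  for (i in seq_len(nrow(variants))) {
    acc <- variants$protein_accession[i]
    pos <- variants$position[i]
    if (!acc %in% names(seqs) || pos < 1L || pos > nchar(seqs[[acc]]) ||
        substr(seqs[[acc]], pos, pos) != variants$ref_aa[i]) {
      bad <- c(bad, sprintf("%s %s%d%s", acc, variants$ref_aa[i], pos,
                            variants$alt_aa[i]))
      next
    }
    v <- seqs[[acc]]
    substr(v, pos, pos) <- variants$alt_aa[i]
    out[sprintf("%s_%s%d%s", acc, variants$ref_aa[i], pos,
                variants$alt_aa[i])] <- v
  }
  if (length(bad)) {
    stop("variant(s) do not match the reference sequence: ",
         paste(bad, collapse = "; "), call. = FALSE)
  }
  c(seqs, out)
}

#' Theoretical b/y fragment masses
#'
#' Neutral monoisotopic masses of the b and y fragment ion series of a
#' proteoform core sequence (the series produced by collisional
#' dissociation): \eqn{b_k} is the sum of the first k residue masses and
#' \eqn{y_k} the sum of the last k residue masses plus one water
#' (18.010565 Da). Cysteine carbamidomethylation (+57.02146 Da) is applied
#' as a fixed modification. A localized modification is added to a fragment
#' only when the fragment fully contains its span.
#'
#' @param core_sequence residue string (standard amino acids).
#' @param named_mods optional data.frame of localized modifications with
#'   `start`, `end`, `mass` (core coordinates; `NA` masses are ignored).
#' @param fixed_cys apply carbamidomethyl to every cysteine (default TRUE).
#' @return data.frame with `ion` ("b"/"y"), `index` (k), `cleavage` (the
#'   backbone cleavage position: between residues `cleavage` and
#'   `cleavage + 1`), and `mass` in Da; `2 * (n - 1)` rows for an n-residue
#'   sequence.
#' @export
theoretical_fragments <- function(core_sequence, named_mods = NULL,
                                  fixed_cys = TRUE) {
  stopifnot(is.character(core_sequence), length(core_sequence) == 1L,
            nzchar(core_sequence))
  res <- strsplit(core_sequence, "")[[1]]
  bad <- setdiff(res, names(AA_MONO))
  if (length(bad)) {
    stop("unknown residue(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  n <- length(res)
  rm <- unname(AA_MONO[res])
  if (fixed_cys) rm[res == "C"] <- rm[res == "C"] + MOD_MONO[["carbamidomethyl"]]
  if (n == 1L) {
    return(data.frame(ion = character(0), index = integer(0),
                      cleavage = integer(0), mass = numeric(0)))
  }
  csum <- cumsum(rm)
  k <- seq_len(n - 1L)
  b <- csum[k]
  y <- (csum[n] - csum[n - k]) + WATER_MONO
  if (!is.null(named_mods) && nrow(named_mods)) {
    for (i in seq_len(nrow(named_mods))) {
      m <- named_mods$mass[i]
      if (is.na(m)) next
      a <- named_mods$start[i]; e <- named_mods$end[i]
      b[k >= e] <- b[k >= e] + m                 # b_k spans 1..k
      y[(n - k + 1L) <= a] <- y[(n - k + 1L) <= a] + m  # y_k spans n-k+1..n
    }
  }
  data.frame(
    ion = rep(c("b", "y"), each = n - 1L),
    index = c(k, k),
    cleavage = c(k, n - k),
    mass = c(b, y)
  )
}

#' Match observed fragment masses against a theoretical list
#'
#' A theoretical fragment is matched when some observed neutral mass lies
#' within `tol_ppm` parts per million of it.
#'
#' @param theoretical data.frame from [theoretical_fragments()].
#' @param observed numeric vector of observed neutral masses.
#' @param tol_ppm relative tolerance in ppm (default 15).
#' @return logical vector along the rows of `theoretical`.
#' @export
match_fragments <- function(theoretical, observed, tol_ppm = 15) {
  if (!is.numeric(tol_ppm) || length(tol_ppm) != 1L || tol_ppm <= 0) {
    stop("tol_ppm must be a single positive number", call. = FALSE)
  }
  if (length(observed) == 0L) return(rep(FALSE, nrow(theoretical)))
  vapply(theoretical$mass, function(m) {
    any(abs(observed - m) / m * 1e6 <= tol_ppm)
  }, logical(1))
}

#' SAAV proteoform confidence filter
#'
#' A proteoform carrying single amino acid variant (SAAV) sites is reported
#' as a confident identification when it contains no unexpected mass shift,
#' or when every SAAV site is supported by at least `min_ions` matched
#' fragment ions lying between the site and the unexpected shift: a matched
#' fragment counts as flanking a site when its backbone cleavage position is
#' strictly between the variant residue and the nearer boundary of the
#' shift's localization interval. An unlocalized shift or a site inside the
#' shift interval has no flanking cleavages and therefore cannot reach the
#' threshold. Fragment ion species are counted individually (a matched b
#' and a matched y at the same cleavage contribute 2).
#'
#' @param theoretical theoretical fragments of the variant proteoform
#'   ([theoretical_fragments()]).
#' @param observed numeric vector of observed fragment neutral masses.
#' @param sites integer vector of SAAV residue positions (core coordinates).
#' @param shift_interval `NULL` when the proteoform carries no unexpected
#'   shift, otherwise `c(start, end)` of the shift's localization interval.
#' @param tol_ppm fragment match tolerance in ppm (default 15).
#' @param min_ions flanking-ion threshold per site (default 3).
#' @return list with `confident` (logical) and `flanking_counts` (integer
#'   vector named by site; `NA` when no shift is present, since the first
#'   disjunct applies and no counting is needed).
#' @export
saav_confidence_filter <- function(theoretical, observed, sites,
                                   shift_interval = NULL, tol_ppm = 15,
                                   min_ions = 3L) {
  stopifnot(length(sites) >= 1L, all(sites >= 1L))
  if (is.null(shift_interval)) {
    return(list(confident = TRUE,
                flanking_counts = stats::setNames(
                  rep(NA_integer_, length(sites)), sites)))
  }
  stopifnot(length(shift_interval) == 2L,
            shift_interval[1] <= shift_interval[2])
  matched <- match_fragments(theoretical, observed, tol_ppm)
  cleav <- theoretical$cleavage[matched]
  counts <- vapply(sites, function(p) {
    a <- shift_interval[1]; b <- shift_interval[2]
    rng <- if (p < a) seq(p, a - 1L)
    else if (p > b) seq(b, p - 1L)
    else integer(0)  # site inside the shift interval
    sum(cleav %in% rng)
  }, integer(1))
  names(counts) <- sites
  list(confident = all(counts >= min_ions), flanking_counts = counts)
}
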