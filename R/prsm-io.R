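#' @importFrom utils read.delim write.table
NULL

# mandatory columns of the PrSM TSV dialect
PRSM_COLUMNS <- c("spectrum_id", "condition", "replicate", "fraction",
                  "protein_accession", "proteoform", "start_pos", "end_pos",
                  "precursor_mass", "e_value", "intensity", "charge",
                  "migration_time")

DECOY_PREFIX <- "DECOY_"

#' Read a PrSM table
#'
#' Reads the tab-separated PrSM (proteoform-spectrum match) dialect used by
#' this package: UTF-8, one header line, `"NA"` for missing intensity. One
#' row is one spectrum-to-proteoform match with its run context (condition,
#' replicate, fraction), neutral monoisotopic precursor mass in Da, E-value
#' and feature intensity.
#'
#' Rows whose precursor mass or E-value does not parse as a number, or whose
#' E-value is not strictly positive, are dropped; the number of dropped rows
#' is reported with a message. The decoy flag is derived from the accession
#' (`"DECOY_"` prefix); if an `is_decoy` column is present it must agree.
#'
#' @param path path to the TSV file.
#' @return a data.frame of PrSM records with an `is_decoy` logical column.
#' @export
read_prsm_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   stringsAsFactors = FALSE, na.strings = "NA",
                   fileEncoding = "UTF-8",
                   colClasses = "character")
  missing_cols <- setdiff(PRSM_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("PrSM table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n0 <- nrow(df)
  num <- function(x) suppressWarnings(as.numeric(x))
  int <- function(x) suppressWarnings(as.integer(x))
  df$precursor_mass <- num(df$precursor_mass)
  df$e_value <- num(df$e_value)
  df$intensity <- num(df$intensity)
  df$start_pos <- int(df$start_pos)
  df$end_pos <- int(df$end_pos)
  df$replicate <- int(df$replicate)
  df$fraction <- int(df$fraction)
  df$charge <- int(df$charge)
  df$migration_time <- num(df$migration_time)
  ok <- !is.na(df$precursor_mass) & !is.na(df$e_value) & df$e_value > 0
  if (any(!ok)) {
    message(sum(!ok), " of ", n0,
            " rows rejected (unparseable mass/E-value or E-value <= 0)")
    df <- df[ok, , drop = FALSE]
  }
  derived <- startsWith(df$protein_accession, DECOY_PREFIX)
  if ("is_decoy" %in% names(df)) {
    stated <- df$is_decoy %in% c("TRUE", "true", "1")
    if (!all(stated == derived)) {
      stop("is_decoy column disagrees with the DECOY_ accession prefix",
           call. = FALSE)
    }
  }
  df$is_decoy <- derived
  rownames(df) <- NULL
  df
}

#' Write a PrSM table
#'
#' Inverse of [read_prsm_table()]: tab-separated, UTF-8, `"NA"` for missing
#' values, no quoting, no row names.
#'
#' @param prsms data.frame of PrSM records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_prsm_table <- function(prsms, path) {
  cols <- c(PRSM_COLUMNS, intersect("is_decoy", names(prsms)))
  missing_cols <- setdiff(PRSM_COLUMNS, names(prsms))
  if (length(missing_cols)) {
    stop("cannot write PrSM table; missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  write.table(prsms[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write protein FASTA
#'
#' Thin wrappers over Biostrings. Sequences are handled as a named character
#' vector (names are accessions; decoy entries carry the `"DECOY_"` prefix).
#'
#' @param path FASTA file path.
#' @param seqs named character vector of amino acid sequences.
#' @return `read_fasta()` returns a named character vector; `write_fasta()`
#'   returns `path` invisibly.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  # keep only the accession token of the description line
  names(out) <- vapply(strsplit(names(x), "\\s+"), `[`, "", 1L)
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Read a variant table
#'
#' Tab-separated table of single amino acid variants with columns
#' `protein_accession`, `position` (1-based residue index), `ref_aa`,
#' `alt_aa`.
#'
#' @param path TSV path.
#' @return data.frame of variant records.
#' @export
read_variant_table <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("protein_accession", "position", "ref_aa", "alt_aa")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("variant table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$position <- as.integer(df$position)
  if (any(df$ref_aa == df$alt_aa)) {
    stop("variant table contains rows with ref_aa == alt_aa", call. = FALSE)
  }
  df
}

#' Read and write fragment-mass lists
#'
#' Tab-separated list of observed fragment neutral masses per proteoform:
#' columns `proteoform_id`, `mass` (Da).
#'
#' @param path TSV path.
#' @param frags data.frame with columns `proteoform_id`, `mass`.
#' @return `read_fragment_table()` returns a data.frame;
#'   `write_fragment_table()` returns `path` invisibly.
#' @export
read_fragment_table <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("proteoform_id", "mass")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("fragment table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$mass <- as.numeric(df$mass)
  df
}

#' @rdname read_fragment_table
#' @export
write_fragment_table <- function(frags, path) {
  write.table(frags, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}
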