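#' Parse a proteoform string
#'
#' Proteoform strings follow the notation used in top-down search engine
#' output: an optional single-residue N-terminal flank followed by `"."`, a
#' core sequence in which modified stretches are written as bracket groups,
#' and an optional `"."` plus single-residue C-terminal flank. Two kinds of
#' groups are recognized:
#'
#' * named modifications, `"(RESIDUES)[modname]"`, e.g. `"(A)[acetyl]"`;
#' * unexpected (unannotated) mass shifts,
#'   `"(RESIDUES) (mass shift: N Da, free text)"`.
#'
#' A parenthesized annotation that does not begin with `"mass shift"` (e.g.
#' `"(C) (carbamidomethylation)"`) is accepted as a named modification written
#' in the loose typography that occurs in published tables. Whitespace between
#' tokens is normalized away.
#'
#' Coordinates are 1-based inclusive positions on the core sequence (the
#' concatenation of all residues with bracketing removed).
#'
#' @param s a single proteoform string.
#' @param max_shifts maximum number of unexpected shifts permitted (the
#'   search setting in this workflow allows one); exceeding it is an error.
#' @return an object of class `parsed_proteoform`: a list with elements
#'   `prefix_residue`, `suffix_residue` (single characters or `NA`),
#'   `core_sequence`, `named_mods` (data.frame `start`, `end`, `name`,
#'   `mass`), and `unexpected_shifts` (data.frame `start`, `end`, `mass`,
#'   `annotation`).
#' @seealso [format_proteoform()] for the inverse operation.
#' @examples
#' p <- parse_proteoform("M.(A)[acetyl]ASAK.S")
#' p$core_sequence      # "AASAK"
#' p$named_mods         # acetyl on span (1, 1)
#' @export
parse_proteoform <- function(s, max_shifts = 1L) {
  stopifnot(is.character(s), length(s) == 1L, !is.na(s))
  s <- trimws(s)
  n <- nchar(s)

  # flanking residues: "X." prefix / ".X" suffix; a bare dot means the
  # proteoform extends to the protein terminus (no flank)
  prefix <- NA_character_
  if (grepl("^[A-Z]\\.", s)) {
    prefix <- substr(s, 1L, 1L)
    s <- substr(s, 3L, n)
  } else if (startsWith(s, ".")) {
    s <- substr(s, 2L, n)
  }
  n <- nchar(s)
  suffix <- NA_character_
  if (grepl("\\.[A-Z]$", s)) {
    suffix <- substr(s, n, n)
    s <- substr(s, 1L, n - 2L)
  } else if (endsWith(s, ".")) {
    s <- substr(s, 1L, n - 1L)
  }

  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  core <- character(0)
  mods <- list()
  shifts <- list()
  i <- 1L
  np <- length(chars)

  read_until <- function(i, close) {
    # read from position i to the matching close character; returns
    # c(content, next index); no nesting inside groups
    j <- i
    while (j <= np && chars[j] != close) j <- j + 1L
    if (j > np) {
      stop(sprintf("unbalanced '%s' group starting at position %d in proteoform string",
                   close, i - 1L), call. = FALSE)
    }
    list(text = paste(chars[seq(i, j - 1L)], collapse = ""), nxt = j + 1L)
  }

  while (i <= np) {
    ch <- chars[i]
    if (grepl("^[A-Z]$", ch)) {
      core <- c(core, ch)
      i <- i + 1L
    } else if (grepl("^\\s$", ch)) {
      i <- i + 1L
    } else if (ch == "(") {
      grp <- read_until(i + 1L, ")")
      res <- gsub("\\s", "", grp$text)
      if (!grepl("^[A-Z]+$", res)) {
        stop(sprintf("expected residues inside '(...)' at position %d, got \"%s\"",
                     i, grp$text), call. = FALSE)
      }
      span_start <- length(core) + 1L
      core <- c(core, strsplit(res, "")[[1]])
      span_end <- length(core)
      i <- grp$nxt
      while (i <= np && grepl("^\\s$", chars[i])) i <- i + 1L
      if (i <= np && chars[i] == "[") {
        ann <- read_until(i + 1L, "]")
        name <- trimws(ann$text)
        mods[[length(mods) + 1L]] <- data.frame(
          start = span_start, end = span_end, name = name,
          mass = mod_mass(name), stringsAsFactors = FALSE)
        i <- ann$nxt
      } else if (i <= np && chars[i] == "(") {
        ann <- read_until(i + 1L, ")")
        text <- trimws(ann$text)
        m <- regmatches(text, regexec(
          "^mass\\s+shift:\\s*(-?[0-9]+\\.?[0-9]*)\\s*Da\\s*,?\\s*(.*)$", text))[[1]]
        if (length(m)) {
          shifts[[length(shifts) + 1L]] <- data.frame(
            start = span_start, end = span_end,
            mass = as.numeric(m[2]), annotation = m[3],
            stringsAsFactors = FALSE)
        } else {
          # loose typography: "(C) (carbamidomethylation)" is a named mod
          mods[[length(mods) + 1L]] <- data.frame(
            start = span_start, end = span_end, name = text,
            mass = mod_mass(text), stringsAsFactors = FALSE)
        }
        i <- ann$nxt
      } else {
        stop(sprintf("expected '[mod]' or '(mass shift: ...)' annotation after group ending at position %d",
                     i - 1L), call. = FALSE)
      }
    } else {
      stop(sprintf("unexpected character '%s' at position %d in proteoform string",
                   ch, i), call. = FALSE)
    }
  }

  named_mods <- if (length(mods)) do.call(rbind, mods) else
    data.frame(start = integer(0), end = integer(0), name = character(0),
               mass = numeric(0), stringsAsFactors = FALSE)
  unexpected <- if (length(shifts)) do.call(rbind, shifts) else
    data.frame(start = integer(0), end = integer(0), mass = numeric(0),
               annotation = character(0), stringsAsFactors = FALSE)
  if (nrow(unexpected) > max_shifts) {
    stop(sprintf("proteoform string has %d unexpected mass shifts; at most %d allowed",
                 nrow(unexpected), max_shifts), call. = FALSE)
  }

  structure(list(
    prefix_residue = prefix,
    suffix_residue = suffix,
    core_sequence = paste(core, collapse = ""),
    named_mods = named_mods,
    unexpected_shifts = unexpected
  ), class = "parsed_proteoform")
}

#' Format a parsed proteoform back to its string notation
#'
#' Inverse of [parse_proteoform()]: emits the canonical form with flanking
#' residues separated by dots (a bare dot when the flank is absent), named
#' modifications as `"(RES)[name]"` and unexpected shifts as
#' `"(RES) (mass shift: N Da, annotation)"`. `parse_proteoform()` of the
#' result recovers the input.
#'
#' @param p a `parsed_proteoform`.
#' @return a single character string.
#' @export
format_proteoform <- function(p) {
  stopifnot(inherits(p, "parsed_proteoform"))
  groups <- rbind(
    if (nrow(p$named_mods)) cbind(p$named_mods[, c("start", "end")],
                                  kind = "mod", idx = seq_len(nrow(p$named_mods))),
    if (nrow(p$unexpected_shifts)) cbind(p$unexpected_shifts[, c("start", "end")],
                                         kind = "shift", idx = seq_len(nrow(p$unexpected_shifts)))
  )
  core <- p$core_sequence
  out <- character(0)
  pos <- 1L
  if (!is.null(groups) && nrow(groups)) {
    groups <- groups[order(groups$start), , drop = FALSE]
    if (any(groups$start[-1] <= groups$end[-nrow(groups)])) {
      stop("overlapping modification groups cannot be formatted", call. = FALSE)
    }
    for (g in seq_len(nrow(groups))) {
      if (groups$start[g] > pos) {
        out <- c(out, substr(core, pos, groups$start[g] - 1L))
      }
      span <- substr(core, groups$start[g], groups$end[g])
      if (groups$kind[g] == "mod") {
        out <- c(out, sprintf("(%s)[%s]", span, p$named_mods$name[groups$idx[g]]))
      } else {
        sh <- p$unexpected_shifts[groups$idx[g], ]
        ann <- if (nzchar(sh$annotation)) paste0(", ", sh$annotation) else ""
        out <- c(out, sprintf("(%s) (mass shift: %s Da%s)", span,
                              sprintf("%.15g", sh$mass), ann))
      }
      pos <- groups$end[g] + 1L
    }
  }
  if (pos <= nchar(core)) out <- c(out, substr(core, pos, nchar(core)))
  paste0(
    if (is.na(p$prefix_residue)) "." else paste0(p$prefix_residue, "."),
    paste(out, collapse = ""),
    if (is.na(p$suffix_residue)) "." else paste0(".", p$suffix_residue)
  )
}

#' @export
print.parsed_proteoform <- function(x, ...) {
  cat("parsed_proteoform:", format_proteoform(x), "\n")
  cat(sprintf("  core: %d residues, %d named mod(s), %d unexpected shift(s)\n",
              nchar(x$core_sequence), nrow(x$named_mods),
              nrow(x$unexpected_shifts)))
  invisible(x)
}

#' Total modification mass carried by a parsed proteoform
#'
#' Sum of the monoisotopic masses of all named modifications (unknown names,
#' which carry `NA` mass, are ignored) plus all unexpected mass shifts. This
#' is the quantity binned by [ptm_census()].
#'
#' @param p a `parsed_proteoform`.
#' @return total delta mass in Da.
#' @export
proteoform_mod_mass <- function(p) {
  stopifnot(inherits(p, "parsed_proteoform"))
  sum(p$named_mods$mass, na.rm = TRUE) + sum(p$unexpected_shifts$mass)
}

#' Neutral monoisotopic mass of a parsed proteoform
#'
#' Residue masses plus one water plus all modification masses (named and
#' unexpected). Cysteines are assumed already carbamidomethylated only if the
#' string carries the modification explicitly; use `fixed_cys = TRUE` to add
#' +57.02146 Da per unannotated cysteine, matching a search with fixed
#' carbamidomethylation.
#'
#' @param p a `parsed_proteoform`.
#' @param fixed_cys add carbamidomethyl to every cysteine not already covered
#'   by a carbamidomethyl named-mod group.
#' @return neutral monoisotopic mass in Da.
#' @export
proteoform_mass <- function(p, fixed_cys = FALSE) {
  stopifnot(inherits(p, "parsed_proteoform"))
  res <- strsplit(p$core_sequence, "")[[1]]
  bad <- setdiff(res, names(AA_MONO))
  if (length(bad)) {
    stop("unknown residue(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  m <- sum(AA_MONO[res]) + WATER_MONO + proteoform_mod_mass(p)
  if (fixed_cys) {
    cys <- which(res == "C")
    cam <- p$named_mods[grepl("^carbamidomethyl", p$named_mods$name,
                              ignore.case = TRUE), , drop = FALSE]
    covered <- unlist(Map(seq, cam$start, cam$end))
    m <- m + MOD_MONO[["carbamidomethyl"]] * length(setdiff(cys, covered))
  }
  unname(m)
}
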