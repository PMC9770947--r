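#' Target-decoy q-values
#'
#' Estimates per-item q-values from a combined target/decoy collection scored
#' by E-value (lower is better). Items are ranked by ascending E-value with
#' exact ties grouped, so the result does not depend on input order. At each
#' rank the raw FDR is the decoy/target count ratio
#' \eqn{\mathrm{FDR}(k) = D(k) / \max(1, T(k))} over the items at or above
#' that rank (the D/T convention of the TopPIC suite), and the q-value is
#' the running minimum of the raw FDR taken from the worst score upward, so
#' q-values are monotone non-decreasing in E-value.
#'
#' @param items data.frame with numeric `e_value` (> 0) and logical
#'   `is_decoy` columns.
#' @return `items` with a `q_value` column appended, in the original row
#'   order.
#' @export
add_q_values <- function(items) {
  stopifnot(is.data.frame(items),
            all(c("e_value", "is_decoy") %in% names(items)))
  if (nrow(items) == 0L) {
    items$q_value <- numeric(0)
    return(items)
  }
  if (any(is.na(items$e_value)) || any(items$e_value <= 0)) {
    stop("all E-values must be positive and non-missing", call. = FALSE)
  }
  ord <- order(items$e_value)
  ev <- items$e_value[ord]
  dec <- items$is_decoy[ord]
  cum_d <- cumsum(dec)
  cum_t <- cumsum(!dec)
  # ties share the counts at the end of their tie group
  grp_end <- cumsum(rle(ev)$lengths)
  grp_id <- rep(seq_along(grp_end), rle(ev)$lengths)
  raw <- (cum_d[grp_end] / pmax(1L, cum_t[grp_end]))
  qg <- rev(cummin(rev(raw)))
  q_sorted <- qg[grp_id]
  q <- numeric(length(ord))
  q[ord] <- q_sorted
  items$q_value <- q
  items
}

#' Filter identifications at an FDR threshold
#'
#' Retains the target items whose q-value is at or below `threshold`; decoy
#' items are never reported downstream. Computes q-values first via
#' [add_q_values()] if the collection does not already carry them.
#'
#' @param items data.frame with `e_value`, `is_decoy` and optionally
#'   `q_value` columns.
#' @param threshold FDR threshold in (0, 1); the workflow defaults are 0.05
#'   at the spectrum level and 0.01 at the proteoform level (0.05 for
#'   variant-database searches).
#' @return the retained target rows, with `q_value`.
#' @export
filter_at_fdr <- function(items, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must be a single number in (0, 1)", call. = FALSE)
  }
  if (!"q_value" %in% names(items)) items <- add_q_values(items)
  out <- items[!items$is_decoy & items$q_value <= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}
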