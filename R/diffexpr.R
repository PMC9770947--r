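#' S0-moderated two-sample statistic
#'
#' The SAM-family statistic
#' \deqn{d = \frac{\bar x - \bar y}{s + s_0}}
#' where \eqn{s} is the pooled two-sample standard error
#' \eqn{s = s_p \sqrt{1/n_x + 1/n_y}} and \eqn{s_0 \ge 0} is a constant
#' offset on the abundance (here log2) scale that damps the significance of
#' low-variance rows. With `s0 = 0` the statistic is exactly Student's
#' equal-variance t.
#'
#' @param x,y numeric vectors of log2 abundances for the two groups, each of
#'   length at least 2.
#' @param s0 non-negative offset (default 1, the Perseus-style setting used
#'   for proteoform volcano analysis).
#' @return the statistic `d` (a single number).
#' @export
s0_statistic <- function(x, y, s0 = 1) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (!is.numeric(s0) || length(s0) != 1L || s0 < 0) {
    stop("s0 must be a single non-negative number", call. = FALSE)
  }
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  se <- sqrt(sp2) * sqrt(1 / nx + 1 / ny)
  (mean(x) - mean(y)) / (se + s0)
}

# vectorized d over matrix rows; g1/g2 are column index vectors
.row_d <- function(m, g1, g2, s0) {
  n1 <- length(g1); n2 <- length(g2)
  x <- m[, g1, drop = FALSE]; y <- m[, g2, drop = FALSE]
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (n1 - 1)
  vy <- rowSums((y - my)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * vx + (n2 - 1) * vy) / (n1 + n2 - 2)
  se <- sqrt(sp2) * sqrt(1 / n1 + 1 / n2)
  (mx - my) / (se + s0)
}

#' Differential proteoform test with permutation-based FDR
#'
#' Computes the S0-moderated statistic [s0_statistic()] for every matrix row
#' (condition 1 minus condition 2 on the log2 scale) and estimates q-values
#' by permuting condition labels, in the spirit of the SAM procedure that
#' the Perseus "S0 / FDR" volcano settings imply:
#'
#' 1. Observed `|d|` per row.
#' 2. For each balanced label shuffle — a relabeling that preserves the two
#'    group sizes and differs from the observed grouping (the observed
#'    labeling and its mirror are excluded, since they reproduce the
#'    observed statistics rather than the null) — the permuted `|d|` per
#'    row. All distinct informative shuffles are enumerated exhaustively
#'    when there are at most `n_permutations` of them; for a 3 vs 3 design
#'    that is the 18 relabelings besides the observed pair. Otherwise
#'    `n_permutations` seeded random shuffles are drawn.
#' 3. For row *i*, `q_i` is the mean over permutations of the fraction of
#'    permuted `|d|` values at or above `|d_i|`, divided by the fraction of
#'    observed `|d|` values at or above `|d_i|` (an E\[V\]/R estimate),
#'    capped at 1 and made monotone non-decreasing in rank.
#'
#' A row is flagged significant when its q-value is at or below `fdr`.
#' Classical two-sided Student t p-values are reported alongside for the
#' volcano plot.
#'
#' @param qm a log2-scale [quant_matrix()] with exactly two conditions and
#'   at least two replicates each, or a plain numeric matrix (then `design`
#'   must be given).
#' @param design optional data.frame with `condition` per column of a plain
#'   matrix input.
#' @param s0 statistic offset (default 1).
#' @param fdr significance threshold on the permutation q-value (default
#'   0.05).
#' @param n_permutations maximum number of label shuffles (default 1000).
#' @param seed integer seed for shuffle sampling (ignored when shuffles are
#'   enumerated exhaustively).
#' @return data.frame of class `diff_result`: `key`, `log2_fc` (condition 1
#'   minus condition 2), `d_statistic`, `p_value`, `q_permutation`,
#'   `significant`, `direction`.
#' @export
permutation_fdr <- function(qm, design = NULL, s0 = 1, fdr = 0.05,
                            n_permutations = 1000L, seed = 1L) {
  if (inherits(qm, "quant_matrix")) {
    if (!qm$log2) stop("expected a log2-scale quant_matrix", call. = FALSE)
    m <- qm$abundance
    design <- qm$design
    keys <- if ("cluster_id" %in% names(qm$rows)) qm$rows$cluster_id else
      as.character(seq_len(nrow(m)))
  } else {
    m <- as.matrix(qm)
    if (is.null(design)) stop("design required for matrix input", call. = FALSE)
    keys <- if (!is.null(rownames(m))) rownames(m) else
      as.character(seq_len(nrow(m)))
  }
  if (!is.numeric(fdr) || fdr <= 0 || fdr >= 1) {
    stop("fdr must be in (0, 1)", call. = FALSE)
  }
  conds <- unique(design$condition)
  if (length(conds) != 2L) stop("exactly two conditions required", call. = FALSE)
  g1 <- which(design$condition == conds[1])
  g2 <- which(design$condition == conds[2])
  if (length(g1) < 2L || length(g2) < 2L) {
    stop("at least two replicates per condition required", call. = FALSE)
  }
  n <- ncol(m); n1 <- length(g1)
  d_obs <- .row_d(m, g1, g2, s0)
  abs_obs <- abs(d_obs)
  nr <- nrow(m)

  is_observed <- function(p1) {
    identical(p1, sort(g1)) || identical(p1, sort(g2))
  }
  n_shuffles <- choose(n, n1) -
    (1L + as.integer(length(g1) == length(g2)))
  if (n_shuffles < 2) stop("fewer than 2 distinct label shuffles", call. = FALSE)
  if (choose(n, n1) <= n_permutations) {
    perms <- Filter(Negate(is_observed), utils::combn(n, n1, simplify = FALSE))
  } else {
    perms <- with_local_seed(seed, {
      out <- list()
      while (length(out) < n_permutations) {
        p1 <- sort(sample.int(n, n1))
        if (!is_observed(p1)) out[[length(out) + 1L]] <- p1
      }
      out
    })
  }
  # pool all permuted |d|; E[V_i] = #{pooled >= |d_i|} / n_perms
  perm_abs <- unlist(lapply(perms, function(p1) {
    abs(.row_d(m, p1, setdiff(seq_len(n), p1), s0))
  }), use.names = FALSE)
  np <- length(perms)
  # counts of permuted / observed values >= each observed |d|
  v_mean <- (length(perm_abs) -
               findInterval(abs_obs - .Machine$double.eps^0.5,
                            sort(perm_abs))) / np
  r_obs <- vapply(abs_obs, function(t) sum(abs_obs >= t - .Machine$double.eps^0.5),
                  numeric(1))
  q_raw <- pmin(1, (v_mean / nr) / (r_obs / nr))
  # monotone: most significant rows first, running min from the bottom
  ord <- order(abs_obs, decreasing = TRUE)
  q_sorted <- q_raw[ord]
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(nr); q[ord] <- q_sorted

  # classical p-values for reporting
  tstat <- .row_d(m, g1, g2, 0)
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)

  out <- data.frame(
    key = keys,
    log2_fc = rowMeans(m[, g1, drop = FALSE]) - rowMeans(m[, g2, drop = FALSE]),
    d_statistic = d_obs,
    p_value = p,
    q_permutation = q,
    significant = q <= fdr,
    direction = ifelse(d_obs >= 0, conds[1], conds[2]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "conditions") <- conds
  attr(out, "fdr") <- fdr
  attr(out, "s0") <- s0
  attr(out, "n_shuffles") <- np
  class(out) <- c("diff_result", "data.frame")
  out
}

#' Volcano-plot table
#'
#' Classifies tested proteoforms for the volcano display: rows significant
#' and higher in condition 1, significant and higher in condition 2, or not
#' significant.
#'
#' @param results a `diff_result` from [permutation_fdr()].
#' @return data.frame with `key`, `log2_fc`, `neg_log10_p` and `flag`.
#' @export
volcano_table <- function(results) {
  stopifnot(inherits(results, "diff_result"))
  conds <- attr(results, "conditions")
  flag <- rep("not_significant", nrow(results))
  flag[results$significant & results$log2_fc > 0] <-
    paste0("higher_in_", conds[1])
  flag[results$significant & results$log2_fc < 0] <-
    paste0("higher_in_", conds[2])
  data.frame(key = results$key, log2_fc = results$log2_fc,
             neg_log10_p = -log10(results$p_value), flag = flag,
             stringsAsFactors = FALSE)
}

#' Compare two groups of scalars
#'
#' The simple mean +/- SD comparison used for summary statements (e.g.
#' within- versus between-condition overlap percentages): classical
#' equal-variance two-sample Student t test, two-tailed.
#'
#' @param a,b numeric vectors, each of length at least 2.
#' @return list with `mean_a`, `sd_a`, `mean_b`, `sd_b`, `t` and `p_value`.
#'   Degenerate zero-variance inputs report the p-value as the numeric
#'   underflow floor rather than exactly 0.
#' @export
compare_group_means <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- if (se == 0) {
    if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
  } else (mean(a) - mean(b)) / se
  p <- 2 * stats::pt(abs(t), df = na + nb - 2, lower.tail = FALSE)
  if (p == 0) p <- .Machine$double.xmin
  list(mean_a = mean(a), sd_a = stats::sd(a),
       mean_b = mean(b), sd_b = stats::sd(b),
       t = t, p_value = p)
}
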