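#' Volcano plot of differential proteoforms
#'
#' Standard volcano display: log2 fold change against -log10 p-value, with
#' proteoforms significant at the permutation FDR colored by the condition
#' they are higher in.
#'
#' @param results a `diff_result` from [permutation_fdr()].
#' @param file optional PNG path; when given the plot is written there.
#' @param ... further arguments passed to [graphics::plot()].
#' @return invisibly, the [volcano_table()] used for the display.
#' @export
plot_volcano <- function(results, file = NULL, ...) {
  vt <- volcano_table(results)
  conds <- attr(results, "conditions")
  col <- rep("grey60", nrow(vt))
  col[vt$flag == paste0("higher_in_", conds[1])] <- "firebrick"
  col[vt$flag == paste0("higher_in_", conds[2])] <- "dodgerblue3"
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700, res = 120)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(vt$log2_fc, vt$neg_log10_p, col = col, pch = 16,
                 cex = 0.6, xlab = expression(log[2] ~ "fold change"),
                 ylab = expression(-log[10] ~ italic(p)), ...)
  graphics::legend("topright", bty = "n", pch = 16,
                   col = c("firebrick", "dodgerblue3", "grey60"),
                   legend = c(paste("higher in", conds[1]),
                              paste("higher in", conds[2]),
                              "not significant"))
  invisible(vt)
}

#' Heatmap of a proteoform overlap matrix
#'
#' @param m matrix from [overlap_matrix()].
#' @param file optional PNG path.
#' @return invisibly, `m`.
#' @export
plot_overlap_heatmap <- function(m, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 700, height = 650, res = 120)
    on.exit(grDevices::dev.off())
  }
  n <- nrow(m)
  graphics::image(seq_len(n), seq_len(n), t(m[n:1, , drop = FALSE]),
                  zlim = c(0, 1), axes = FALSE, xlab = "", ylab = "",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE))
  graphics::axis(1, at = seq_len(n), labels = colnames(m), las = 2,
                 cex.axis = 0.8)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(m)), las = 2,
                 cex.axis = 0.8)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    graphics::text(j, n + 1 - i, sprintf("%.2f", m[i, j]), cex = 0.7)
  }
  invisible(m)
}
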