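#' Scatterplot of z-scores against mean log ratio
#'
#' The standard screen overview: each unfiltered barcode (or gene cluster)
#' plotted by its mean log2 abundance and its z-score, with the extreme
#' depleted/enriched records standing out. Written as a PNG file.
#'
#' @param scores a [scoreBarcodes()] table.
#' @param file output PNG path.
#' @param highlight optional vector of barcode ids to mark.
#' @return `file`, invisibly.
#' @export
plotScoreScatter <- function(scores, file, highlight = NULL) {
  act <- scores[!scores$filtered, , drop = FALSE]
  grDevices::png(file, width = 900, height = 700)
  on.exit(grDevices::dev.off())
  x <- log2((act$mean_case_ratio + act$mean_control_ratio) / 2)
  plot(x, act$z_score, pch = 20, col = "grey40",
       xlab = "mean log2 abundance ratio", ylab = "z-score",
       main = "barcode depletion/enrichment")
  graphics::abline(h = c(-2, 2), lty = 2, col = "red")
  if (!is.null(highlight)) {
    sel <- act$barcode_id %in% highlight
    graphics::points(x[sel], act$z_score[sel], pch = 20, col = "red")
  }
  invisible(file)
}

#' Heat-map of time-dependent fc-scores
#'
#' Barcodes x time points image of [timeseriesFC()] output, rows ordered
#' by the final time point's fc-score so depletion trajectories band
#' together.
#'
#' @param tsfc long-format table from [timeseriesFC()].
#' @param file output PNG path.
#' @param top plot only the `top` barcodes with the largest absolute final
#'   fc (default 50; `Inf` for all).
#' @return `file`, invisibly.
#' @export
plotTimeHeatmap <- function(tsfc, file, top = 50) {
  wide <- tapply(tsfc$fc_score, list(tsfc$barcode_id, tsfc$time_point),
                 identity)
  last <- wide[, ncol(wide)]
  ord <- order(last)
  wide <- wide[ord, , drop = FALSE]
  if (is.finite(top) && nrow(wide) > top) {
    keep <- order(-abs(wide[, ncol(wide)]))[seq_len(top)]
    wide <- wide[sort(keep), , drop = FALSE]
  }
  grDevices::png(file, width = 700, height = 900)
  on.exit(grDevices::dev.off())
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(64)
  lim <- max(abs(wide), na.rm = TRUE)
  graphics::image(x = seq_len(ncol(wide)), y = seq_len(nrow(wide)),
                  z = t(wide), zlim = c(-lim, lim), col = pal,
                  xlab = "time point", ylab = "", axes = FALSE,
                  main = "fc-score by time")
  graphics::axis(1, at = seq_len(ncol(wide)), labels = colnames(wide))
  graphics::axis(2, at = seq_len(nrow(wide)), labels = rownames(wide),
                 las = 2, cex.axis = 0.5)
  invisible(file)
}
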