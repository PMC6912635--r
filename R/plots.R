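#' Double-plotted actogram
#'
#' Raster plot of activity over successive days with 48 h per row (day d
#' beside day d + 1), the standard display for spotting free-running drift.
#' Exported for human review; the automated pipeline never interprets it.
#'
#' @param record an [activity_record()]
#' @param bin_minutes bin width for the bars
#' @param main plot title; defaults to the individual id
#' @export
plot_actogram <- function(record, bin_minutes = 20,
                          main = record$individual_id) {
  nb <- 1440L %/% bin_minutes
  n_days <- length(record$counts) %/% 1440L
  daymat <- vapply(seq_len(n_days), function(d) {
    v <- record$counts[((d - 1) * 1440 + 1):(d * 1440)]
    colSums(matrix(v, nrow = bin_minutes))
  }, numeric(nb))
  top <- max(daymat, 1)
  op <- graphics::par(mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  graphics::plot(NULL, xlim = c(0, 48), ylim = c(n_days, 0), yaxs = "i",
                 xlab = "Time (h, double-plotted)", ylab = "Day",
                 main = main)
  for (d in seq_len(n_days - 1L)) {
    row <- c(daymat[, d], daymat[, d + 1L]) / top
    x0 <- (seq_along(row) - 1) * bin_minutes / 60
    graphics::rect(x0, d, x0 + bin_minutes / 60, d - pmin(row, 1) * 0.9,
                   col = "black", border = NA)
  }
  invisible(record)
}
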