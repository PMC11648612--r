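#' Plot a PSTH with its surrogate acceptance bands
#'
#' Draws the observed peristimulus histogram as a step line with the
#' surrogate mean (blue), pointwise band (red) and global band (pink)
#' overlaid, mirroring the standard presentation of jitter-corrected
#' stimulus-response tests.
#'
#' @param observed a [build_psth()] result.
#' @param bands a [compute_bands()] result with matching geometry.
#' @param main plot title.
#' @return Invisibly, `NULL`. Called for its side effect.
#' @export
plot_psth_bands <- function(observed, bands, main = "") {
  stopifnot(inherits(observed, "psth"), inherits(bands, "jitter_bands"))
  x <- observed$bin_left + observed$bin_width / 2
  ylim <- range(0, observed$counts, bands$global_high * 1.1)
  graphics::plot(x, observed$counts, type = "s", xlab = "time from stimulus (s)",
                 ylab = "count", main = main, ylim = ylim)
  graphics::lines(x, bands$surrogate_mean, col = "blue", lty = 2)
  graphics::lines(x, bands$pointwise_low, col = "red", lty = 2)
  graphics::lines(x, bands$pointwise_high, col = "red", lty = 2)
  graphics::abline(h = c(bands$global_low, bands$global_high),
                   col = "pink3", lty = 2)
  graphics::abline(v = 0, col = "grey60")
  invisible(NULL)
}

#' Heatmap of normalized fluorescence
#'
#' Renders the ROI-by-frame dF/F0 matrix from [heatmap_matrix()] with
#' `image()`, time on the x axis and ROIs stacked on the y axis.
#'
#' @param norm a `normalized_traces` object.
#' @param sort row ordering, as in [heatmap_matrix()].
#' @param main plot title.
#' @return Invisibly, the plotted matrix.
#' @export
plot_dff_heatmap <- function(norm, sort = "none", main = "dF/F0") {
  hm <- heatmap_matrix(norm, sort)
  m <- hm$matrix
  graphics::image(x = norm$times, y = seq_len(nrow(m)), z = t(m),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "time (s)", ylab = "ROI", main = main)
  invisible(m)
}
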