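#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of a condition summary
#'
#' The figure-style view: one bar per genotype x UV cell, mean +/- SE across
#' experiments, compact significance letters above the bars and a star on
#' genotypes whose +/-UV contrast is significant.
#'
#' @param object A `fret_summary` from [summarize_conditions()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot fret_summary
#' @export
autoplot.fret_summary <- function(object, ...) {
  df <- object$summary
  df$uv_lab <- ifelse(df$uv %in% c("TRUE", TRUE), "+UV-B", "-UV-B")
  df$lab <- paste0(df$letter, ifelse(df$star, " *", ""))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$genotype, y = .data$mean,
                                   fill = .data$uv_lab)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      position = ggplot2::position_dodge(0.8), width = 0.2) +
    ggplot2::geom_text(
      ggplot2::aes(y = .data$mean + 2 * dplyr::coalesce(.data$se, 0),
                   label = .data$lab),
      position = ggplot2::position_dodge(0.8), vjust = -0.4, size = 3) +
    ggplot2::scale_fill_manual(values = c("-UV-B" = "grey35",
                                          "+UV-B" = "grey70"), name = NULL) +
    ggplot2::labs(x = NULL, y = "mean ± SE") +
    ggplot2::theme_classic()
}

#' Display an acquisition's channels
#'
#' @param object An `acquisition`.
#' @param ... Ignored.
#' @return A ggplot object: the three channels as intensity tiles.
#' @method autoplot acquisition
#' @export
autoplot.acquisition <- function(object, ...) {
  melt <- function(m, ch) {
    tibble::tibble(row = rep(seq_len(nrow(m)), ncol(m)),
                   col = rep(seq_len(ncol(m)), each = nrow(m)),
                   intensity = as.vector(m), channel = ch)
  }
  df <- dplyr::bind_rows(melt(object$donor_488, "donor 488"),
                         melt(object$fret_488, "FRET 488"),
                         melt(object$acceptor_552, "acceptor 552"))
  df$channel <- factor(df$channel,
                       levels = c("donor 488", "FRET 488", "acceptor 552"))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~channel, nrow = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "DN") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Periphery intensity profile before and after photobleaching
#'
#' The primary-data view of the photobleaching readout: donor intensity at
#' each traced periphery point, pre- and post-bleach, for the bleached and
#' control regions.
#'
#' @param object A `bleach_result` computed with `method = "profile"`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot bleach_result
#' @export
autoplot.bleach_result <- function(object, ...) {
  if (is.null(object$profiles)) {
    stop("profile plot needs a bleach_result computed with method = 'profile'.",
         call. = FALSE)
  }
  df <- tidy(object) |>
    tidyr::pivot_longer(c("pre", "post"), names_to = "phase",
                        values_to = "intensity")
  df$phase <- factor(df$phase, levels = c("pre", "post"),
                     labels = c("Pre", "Pb"))
  ggplot2::ggplot(df, ggplot2::aes(.data$point, .data$intensity,
                                   colour = .data$phase)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~region, ncol = 1, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(Pre = "#3366cc", Pb = "#cc3333"),
                                 name = NULL) +
    ggplot2::labs(x = "periphery point", y = "donor intensity (DN)") +
    ggplot2::theme_classic()
}
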