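#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_hline
#'   labs theme_minimal scale_colour_manual
#' @export
ggplot2::autoplot

#' Manhattan-style plot of a window-variance scan
#'
#' One point per anchored window at its start position, cumulative over
#' chromosomes, with the significance threshold drawn as a horizontal line.
#'
#' @param object a [window_scan()] result.
#' @param threshold significance threshold in percent (default 1.56).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.wssgwas_scan <- function(object, threshold = 1.56, ...) {
  chroms <- unique(object$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(ch)
    max(object$end_bp[object$chrom == ch]), numeric(1))))
  names(offs) <- c(chroms, "end")
  df <- dplyr::mutate(
    as_tibble(object),
    x = .data$start_bp + offs[.data$chrom],
    parity_col = factor(match(.data$chrom, chroms) %% 2))
  ggplot(df, aes(x = .data$x / 1e6, y = .data$pct_var,
                 colour = .data$parity_col)) +
    geom_point(size = 0.8, show.legend = FALSE) +
    geom_hline(yintercept = threshold, linetype = "dashed") +
    scale_colour_manual(values = c("grey35", "steelblue4")) +
    labs(x = "Genome position (Mb, cumulative)",
         y = "Genetic variance explained by window (%)") +
    theme_minimal()
}

#' Plot an LD-decay curve
#'
#' Mean r2 per distance bin with the threshold and interpolated decay
#' distance marked.
#'
#' @param object an [decay_curve()] `ld_curve` object.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ld_curve <- function(object, ...) {
  df <- dplyr::filter(object$bins, .data$n_pairs > 0)
  p <- ggplot(df, aes(x = .data$mid_bp / 1e3, y = .data$mean_r2)) +
    geom_line(colour = "steelblue4") +
    geom_point(size = 0.8) +
    geom_hline(yintercept = object$r2_threshold, linetype = "dashed") +
    labs(x = "Pair distance (kb)", y = expression(mean ~ r^2)) +
    theme_minimal()
  if (!is.na(object$decay_distance_bp))
    p <- p + ggplot2::geom_vline(xintercept = object$decay_distance_bp / 1e3,
                                 linetype = "dotted")
  p
}

#' @export
plot.wssgwas_scan <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.ld_curve <- function(x, ...) print(autoplot(x, ...))
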