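#' Manhattan plot of a window or site track
#'
#' @param track a track tibble (e.g. [z_transform()] or [window_xpehh()]
#'   output).
#' @param threshold optional horizontal calling threshold; drawn at the
#'   value and, for signed statistics, its negative.
#' @param signed draw the negative threshold line too.
#' @param chrom_lengths optional named lengths for the cumulative axis.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(track, threshold = NULL, signed = FALSE,
                           chrom_lengths = NULL) {
  df <- manhattan_export(track, chrom_lengths)
  gg <- ggplot2::ggplot(df[!is.na(df$value), ],
                        ggplot2::aes(x = .data$cumulative_pos,
                                     y = .data$value,
                                     colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = "cumulative position (bp)",
                  y = track_stat(track) %||% "value") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    gg <- gg + ggplot2::geom_hline(yintercept = threshold,
                                   linetype = "dashed")
    if (signed) {
      gg <- gg + ggplot2::geom_hline(yintercept = -threshold,
                                     linetype = "dashed")
    }
  }
  gg
}

#' Plot mean LD r-squared decay across distance bins
#'
#' @param decay tibble from [ld_decay()] (optionally row-bound over groups
#'   with a `group` column).
#' @return A ggplot object.
#' @export
plot_ld_decay <- function(decay) {
  decay$mid <- (decay$bin_start + decay$bin_end) / 2
  aes <- if ("group" %in% names(decay)) {
    ggplot2::aes(x = .data$mid, y = .data$mean_r2, colour = .data$group)
  } else {
    ggplot2::aes(x = .data$mid, y = .data$mean_r2)
  }
  ggplot2::ggplot(decay[!is.na(decay$mean_r2), ], aes) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "distance (bp)", y = expression(mean ~ r^2)) +
    ggplot2::theme_minimal()
}

#' Plot an EHH decay curve
#'
#' @param curve tibble from [ehh()] (optionally row-bound over alleles or
#'   directions with extra grouping columns).
#' @return A ggplot object.
#' @export
plot_ehh <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$offset, y = .data$ehh)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "distance from core (bp)", y = "EHH") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot per-group Hp profiles around a locus
#'
#' @param hp_a,hp_b window tracks from [pooled_heterozygosity()] for
#'   groups A and B.
#' @param chrom,from,to optional zoom interval.
#' @return A ggplot object.
#' @export
plot_hp_profile <- function(hp_a, hp_b, chrom = NULL, from = NULL,
                            to = NULL) {
  df <- dplyr::bind_rows(A = hp_a, B = hp_b, .id = "group")
  if (!is.null(chrom)) df <- df[df$chrom == chrom, ]
  if (!is.null(from)) df <- df[df$end > from, ]
  if (!is.null(to)) df <- df[df$start < to, ]
  df$mid <- (df$start + df$end) / 2
  ggplot2::ggplot(df[!is.na(df$value), ],
                  ggplot2::aes(x = .data$mid, y = .data$value,
                               colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (bp)", y = "Hp") +
    ggplot2::theme_minimal()
}
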