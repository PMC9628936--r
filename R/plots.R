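#' Plot matched colonies: size versus ratiometric intensity
#'
#' @param object A [match_colonies()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot partchar_matched
#' @export
autoplot.partchar_matched <- function(object, ...) {
  df <- tibble::tibble(size = (object$size_gfp + object$size_rfp) / 2,
                       intensity = object$colony_intensity,
                       saturated = object$flag_saturated)
  ggplot2::ggplot(df, ggplot2::aes(.data$size, .data$intensity,
                                   colour = .data$saturated)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "colony size (px)", y = "colony intensity (GFP/RFP)",
                  colour = "saturated") +
    ggplot2::theme_minimal()
}

#' Plot the per-tag-pair read count grid
#'
#' @param object A [read_count_report()] result.
#' @param ... Ignored.
#' @return A ggplot (forward tags as rows, reverse tags as columns).
#' @method autoplot partchar_readcounts
#' @export
autoplot.partchar_readcounts <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$rev_id, .data$fwd_id,
                                       fill = .data$n_reads)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "reverse tag", y = "forward tag", fill = "reads") +
    ggplot2::theme_minimal()
}

#' Plot measured versus input combination ratios of a library profile
#'
#' @param object A [profile_library()] result.
#' @param ... Ignored.
#' @return A ggplot: barplot of combination ratios, overlaid with input
#'   molar expectations when available.
#' @method autoplot partchar_profile
#' @export
autoplot.partchar_profile <- function(object, ...) {
  df <- object$combinations
  p <- ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$construct,
                                                       -.data$ratio),
                                        .data$ratio)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "promoter|RBS combination", y = "library ratio") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  if ("input_ratio" %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(y = .data$input_ratio),
                                 colour = "firebrick", size = 2)
  }
  p
}

#' Plot part strengths as relative units
#'
#' @param object A [part_strength()] result.
#' @param ... Ignored.
#' @return A ggplot: one bar per part with an SD-derived error bar, split
#'   by part type.
#' @method autoplot partchar_strengths
#' @export
autoplot.partchar_strengths <- function(object, ...) {
  std <- attr(object, "standard")
  df <- dplyr::mutate(tibble::as_tibble(object),
                      rel_sd = .data$sd_intensity / std$standard_intensity)
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$part_id,
                                                  -.data$relative_unit),
                                   .data$relative_unit)) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$relative_unit - .data$rel_sd,
                                        ymax = .data$relative_unit + .data$rel_sd),
                           width = 0.3) +
    ggplot2::facet_grid(. ~ part_type, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "relative unit (RPU / RRU)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the size-bias diagnostic
#'
#' @param object A [size_bias_report()] result.
#' @param ... Ignored.
#' @return A ggplot scatter with the rank correlation in the subtitle.
#' @method autoplot partchar_sizebias
#' @export
autoplot.partchar_sizebias <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$size_px,
                                            .data$colony_intensity)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = "colony size (px)", y = "colony intensity (GFP/RFP)",
      subtitle = if (is.na(object$rank_correlation)) {
        "rank correlation undefined (constant input)"
      } else {
        sprintf("Spearman rho = %.3f (n = %d)", object$rank_correlation,
                object$n)
      }) +
    ggplot2::theme_minimal()
}
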