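# ggplot2 views of the main result types.

#' Plot a multi-scale insulation profile
#'
#' One line per depth plus the scale average; called TAD boundaries can be
#' overlaid by passing the `tad_set`.
#'
#' @param object An [insulation_profile()].
#' @param tads Optional [call_tads()] result to mark boundaries.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.insulation_profile <- function(object, tads = NULL, ...) {
  prof <- dplyr::mutate(object$profile,
    depth = factor(.data$depth_bp, labels = paste0(sort(unique(.data$depth_bp)) / 1000, " kb"))
  )
  p <- ggplot2::ggplot(prof, ggplot2::aes(.data$bin, .data$score, colour = .data$depth)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "bin", y = "insulation (mean cross-window contact)",
                  colour = "depth") +
    ggplot2::theme_minimal()
  if (!is.null(tads) && length(tads$boundaries)) {
    p <- p + ggplot2::geom_vline(xintercept = tads$boundaries,
                                 linetype = "dashed", colour = "grey30")
  }
  p
}

#' Plot called TADs as a domain track
#'
#' @param object A [call_tads()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tad_set <- function(object, ...) {
  d <- dplyr::mutate(object$domains, ymin = 0, ymax = 1)
  ggplot2::ggplot(d) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = .data$ymin, ymax = .data$ymax, fill = .data$name),
      colour = "grey20", show.legend = FALSE, alpha = 0.6
    ) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = sprintf("position on %s (bp)", d$chrom[1]), y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a screen report: candidates along the locus
#'
#' Candidates drawn at their genomic position with signed labels; colour
#' encodes the number of active marks.
#'
#' @param object A [screen_locus()] report.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.screen_report <- function(object, ...) {
  x <- object$candidates
  if (!nrow(x)) {
    return(ggplot2::ggplot() +
      ggplot2::annotate("text", 0, 0, label = "no candidates") +
      ggplot2::theme_void())
  }
  pm <- (object$config$promoter_start + object$config$promoter_end) / 2
  ggplot2::ggplot(x) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end, y = 0, yend = 0,
                   colour = .data$n_active_marks),
      linewidth = 4
    ) +
    ggplot2::geom_text(
      ggplot2::aes(x = (.data$start + .data$end) / 2, y = 0.08,
                   label = .data$label),
      size = 3
    ) +
    ggplot2::geom_vline(xintercept = pm, colour = "red", linetype = "dotted") +
    ggplot2::scale_y_continuous(limits = c(-0.2, 0.2), breaks = NULL) +
    ggplot2::labs(x = sprintf("position on %s (bp)", x$chrom[1]), y = NULL,
                  colour = "active marks") +
    ggplot2::theme_minimal()
}

#' Box plot of normalized reporter intensity per construct
#'
#' The package's view of grouped reporter data: per-group boxes (median,
#' interquartile range, range) with Dunnett significance stars against the
#' control.
#'
#' @param object An [anova_dunnett()] fit.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dunnett_fit <- function(object, ...) {
  d <- object$data
  stars <- dplyr::mutate(object$comparisons,
    y = vapply(.data$group, function(g) max(d$value[d$group == g]), double(1)),
    lab = ifelse(.data$significant, "*", "ns")
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$group, .data$value)) +
    ggplot2::geom_boxplot(fill = "grey90") +
    ggplot2::geom_text(
      data = stars,
      ggplot2::aes(x = .data$group, y = .data$y, label = .data$lab),
      vjust = -0.8
    ) +
    ggplot2::labs(x = NULL, y = "GFP / RFP (normalized intensity)") +
    ggplot2::theme_minimal()
}
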