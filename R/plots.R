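#' Plot a BAF/LRR probe track with called segments
#'
#' Two stacked panels in the style of array CNV browsers: per-probe BAF
#' (heterozygous diploid probes cluster at 0.5; a duplication splits them
#' into 1/3 and 2/3 bands) and LRR, with called segments overlaid as
#' shaded rectangles.
#'
#' @param probes Probe tibble for one sample and chromosome.
#' @param segments Optional segment tibble to overlay.
#' @return A ggplot object.
#' @export
plot_array_track <- function(probes, segments = NULL) {
  long <- probes |>
    tidyr::pivot_longer(c("baf", "lrr"), names_to = "track",
      values_to = "value") |>
    dplyr::mutate(track = toupper(.data$track))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$pos, y = .data$value)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::facet_wrap(~track, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "position (bp)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(segments) && nrow(segments) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = segments,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, fill = "red", alpha = 0.15,
      inherit.aes = FALSE
    )
  }
  p
}

#' @rdname call_cnv_segments
#' @param object A `cnv_segments` tibble.
#' @method autoplot cnv_segments
#' @export
autoplot.cnv_segments <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$start, xend = .data$end,
    y = factor(.data$copy_number), yend = factor(.data$copy_number)
  )) +
    ggplot2::geom_segment(linewidth = 2, colour = "red") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "copy number") +
    ggplot2::theme_minimal()
}

#' @rdname copy_number
#' @param object A `cn_estimate` tibble.
#' @method autoplot cn_estimate
#' @export
autoplot.cn_estimate <- function(object, ...) {
  has_locus <- "locus" %in% names(object)
  p <- ggplot2::ggplot(object, ggplot2::aes(
    x = .data$sample_id, y = .data$cn,
    ymin = .data$ci_low, ymax = .data$ci_high, colour = .data$call
  )) +
    ggplot2::geom_pointrange() +
    ggplot2::geom_hline(yintercept = c(2, 3), linetype = "dashed",
      alpha = 0.4) +
    ggplot2::labs(x = NULL, y = "copy number") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
      hjust = 1))
  if (has_locus) p <- p + ggplot2::facet_wrap(~locus)
  p
}

#' @rdname run_cascade
#' @method autoplot cascade_result
#' @export
autoplot.cascade_result <- function(object, ...) {
  counts <- object$counts
  funnel <- tibble::tibble(
    stage = factor(
      c("input", "shared rare missense", "cortex-expressed", "VUS",
        "consensus-deleterious", "disease-associated", "final"),
      levels = c("input", "shared rare missense", "cortex-expressed",
        "VUS", "consensus-deleterious", "disease-associated", "final")
    ),
    n = c(counts$n_input, counts$n_survivors, counts$n_expressed,
      counts$n_vus, counts$n_consensus, counts$n_disgenet, counts$n_final)
  )
  ggplot2::ggplot(funnel, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "variants") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
      hjust = 1))
}
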