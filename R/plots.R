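# ggplot2 visualisations for the main result types.

#' Plot the indel-region map of a promoter pair
#'
#' Two horizontal promoter tracks with the length-divergent regions drawn
#' as blocks on their carriers, colored by origin call when available.
#'
#' @param regions Region tibble from [segment_length_divergent_regions()]
#'   or [compare_promoters()].
#' @param promoter_lengths Optional named vector of promoter lengths (names
#'   matching the carrier ids) to scale the tracks.
#' @return A ggplot object.
#' @export
plot_region_map <- function(regions, promoter_lengths = NULL) {
  carriers <- sort(unique(regions$carrier))
  if (!is.null(promoter_lengths)) carriers <- names(promoter_lengths)
  df <- dplyr::mutate(regions,
                      y = match(.data$carrier, carriers),
                      fill = if ("call" %in% names(regions)) .data$call else "region")
  p <- ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start, xmax = .data$end,
      ymin = .data$y - 0.3, ymax = .data$y + 0.3, fill = .data$fill
    )) +
    ggplot2::geom_text(ggplot2::aes(
      x = (.data$start + .data$end) / 2, y = .data$y, label = .data$region
    ), size = 3) +
    ggplot2::scale_y_continuous(breaks = seq_along(carriers), labels = carriers,
                                limits = c(0.5, length(carriers) + 0.5)) +
    ggplot2::labs(x = "position (bp)", y = NULL, fill = NULL,
                  title = "Length-divergent promoter regions")
  if (!is.null(promoter_lengths)) {
    segs <- tibble(y = seq_along(carriers), xend = unname(promoter_lengths))
    p <- p + ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = 1, xend = .data$xend, y = .data$y, yend = .data$y),
      linewidth = 0.3, color = "grey40"
    )
  }
  p
}

#' Plot motif hits along a sequence
#'
#' @param object A hit tibble from [scan_sequence()].
#' @param ... Unused.
#' @return A ggplot object (position vs score, shaped by strand).
#' @export
plot_motif_hits <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$start, y = .data$score,
                                       shape = .data$strand)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "position (bp)", y = "log-odds score (nats)",
                  title = "PWM hits")
}

#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.clock_tree <- function(object, ...) {
  td <- tidy(object)
  tr <- object$tree
  nt <- ape::Ntip(tr)
  # tip y-positions in plotting order, internal nodes midway between children
  y <- numeric(nt + tr$Nnode)
  y[seq_len(nt)] <- seq_len(nt)
  po <- ape::reorder.phylo(tr, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]
    kids <- po$edge[po$edge[, 1L] == p, 2L]
    y[p] <- mean(y[kids])
  }
  edges <- tibble(
    x = object$ages[tr$edge[, 1L]], xend = object$ages[tr$edge[, 2L]],
    y = y[tr$edge[, 2L]], yend = y[tr$edge[, 2L]],
    yp = y[tr$edge[, 1L]]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges, ggplot2::aes(
      x = .data$x, xend = .data$xend, y = .data$y, yend = .data$yend
    )) +
    ggplot2::geom_segment(data = edges, ggplot2::aes(
      x = .data$x, xend = .data$x, y = .data$yp, yend = .data$y
    )) +
    ggplot2::geom_text(
      data = td[td$is_tip, ],
      ggplot2::aes(x = .data$age, y = y[td$node[td$is_tip]], label = .data$label),
      hjust = 1.1, size = 3
    ) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "age (MY)", y = NULL,
                  title = "Calibrated linearized tree") +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank())
}

#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.insertion_dating <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(g) +
    ggplot2::geom_pointrange(ggplot2::aes(
      x = "element insertion", y = .data$age_point,
      ymin = .data$age_low, ymax = .data$age_high
    )) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$reference_age),
                        linetype = "dashed") +
    ggplot2::annotate("text", x = 1.3, y = g$reference_age,
                      label = "reference (duplication)", vjust = -0.5, size = 3) +
    ggplot2::labs(x = NULL, y = "age (MY)",
                  title = sprintf("Insertion dating: %s", g$verdict))
}
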