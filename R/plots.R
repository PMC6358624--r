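#' Heat map of a coancestry matrix
#'
#' @param x A `coancestry_matrix` (or plain matrix).
#' @param order Optional id ordering (e.g. grouped by cluster).
#' @param cap Upper quantile at which values are truncated for display
#'   (default 0.9, so strong within-cluster drift does not wash out the
#'   bulk of the variation).
#' @return A ggplot object.
#' @export
plot_coancestry <- function(x, order = NULL, cap = 0.9) {
  m <- as.matrix(x)
  if (!is.null(order)) m <- m[order, order]
  df <- tibble::tibble(
    recipient = factor(rep(rownames(m), ncol(m)), levels = rev(rownames(m))),
    donor = factor(rep(colnames(m), each = nrow(m)), levels = colnames(m)),
    value = pmin(as.vector(m), stats::quantile(m[m > 0], cap)))
  ggplot2::ggplot(df, ggplot2::aes(.data$donor, .data$recipient,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "coancestry (cM)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank()) +
    ggplot2::labs(x = "donor", y = "recipient")
}

#' Drift-test matrix plot
#'
#' Tiles of -log10(p) for each recipient/source cluster pair; flagged pairs
#' (p below the reporting threshold) are outlined.
#'
#' @param x A `drift_test` from [bootstrap_coancestry_test()].
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.drift_test <- function(x, ...) {
  df <- tibble::as_tibble(x)
  ggplot2::ggplot(df, ggplot2::aes(.data$source, .data$recipient,
                                   fill = -log10(.data$p))) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = df[df$flagged, ], fill = NA, colour = "black",
                       linewidth = 1) +
    ggplot2::scale_fill_viridis_c(name = "-log10(p)") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "source cluster", y = "recipient cluster")
}

#' Ancestry-profile bars with bootstrap intervals
#'
#' @param x Output of [bootstrap_profile_intervals()] (optionally with a
#'   `cluster` column) or a bare `ancestry_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_profile <- function(x, ...) {
  df <- tibble::as_tibble(x)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$coefficient)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = NULL, y = "mixture coefficient")
  if (all(c("lo95", "hi95") %in% names(df)))
    p <- p + ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo95,
                                                 ymax = .data$hi95),
                                    width = 0.25)
  if ("cluster" %in% names(df))
    p <- p + ggplot2::facet_wrap(~cluster)
  p
}

#' Coancestry curves with fitted exponentials
#'
#' @param x A `coancestry_curves` object (its `tbl` is plotted) and, if
#'   supplied, the shared-rate fit overlay from an `admixture_event`.
#' @param event Optional `admixture_event` whose fitted curves to overlay.
#' @return A ggplot object.
#' @export
plot_coancestry_curves <- function(x, event = NULL) {
  tbl <- if (inherits(x, "coancestry_curves")) x$tbl else x
  tbl$pair <- paste(tbl$group_a, tbl$group_b, sep = " - ")
  p <- ggplot2::ggplot(tbl, ggplot2::aes(.data$bin_mid, .data$value)) +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::facet_wrap(~pair, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "genetic distance (cM)", y = "ancestry covariance")
  if (!is.null(event)) {
    f <- event$fit
    pred <- tbl
    idx <- cbind(match(tbl$group_a, rownames(f$A)),
                 match(tbl$group_b, colnames(f$A)))
    pred$fit <- f$A[idx] * exp(-f$lambda * tbl$bin_mid) + f$C[idx]
    p <- p + ggplot2::geom_line(data = pred,
                                ggplot2::aes(y = .data$fit),
                                colour = "firebrick")
  }
  p
}

#' Raster map of a smoothed grid coefficient
#'
#' @param grid_profiles Output of [grid_profiles()] (or
#'   [cluster_density_grid()], with `fill_var = "contribution"` and
#'   `facet_var = "cluster"`).
#' @param group Donor group (or cluster) to map.
#' @param placed Optional [place_individuals()] tibble to overlay points.
#' @param fill_var,facet_var Column names for fill and selection.
#' @return A ggplot object.
#' @export
plot_grid_map <- function(grid_profiles, group, placed = NULL,
                          fill_var = "coefficient", facet_var = "group") {
  df <- grid_profiles[grid_profiles[[facet_var]] == group, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$cell_x, .data$cell_y,
                                        fill = .data[[fill_var]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = group) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "km (east)", y = "km (north)")
  if (!is.null(placed))
    p <- p + ggplot2::geom_point(data = placed[placed$retained, ],
                                 ggplot2::aes(.data$display_x,
                                              .data$display_y),
                                 inherit.aes = FALSE, size = 0.5,
                                 colour = "grey30")
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
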