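#' Plot the fitted methylation mixture
#'
#' Mixture and component densities on the normalized log-IPD scale,
#' optionally over a histogram of the data used for fitting.
#'
#' @param object A `samosa_mixture`.
#' @param z Optional vector of normalized IPDs to show as a histogram.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.samosa_mixture <- function(object, z = NULL, ...) {
  lim <- range(object$mu0 - 4 * object$sd0, object$mu1 + 4 * object$sd1)
  grid <- seq(lim[1], lim[2], length.out = 512)
  dens <- tibble::tibble(
    z = rep(grid, 3),
    density = c(object$w0 * dnorm(grid, object$mu0, object$sd0),
                object$w1 * dnorm(grid, object$mu1, object$sd1),
                object$w0 * dnorm(grid, object$mu0, object$sd0) +
                  object$w1 * dnorm(grid, object$mu1, object$sd1)),
    component = rep(c("unmethylated", "methylated", "mixture"),
                    each = length(grid))
  )
  p <- ggplot2::ggplot(dens, ggplot2::aes(.data$z, .data$density,
                                          colour = .data$component))
  if (!is.null(z)) {
    p <- p + ggplot2::geom_histogram(
      data = tibble::tibble(z = z[is.finite(z)]),
      ggplot2::aes(x = .data$z, y = ggplot2::after_stat(.data$density)),
      inherit.aes = FALSE, bins = 80, fill = "grey85", colour = NA
    )
  }
  p + ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "normalized log2 IPD", y = "density",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-cluster mean modification profiles
#'
#' @param summary Tibble from [summarize_clusters()] (needs the `profile`
#'   list-column).
#' @return A ggplot of mean modification probability along the 5' end of
#'   the molecules, one facet line per cluster.
#' @export
plot_cluster_profiles <- function(summary) {
  assert_that("profile" %in% names(summary),
              "summarize_clusters() must be run with tracks")
  df <- summary |>
    dplyr::select("cluster", "profile") |>
    tidyr::unnest_longer("profile", values_to = "mean_prob",
                         indices_to = "position") |>
    dplyr::mutate(position = .data$position - 1L)
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$mean_prob)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::facet_wrap(~cluster, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "position along molecule (bp)",
                  y = "mean modification probability") +
    ggplot2::theme_minimal()
}

#' Plot per-cluster mean autocorrelograms
#'
#' @param summary Tibble from [summarize_clusters()] (needs `mean_acg`).
#' @return A ggplot, one line per cluster.
#' @export
plot_cluster_autocorrelograms <- function(summary) {
  assert_that("mean_acg" %in% names(summary),
              "summarize_clusters() must be run with acgs")
  df <- summary |>
    dplyr::select("cluster", "mean_acg") |>
    tidyr::unnest_longer("mean_acg", values_to = "correlation",
                         indices_to = "lag") |>
    dplyr::mutate(lag = .data$lag - 1L)
  ggplot2::ggplot(df, ggplot2::aes(.data$lag, .data$correlation,
                                   colour = factor(.data$cluster))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag (bp)", y = "autocorrelation",
                  colour = "cluster") +
    ggplot2::theme_minimal()
}

#' Histogram of single-molecule NRL estimates
#'
#' @param nrl_calls Tibble from [find_nrl_peak()].
#' @param assignment Optional cluster assignment to facet by cluster.
#' @param binwidth Histogram bin width in bp.
#' @return A ggplot.
#' @export
plot_nrl_distribution <- function(nrl_calls, assignment = NULL, binwidth = 5) {
  df <- dplyr::filter(nrl_calls, .data$peak_found)
  if (!is.null(assignment)) {
    df <- dplyr::inner_join(df, assignment, by = "molecule_id")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$nrl_lag)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "#2c7fb8") +
    ggplot2::labs(x = "single-molecule NRL (bp)", y = "molecules") +
    ggplot2::theme_minimal()
  if (!is.null(assignment)) {
    p <- p + ggplot2::facet_wrap(~cluster, labeller = ggplot2::label_both,
                                 scales = "free_y")
  }
  p
}

#' Plot a fragment-end cut profile around motifs
#'
#' @param profile Tibble from [cut_profile()].
#' @return A ggplot of cuts per molecule against offset from the motif
#'   midpoint.
#' @export
plot_cut_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(.data$offset, .data$per_molecule)) +
    ggplot2::geom_line(colour = "#d95f0e") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "offset from motif midpoint (bp)",
                  y = "cuts per molecule") +
    ggplot2::theme_minimal()
}

#' Heatmap of a cluster-by-category enrichment scan
#'
#' Tiles show log2 odds ratios; significant pairs (q below the scan's
#' threshold) are marked.
#'
#' @param enrichment Tibble from [enrichment_scan()].
#' @return A ggplot.
#' @export
plot_enrichment <- function(enrichment) {
  df <- dplyr::mutate(
    enrichment,
    log2_or = log2(pmin(pmax(.data$odds_ratio, 1 / 64), 64))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$category, factor(.data$cluster),
                                   fill = .data$log2_or)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(data = dplyr::filter(df, .data$significant),
                       ggplot2::aes(label = "*"), size = 5) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = NULL, y = "cluster", fill = "log2 OR") +
    ggplot2::theme_minimal()
}
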