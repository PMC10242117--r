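#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a pairwise maximum-entropy fit
#'
#' One row per free parameter: the `N` biases (`h[i]`) and the `N(N-1)/2`
#' couplings (`J[i,j]`, upper triangle).
#'
#' @param x An `mem_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `type`, `i`, `j`, `estimate`.
#' @method tidy mem_fit
#' @export
tidy.mem_fit <- function(x, ...) {
  n <- x$params$n_rois
  ut <- which(upper.tri(x$params$J), arr.ind = TRUE)
  dplyr::bind_rows(
    tibble::tibble(term = paste0("h[", seq_len(n), "]"), type = "bias",
                   i = seq_len(n), j = NA_integer_, estimate = x$params$h),
    tibble::tibble(term = paste0("J[", ut[, 1], ",", ut[, 2], "]"),
                   type = "coupling", i = as.integer(ut[, 1]),
                   j = as.integer(ut[, 2]),
                   estimate = x$params$J[ut]))
}

#' Glance at a pairwise maximum-entropy fit
#'
#' @param x An `mem_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_rois`, `d2_bits`, `n_iter`, `converged`,
#'   `max_mismatch` (largest absolute residual moment error).
#' @method glance mem_fit
#' @export
glance.mem_fit <- function(x, ...) {
  gh <- x$target_moments$mean - x$model_moments$mean
  gJ <- x$target_moments$corr - x$model_moments$corr
  diag(gJ) <- 0
  tibble::tibble(n_rois = x$params$n_rois, d2_bits = x$d2_bits,
                 n_iter = x$n_iter, converged = x$converged,
                 max_mismatch = max(abs(gh), abs(gJ)))
}

#' Tidy a disconnectivity graph
#'
#' @param x A `disconnectivity` object.
#' @param ... Unused.
#' @return The minima tibble (`state`, `energy`).
#' @method tidy disconnectivity
#' @export
tidy.disconnectivity <- function(x, ...) x$minima

#' Tidy a state labeling
#'
#' @param x A `state_labeling` object.
#' @param ... Unused.
#' @return Tibble of minima with `state`, `energy`, `label` and the size
#'   and stationary occupancy of each basin.
#' @method tidy state_labeling
#' @export
tidy.state_labeling <- function(x, ...) {
  sizes <- table(factor(x$basins, levels = x$minima$state))
  out <- x$minima
  out$basin_size <- as.integer(sizes)
  out
}

#' Plot the energy profile of a landscape
#'
#' Energies of all patterns in state-index order with local minima
#' highlighted.
#'
#' @param object An `energy_landscape`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot energy_landscape
#' @export
autoplot.energy_landscape <- function(object, ...) {
  df <- tibble::tibble(state = seq_along(object$energies) - 1L,
                       energy = object$energies)
  minima <- find_local_minima(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$state, y = .data$energy)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_point(data = minima, colour = "red", size = 2) +
    ggplot2::labs(x = "state index", y = "energy",
                  title = "Energy landscape",
                  subtitle = paste(nrow(minima), "local minima (red)")) +
    ggplot2::theme_minimal()
}

#' Plot a disconnectivity tree
#'
#' The classic branching diagram: each leaf is a local minimum drawn at its
#' energy, and two branches join at the height of the energy barrier
#' separating their basins.
#'
#' @param object A `disconnectivity` object.
#' @param labeling Optional [classify_states()] result used to colour
#'   leaves by major/minor class.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot disconnectivity
#' @export
autoplot.disconnectivity <- function(object, labeling = NULL, ...) {
  minima <- object$minima
  n_min <- nrow(minima)
  if (n_min == 1L) {
    df <- tibble::tibble(x = 1, y = minima$energy, state = minima$state)
    return(ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
             ggplot2::geom_point() + ggplot2::theme_minimal())
  }
  hc <- stats::hclust(stats::as.dist(object$barrier), method = "single")
  leaf_x <- order(hc$order)
  comp_x <- as.list(leaf_x)
  comp_top <- as.list(minima$energy)
  comp_of <- seq_len(n_min)
  segs <- list()
  merges <- object$merges[order(object$merges$barrier), ]
  for (i in seq_len(nrow(merges))) {
    b <- merges$barrier[i]
    c1 <- comp_of[merges$left[[i]][1]]
    c2 <- comp_of[merges$right[[i]][1]]
    x1 <- comp_x[[c1]]; x2 <- comp_x[[c2]]
    segs[[length(segs) + 1L]] <- tibble::tibble(
      x = c(x1, x2, min(x1, x2)), xend = c(x1, x2, max(x1, x2)),
      y = c(comp_top[[c1]], comp_top[[c2]], b), yend = c(b, b, b))
    keep <- min(c1, c2)
    comp_of[comp_of %in% c(c1, c2)] <- keep
    comp_x[[keep]] <- mean(c(x1, x2))
    comp_top[[keep]] <- b
  }
  seg_df <- dplyr::bind_rows(segs)
  leaf_df <- tibble::tibble(x = leaf_x, y = minima$energy,
                            state = minima$state,
                            label = if (!is.null(labeling)) labeling$minima$label else "minimum")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg_df,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_point(data = leaf_df,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$label), size = 2.5) +
    ggplot2::labs(x = NULL, y = "energy", title = "Disconnectivity graph") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Compare a dynamic metric across groups
#'
#' Box plots of a per-subject metric by group, the standard display for the
#' appearance-frequency, transition-frequency and duration contrasts.
#'
#' @param metrics The `metrics` tibble of a [run_landscape_pipeline()]
#'   result.
#' @param metric Metric column to plot.
#' @return A ggplot object.
#' @export
plot_metric_by_group <- function(metrics, metric = "freq_minor") {
  stopifnot(metric %in% names(metrics))
  ggplot2::ggplot(metrics, ggplot2::aes(x = .data$group,
                                        y = .data[[metric]],
                                        fill = .data$group)) +
    ggplot2::geom_boxplot(alpha = 0.6, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Scatter a metric against the clinical score
#'
#' @param metrics The `metrics` tibble of a pipeline result.
#' @param metric Metric column.
#' @param score_col Score column.
#' @return A ggplot object with a least-squares line.
#' @export
plot_metric_vs_score <- function(metrics, metric = "freq_minor",
                                 score_col = "score") {
  stopifnot(metric %in% names(metrics), score_col %in% names(metrics))
  ggplot2::ggplot(metrics, ggplot2::aes(x = .data[[score_col]],
                                        y = .data[[metric]])) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$group), alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black", linewidth = 0.5) +
    ggplot2::labs(x = score_col, y = metric) +
    ggplot2::theme_minimal()
}
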