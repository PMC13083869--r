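#' Tidy the per-event log of an assembly run
#'
#' @param x An `assembly_trajectory`.
#' @param ... Unused.
#' @return Tibble with one row per assembly event (mechanism, parent or
#'   invader connectivity, survival, extinctions triggered, convergence,
#'   richness after the event).
#' @export
tidy.assembly_trajectory <- function(x, ...) x$events

#' One-row summary of an assembly run's final community
#'
#' @param x An `assembly_trajectory`.
#' @param ... Unused.
#' @return One-row tibble: final `S`, `L`, `connectance`, `complexity`,
#'   type proportions, total extinctions, survival rate of newcomers, and
#'   the number of non-converged relaxations.
#' @export
glance.assembly_trajectory <- function(x, ...) {
  fin <- snapshot_metrics(x$final$comm, x$config$n_events)
  fin$n_extinctions <- sum(x$events$n_extinct)
  fin$survival_rate <- mean(x$events$survived)
  fin$n_nonconverged <- x$n_nonconverged
  fin$scenario <- x$config$scenario
  fin[, c("scenario", setdiff(names(fin), c("scenario", "event")))]
}

#' Plot the structural trajectory of an assembly run
#'
#' Richness, connectance and complexity against assembly events.
#'
#' @param object An `assembly_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.assembly_trajectory <- function(object, ...) {
  df <- object$snapshots |>
    tidyr::pivot_longer(c("S", "connectance", "complexity"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$event, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "assembly event", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a distribution summary (MAD or correlation distribution)
#'
#' Probability density over the value grid, with the raw values available
#' as a rug.
#'
#' @param object A `dist_summary`.
#' @param rug Show raw values as a rug layer.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dist_summary <- function(object, rug = FALSE, ...) {
  df <- tibble::tibble(value = object$grid, density = object$density)
  pl <- ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$density)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "value", y = "probability density") +
    ggplot2::theme_minimal()
  if (rug)
    pl <- pl + ggplot2::geom_rug(data = tibble::tibble(v = object$values),
                                 ggplot2::aes(x = .data$v), inherit.aes = FALSE,
                                 alpha = 0.3)
  pl
}

#' Plot scenario trajectory summaries
#'
#' Mean complexity (or another summarised metric) per scenario over
#' assembly events, with standard-error bars.
#'
#' @param summary The `summary` tibble from [run_trajectory()].
#' @param metric One of the summarised metrics (default `"complexity"`).
#' @return A ggplot object.
#' @export
plot_trajectory_summary <- function(summary, metric = "complexity") {
  mcol <- paste0(metric, "_mean")
  scol <- paste0(metric, "_se")
  stopifnot(mcol %in% names(summary))
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$event, y = .data[[mcol]],
                                        colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data[[mcol]] - .data[[scol]],
                                          ymax = .data[[mcol]] + .data[[scol]]),
                             size = 0.2) +
    ggplot2::labs(x = "assembly event", y = metric, colour = "scenario") +
    ggplot2::theme_minimal()
}
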