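#' Plot a simulation run
#'
#' Space-time heat map of either field, or the time series at the probe
#' location.
#'
#' @param object An [simulate_rd()] result.
#' @param what `"heatmap"` or `"series"`.
#' @param field `"N"` (population) or `"u"` (control).
#' @param probe Probe location for `what = "series"` (default: domain
#'   midpoint).
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.rdlf_sim <- function(object, what = c("heatmap", "series"),
                              field = c("N", "u"), probe = NULL, ...) {
  what <- match.arg(what)
  field <- match.arg(field)
  if (what == "heatmap") {
    df <- as_tibble(object)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$x,
                                     fill = .data[[field]])) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(name = field) +
      ggplot2::labs(
        x = "time", y = "space",
        title = sprintf("%s(x, t) at tau = %s", field, format(object$tau))
      )
  } else {
    if (is.null(probe)) probe <- object$params$l * pi / 2
    ip <- which.min(abs(object$x - probe))
    df <- tibble(t = object$t, value = object[[field]][ip, ])
    ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value)) +
      ggplot2::geom_line() +
      ggplot2::labs(
        x = "time", y = field,
        title = sprintf("%s at x = %.3f, tau = %s", field,
                        object$x[ip], format(object$tau))
      )
  }
}

#' @export
ggplot2::autoplot

#' Plot a delay sweep
#'
#' Oscillation amplitude at the probe against the delay, annotated with the
#' classification of each run; useful for visualizing the Hopf onset and the
#' supercritical amplitude growth.
#'
#' @param sweep A [delay_sweep()] table.
#' @param tau0 Optional critical delay to mark with a vertical line.
#' @return A ggplot object.
#' @export
plot_delay_sweep <- function(sweep, tau0 = NULL) {
  gg <- ggplot2::ggplot(sweep, ggplot2::aes(x = .data$tau, y = .data$amplitude,
                                            colour = .data$classification)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(ggplot2::aes(group = 1), colour = "grey50",
                       linewidth = 0.3) +
    ggplot2::labs(x = "delay tau", y = "oscillation amplitude")
  if (!is.null(tau0)) {
    gg <- gg + ggplot2::geom_vline(xintercept = tau0, linetype = "dashed")
  }
  gg
}
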