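# Tidiers and plotting methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a pulse-wave-velocity fit
#'
#' @param x a `pwv_result`.
#' @param ... unused.
#' @return A tibble with one row per analysis plane: `arc_position_mm`,
#'   `delay_ms`, `fitted_delay_ms`.
#' @method tidy pwv_result
#' @export
tidy.pwv_result <- function(x, ...) {
  tibble::tibble(
    arc_position_mm = x$arc_positions,
    delay_ms = x$delays,
    fitted_delay_ms = x$fit_slope * x$arc_positions +
      (mean(x$delays) - x$fit_slope * mean(x$arc_positions))
  )
}

#' Glance at a pulse-wave-velocity fit
#'
#' @param x a `pwv_result`.
#' @param ... unused.
#' @return A one-row tibble: `pwv_m_s`, `fit_slope_ms_mm`, `fit_r2`,
#'   `n_planes`, `reliable`.
#' @method glance pwv_result
#' @export
glance.pwv_result <- function(x, ...) {
  tibble::tibble(
    pwv_m_s = x$pwv,
    fit_slope_ms_mm = x$fit_slope,
    fit_r2 = x$fit_r2,
    n_planes = length(x$delays),
    reliable = x$reliable
  )
}

#' Tidy a Bland-Altman analysis
#'
#' @param x a `bland_altman`.
#' @param ... unused.
#' @return A tibble of paired means and differences.
#' @method tidy bland_altman
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(mean = x$means, difference = x$diffs)
}

#' Glance at a Bland-Altman analysis
#'
#' @param x a `bland_altman`.
#' @param ... unused.
#' @return A one-row tibble: `bias`, `loa`, `n`.
#' @method glance bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, loa = x$loa, n = x$n)
}

#' Plot a pulse-wave-velocity fit
#'
#' Plane delays against centerline arc position with the least-squares
#' transit-time fit whose inverse slope is the pulse wave velocity.
#'
#' @param object a `pwv_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot pwv_result
#' @export
autoplot.pwv_result <- function(object, ...) {
  df <- tidy(object)
  lab <- if (object$reliable) {
    sprintf("PWV = %.2f m/s (r2 = %.3f)", object$pwv, object$fit_r2)
  } else {
    "unreliable PWV"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$arc_position_mm, y = .data$delay_ms)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted_delay_ms), linetype = 2) +
    ggplot2::labs(x = "arc position [mm]", y = "delay vs. first plane [ms]",
                  subtitle = lab)
}

#' Plot a set of through-plane flow curves
#'
#' @param object a `flow_curve_set`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot flow_curve_set
#' @export
autoplot.flow_curve_set <- function(object, ...) {
  df <- as.data.frame(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$q_ml_s,
                                   group = .data$arc_position,
                                   colour = .data$arc_position)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [ms]", y = "flow [mL/s]", colour = "arc [mm]")
}

#' Plot a Bland-Altman analysis
#'
#' @param object a `bland_altman`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$bias) +
    ggplot2::geom_hline(yintercept = object$bias + c(-1, 1) * object$loa,
                        linetype = 2) +
    ggplot2::labs(x = "mean of pair", y = "difference")
}

#' @importFrom ggplot2 .data
NULL
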