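#' Tidy and glance methods
#'
#' Broom-style accessors for fitted objects: `tidy()` returns one row per
#' estimated quantity, `glance()` a one-row summary.
#'
#' @param x a `threshold_result`, `martinsson_eval` or `sim_summary`.
#' @param ... unused.
#' @return A tibble.
#' @name accperc-tidiers
NULL

#' @rdname accperc-tidiers
#' @method tidy threshold_result
#' @export
tidy.threshold_result <- function(x, ...) {
  tibble(
    term = c("beta_star", "gamma_prime_star", "gamma_double_prime_star",
             "walk_length_factor"),
    estimate = c(x$beta_star, x$gamma_prime_star, x$gamma_double_prime_star,
                 x$walk_length_factor)
  )
}

#' @rdname accperc-tidiers
#' @method glance threshold_result
#' @export
glance.threshold_result <- function(x, ...) {
  tibble(
    beta_star = x$beta_star,
    gamma_prime_star = x$gamma_prime_star,
    gamma_double_prime_star = x$gamma_double_prime_star,
    walk_length_factor = x$walk_length_factor,
    beta_hat = x$beta_hat,
    accessible = x$accessible,
    delta = x$delta,
    residual = x$residual
  )
}

#' @rdname accperc-tidiers
#' @method tidy martinsson_eval
#' @export
tidy.martinsson_eval <- function(x, ...) {
  x$grid
}

#' @rdname accperc-tidiers
#' @method glance martinsson_eval
#' @export
glance.martinsson_eval <- function(x, ...) {
  tibble(
    classification = x$classification,
    beta = x$beta,
    max_interior = x$max_interior,
    ds_at_1 = x$ds_at_1,
    grid_n = x$grid_n,
    tol = x$tol
  )
}

#' @rdname accperc-tidiers
#' @method glance sim_summary
#' @export
glance.sim_summary <- function(x, ...) {
  tibble(
    p_hat = x$p_hat, ci_low = x$ci_low, ci_high = x$ci_high,
    hits = x$hits, reps = x$reps, beta = x$beta, L = x$L,
    method = x$method,
    mean_path_length = if (x$hits > 0) mean(x$path_lengths) else NA_real_
  )
}

#' Plot methods
#'
#' `autoplot()` methods: accessibility curves per locus count for threshold
#' scans, a `(s, r)` sign heatmap of Martinsson's function for
#' classifications, and the threshold-versus-distance curve.
#'
#' @param object a result object.
#' @param ... unused.
#' @return A ggplot object.
#' @name accperc-plots
NULL

#' @rdname accperc-plots
#' @method autoplot accperc_scan
#' @export
autoplot.accperc_scan <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$beta, y = .data$p_hat,
                               colour = factor(.data$L))) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high,
                                      fill = factor(.data$L)),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = expression(beta), y = "estimated accessibility",
                  colour = "L", fill = "L") +
    ggplot2::theme_minimal()
}

#' @rdname accperc-plots
#' @method autoplot martinsson_eval
#' @export
autoplot.martinsson_eval <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$s, y = .data$r,
                               fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#313695", mid = "white",
                                  high = "#a50026", midpoint = 0) +
    ggplot2::labs(title = sprintf("Martinsson's function at beta = %.4f (%s)",
                                  object$beta, object$classification),
                  x = "s", y = "r", fill = "M*") +
    ggplot2::theme_minimal()
}

#' @rdname accperc-plots
#' @method autoplot accperc_delta_curve
#' @export
autoplot.accperc_delta_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$delta,
                                       y = .data$beta_star)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = expression(delta), y = expression(beta^"*")) +
    ggplot2::theme_minimal()
}
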