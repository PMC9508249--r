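# ggplot2 figure methods.

#' @importFrom ggplot2 ggplot aes geom_tile geom_line geom_point geom_hline
#'   facet_wrap scale_fill_viridis_c scale_fill_gradient2 labs theme_minimal
#'   scale_y_reverse
NULL

#' @rdname make_orientation_pattern
#' @param object A `rate_map`.
#' @param ... Unused.
#' @export
autoplot.rate_map <- function(object, ...) {
  ggplot(object, aes(x = .data$col, y = .data$row, fill = .data$rate)) +
    geom_tile() +
    scale_y_reverse() +
    scale_fill_viridis_c(name = "rate (Hz)") +
    labs(title = paste0("Rate map: ", attr(object, "label")),
         x = NULL, y = NULL) +
    theme_minimal()
}

#' @rdname fit_ppf
#' @param object A `ppf_fit`.
#' @export
autoplot.ppf_fit <- function(object, ...) {
  grid <- tibble::tibble(
    dt = seq(min(object$data$dt), max(object$data$dt), length.out = 200)
  )
  grid$ppf <- ppf_model(grid$dt, object$c1, object$c2, object$tau1, object$tau2)
  ggplot(object$data, aes(x = .data$dt, y = .data$ppf)) +
    geom_point() +
    geom_line(data = grid, colour = "firebrick") +
    labs(x = "pulse interval (ms)", y = "PPF (%)",
         title = sprintf("Double-exponential PPF fit: tau1 = %.3g ms, tau2 = %.3g ms",
                         object$tau1, object$tau2)) +
    theme_minimal()
}

#' @rdname quadrant_map
#' @param object A `quadrant_map` tibble.
#' @export
autoplot.quadrant_map <- function(object, ...) {
  ggplot(object, aes(x = .data$dt1, y = .data$dt2, fill = .data$dG)) +
    geom_tile() +
    scale_fill_gradient2(low = "royalblue", mid = "white", high = "firebrick",
                         name = expression(Delta * G)) +
    geom_hline(yintercept = 0, linewidth = 0.3) +
    labs(x = expression(Delta * t[1] ~ "(ms)"),
         y = expression(Delta * t[2] ~ "(ms)"),
         title = "Triplet-STDP quadrant map") +
    theme_minimal()
}

#' @rdname run_crossbar_learning
#' @param object A `crossbar_fit`.
#' @export
autoplot.crossbar_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$epoch, y = .data$G_uS,
                 group = .data$synapse, colour = .data$role)) +
    geom_line(alpha = 0.8) +
    labs(x = "epoch", y = "conductance (uS)", colour = NULL,
         title = "Crossbar pattern learning: synaptic weights") +
    theme_minimal()
}

#' @rdname run_rearing
#' @param object A `tuning_result`.
#' @param window Epoch window of the running mean applied to the realized
#'   per-orientation rates (display only).
#' @export
autoplot.tuning_result <- function(object, window = 51, ...) {
  rt <- object$rate_trace
  smooth <- dplyr::mutate(
    dplyr::group_by(rt, .data$orientation),
    rho_y = stats::filter(.data$rho_y, rep(1 / window, window), sides = 1)
  )
  smooth <- dplyr::ungroup(smooth)
  smooth$rho_y <- as.numeric(smooth$rho_y)
  ggplot(stats::na.omit(smooth),
         aes(x = .data$epoch, y = .data$rho_y,
             colour = factor(.data$orientation))) +
    geom_line() +
    geom_line(aes(y = .data$theta), colour = "black", linetype = 2) +
    labs(x = "epoch", y = "firing rate (Hz)", colour = "orientation",
         title = paste0("Rearing (", object$protocol$condition,
                        "): responses and sliding threshold")) +
    theme_minimal()
}

#' Weight-map panel for a rearing result
#'
#' Final 9x9 weight maps of the two eyes as tile plots.
#'
#' @param result A `tuning_result`.
#' @return A ggplot object.
#' @export
plot_weight_maps <- function(result) {
  stopifnot(inherits(result, "tuning_result"))
  ggplot(result$weight_maps,
         aes(x = .data$col, y = .data$row, fill = .data$weight)) +
    geom_tile() +
    scale_y_reverse() +
    facet_wrap(~.data$eye) +
    scale_fill_viridis_c(name = "weight") +
    labs(x = NULL, y = NULL, title = "Final receptive fields") +
    theme_minimal()
}
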