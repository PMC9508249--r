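# broom-style tidiers for the fitted objects and experiment results.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname fit_ppf
#' @param x A `ppf_fit`.
#' @param ... Unused.
#' @export
tidy.ppf_fit <- function(x, ...) {
  est <- c(c1 = x$c1, c2 = x$c2, tau1 = x$tau1, tau2 = x$tau2)
  se <- if (isTRUE(x$single)) {
    rep(NA_real_, 4)  # degenerate single-phase fallback
  } else {
    se_raw <- summary(x$fit)$coefficients[, "Std. Error"]
    # the stored parameters may have the two phases swapped relative to the
    # raw fit (tau1 <= tau2 convention); remap the errors accordingly
    if (isTRUE(x$swapped)) se_raw[c("c2", "c1", "tau2", "tau1")]
    else se_raw[c("c1", "c2", "tau1", "tau2")]
  }
  tibble::tibble(term = names(est), estimate = unname(est),
                 std.error = unname(se))
}

#' @rdname fit_ppf
#' @export
glance.ppf_fit <- function(x, ...) {
  tibble::tibble(sigma = x$residual, degenerate = x$degenerate,
                 nobs = nrow(x$data))
}

#' @rdname fit_triplet_params
#' @param x A `triplet_fit`.
#' @param ... Unused.
#' @export
tidy.triplet_fit <- function(x, ...) {
  keep <- c("A2_plus", "A2_minus", "A3_plus", "A3_minus",
            "tau_plus", "tau_minus", "tau_x", "tau_y")
  tibble::tibble(term = keep, estimate = unlist(x$params[keep], use.names = FALSE))
}

#' @rdname fit_triplet_params
#' @export
glance.triplet_fit <- function(x, ...) {
  tibble::tibble(rms = x$residual, constraint_ok = x$constraint_ok,
                 nobs = length(x$observed), convergence = x$convergence)
}

#' @rdname run_crossbar_learning
#' @param x A `crossbar_fit`.
#' @param ... Unused.
#' @export
tidy.crossbar_fit <- function(x, ...) {
  hi <- max(x$final$rate)
  dplyr::mutate(x$weight_trace,
                role = ifelse(x$final$rate[.data$synapse] == hi,
                              "pattern", "background"))
}

#' @rdname run_crossbar_learning
#' @export
glance.crossbar_fit <- function(x, ...) {
  hi <- max(x$final$rate)
  pat <- x$final$G_uS[x$final$rate == hi]
  bg <- x$final$G_uS[x$final$rate < hi]
  tail_n <- max(1L, ceiling(nrow(x$rate_trace) * 0.1))
  tail_tr <- utils::tail(x$rate_trace, tail_n)
  tibble::tibble(
    epochs = nrow(x$rate_trace),
    min_pattern_G = min(pat),
    max_background_G = if (length(bg)) max(bg) else NA_real_,
    separated = if (length(bg)) min(pat) > max(bg) else NA,
    rho_y = mean(tail_tr$rho_y),
    theta = mean(tail_tr$theta)
  )
}

#' @rdname run_rearing
#' @param x A `tuning_result`.
#' @param ... Unused.
#' @export
tidy.tuning_result <- function(x, ...) {
  x$rate_trace
}

#' @rdname run_rearing
#' @export
glance.tuning_result <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(condition = x$protocol$condition,
                                  epochs = x$protocol$epochs),
                   selectivity_metrics(x))
}
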