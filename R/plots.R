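#' Plot simulated profiles with the analytic prediction overlaid
#'
#' Draws the simulated motor density, roadblock density and motor velocity
#' along the track and, when `theory = TRUE`, the closed-form relaxation
#' curves scaled to the post-formation plateau values estimated from the
#' data (the theory fixes relative changes and the decay length; the
#' absolute plateaus are taken from the tail of the profile).
#'
#' @param profile tibble from [estimate_profiles()].
#' @param params a [model_params()]; needed for the theory overlay.
#' @param theory overlay the analytic curves?
#' @return a ggplot object, facetted by observable.
#' @export
plot_profiles <- function(profile, params = NULL, theory = !is.null(params)) {
  long <- tidyr::pivot_longer(profile, c("rho_m", "rho_rb", "v_m"),
                              names_to = "observable", values_to = "value")
  gg <- ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$value)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::facet_wrap(~observable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "position (bp)", y = NULL) +
    ggplot2::theme_minimal()
  if (theory) {
    stopifnot(!is.null(params))
    rel <- relative_profiles(profile$x, params)
    tail_n <- max(5L, nrow(profile) %/% 5L)
    plateau <- function(col) mean(tail(profile[[col]], tail_n), na.rm = TRUE)
    th <- tibble(
      x = rep(profile$x, 3),
      observable = rep(c("rho_m", "rho_rb", "v_m"), each = nrow(profile)),
      value = c(plateau("rho_m") * rel$rho_m_rel,
                plateau("rho_rb") * rel$rho_rb_rel,
                params$k_tp * rel$v_m_rel)
    )
    gg <- gg + ggplot2::geom_line(data = th, colour = "red")
  }
  gg
}
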