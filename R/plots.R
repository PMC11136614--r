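#' Plot mean latent trajectories of a simulated cohort
#'
#' Mean latent score per domain per wave with a ribbon of +/- 1 SD,
#' showing what the generative world implies for development.
#'
#' @param cohort An `lcs_cohort`.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(cohort) {
  lat <- cohort$latents
  doms <- dimnames(lat$y)[[2]]
  W <- lat$params$n_waves
  d <- tidyr::expand_grid(domain = doms, wave = seq_len(W))
  d$mean <- purrr::map2_dbl(d$domain, d$wave, function(dm, w) mean(lat$y[, dm, w]))
  d$sd <- purrr::map2_dbl(d$domain, d$wave, function(dm, w) stats::sd(lat$y[, dm, w]))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$wave, y = .data$mean,
                                  colour = .data$domain, fill = .data$domain)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Wave", y = "Latent score") +
    ggplot2::theme_minimal()
}

#' Plot a measurement-invariance sequence
#'
#' CFI per constraint level with the delta-CFI drops annotated; steps
#' flagged as violations are highlighted.
#'
#' @param object An `lcs_invariance`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lcs_invariance
#' @export
autoplot.lcs_invariance <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$level <- factor(d$level, levels = d$level)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$level, y = .data$cfi, group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$violated), size = 3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "firebrick"),
                                 na.value = "grey70") +
    ggplot2::labs(x = NULL, y = "CFI", colour = "violated") +
    ggplot2::theme_minimal()
}
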