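# ggplot2 autoplot methods for the main result types.

#' @export
autoplot.csp_profile <- function(object, dim = c("H", "N"), ...) {
  dim <- match.arg(dim)
  col <- if (dim == "H") "dd_h_hz" else "dd_n_hz"
  stats <- attr(object, "csp_stats")
  df <- as_tibble(object) %>%
    mutate(resnum = residue_number(.data$residue)) %>%
    filter(!is.na(.data$resnum))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$resnum, y = .data[[col]])) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::labs(
      x = "residue", y = sprintf("|Δδ| (%s, Hz)", dim),
      title = "Chemical shift perturbations"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(stats)) {
    s <- stats[stats$dim == dim, ]
    p <- p +
      ggplot2::geom_hline(yintercept = s$threshold_hz, linetype = "dashed") +
      ggplot2::geom_hline(yintercept = s$floor_hz, linetype = "dotted",
                          colour = "magenta")
  }
  p
}

#' @export
autoplot.kd_fit <- function(object, plot_dim = "H", ...) {
  dmax <- object$delta_max %>% filter(.data$dim == plot_dim)
  curve <- tidyr::expand_grid(
    residue = dmax$residue,
    l_tot_uM = seq(0, max(object$l_tot_uM), length.out = 100)
  ) %>%
    left_join(dmax, by = "residue") %>%
    mutate(fitted = .data$baseline_hz + .data$delta_max_hz *
             fraction_bound(object$p_tot_uM, .data$l_tot_uM, object$kd_uM))
  ggplot2::ggplot(object$residuals %>% filter(.data$dim == plot_dim),
                  ggplot2::aes(x = .data$l_tot_uM, colour = .data$residue)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$dd)) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$fitted)) +
    ggplot2::labs(
      x = "ligand total (µM)", y = "shift displacement (Hz)",
      title = sprintf("Global 1:1 fit: K_d = %.3g mM", object$kd_uM / 1000)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fa_fit <- function(object, ...) {
  grid <- tibble(conc = seq(min(object$data$conc), max(object$data$conc),
                            length.out = 200)) %>%
    mutate(fitted = object$r_free + (object$r_bound - object$r_free) *
             fraction_bound(object$probe_tot, .data$conc, object$kd))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$conc)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$response)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fitted)) +
    ggplot2::labs(x = "titrant", y = "anisotropy",
                  title = sprintf("Direct binding: K_d = %.3g", object$kd)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ic50_fit <- function(object, ...) {
  grid <- tibble(conc = exp(seq(log(min(object$data$conc)),
                                log(max(object$data$conc)), length.out = 200))) %>%
    mutate(fitted = object$bottom + (object$top - object$bottom) /
             (1 + (.data$conc / object$ic50)^object$hill))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$conc)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$response)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fitted)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose", y = "response",
                  title = sprintf("4PL fit: IC50 = %.3g", object$ic50)) +
    ggplot2::theme_minimal()
}

#' Distance traces with block averages
#'
#' One panel per monitored pair: per-frame distances with the
#' window-averaged trace overlaid in red.
#'
#' @param series A `distance_series` or `distance_state_series`.
#' @param window_ns Averaging window for the overlay (ns).
#' @return A ggplot.
#' @export
plot_distance_traces <- function(series, window_ns = 1) {
  dcols <- distance_cols(series)
  avg <- suppressMessages(window_average(series, window_ns))
  long <- as_tibble(series) %>%
    tidyr::pivot_longer(all_of(dcols), names_to = "pair", values_to = "distance_A")
  avg_long <- avg %>%
    tidyr::pivot_longer(all_of(dcols), names_to = "pair", values_to = "distance_A")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_ps / 1000,
                                     y = .data$distance_A)) +
    ggplot2::geom_line(alpha = 0.3, linewidth = 0.2) +
    ggplot2::geom_step(data = avg_long, colour = "red") +
    ggplot2::facet_wrap(~pair) +
    ggplot2::labs(x = "time (ns)", y = "distance (Å)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.distance_stats <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$bin_mid_A, y = .data$count)) +
    ggplot2::geom_col(width = 0.5) +
    ggplot2::facet_wrap(~pair, scales = "free_y") +
    ggplot2::labs(x = "distance (Å)", y = "frames") +
    ggplot2::theme_minimal()
}
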