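# Plot methods for the package's result types.

#' @export
autoplot.isotope_envelope <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mz, y = .data$intensity)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0), linewidth = 1.2) +
    ggplot2::labs(x = "m/z (Th)", y = "relative intensity",
                  title = "Theoretical isotopic envelope") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.turnover_fit <- function(object, ...) {
  pts <- object$data |> filter(!is.na(.data$ratio))
  line <- tibble(time_h = seq(0, max(pts$time_h), length.out = 50)) |>
    mutate(log_fc = object$k_dp * .data$time_h)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$time_h, y = log(.data$ratio + 1))) +
    ggplot2::geom_line(data = line, ggplot2::aes(y = .data$log_fc),
                       colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "pulse time (h)", y = "log(r + 1)",
      title = sprintf("T1/2 = %.4g h (R2 = %.3f, QC = %s)",
                      object$t_half, object$r_squared, object$qc)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.complex_coherence <- function(object, ...) {
  df <- bind_rows(
    tibble(set = "complexes", sd = object$observed$sd_log10),
    tibble(set = "shuffled", sd = object$shuffled_sd)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set, y = .data$sd)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "SD of log10 half-life",
                  title = sprintf("Within-complex coherence (p = %.2g)",
                                  object$p_value)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.halflife_rmse <- function(object, ...) {
  ord <- object$order
  df <- tidy(object) |>
    mutate(protein_a = factor(.data$protein_a, levels = ord),
           protein_b = factor(.data$protein_b, levels = ord))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$protein_a, y = .data$protein_b,
                                   fill = .data$rmse)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "RMSE") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Pairwise log10 half-life RMSE") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
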