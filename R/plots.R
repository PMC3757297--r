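#' Plot a fitted dose-response curve
#'
#' Observed viability points with the fitted logistic curve over the measured
#' dose range, on a log10 dose axis.
#'
#' @param object a `logistic_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot logistic_fit
#' @export
autoplot.logistic_fit <- function(object, ...) {
  obs <- object$data
  xr <- range(log10(obs$dose_nM))
  grid <- tibble(dose_nM = 10^seq(xr[1], xr[2], length.out = 200))
  grid$viability <- predict(object, grid$dose_nM)
  lab <- if (!is.na(object$sample_id)) {
    paste0(object$sample_id, ifelse(is.na(object$drug), "", paste0(" / ", object$drug)))
  } else {
    object$variant
  }
  ggplot2::ggplot(obs, ggplot2::aes(dose_nM, viability)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_line(data = grid, colour = "#2166ac") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (nM)", y = "viability (fraction of control)",
                  title = lab, subtitle = paste0(object$variant, ", AIC ",
                                                 signif(object$aic, 4))) +
    ggplot2::theme_minimal()
}

#' Manhattan-style association plot
#'
#' Plots -log10 p by genomic position (when `chr`/`pos` metadata is supplied)
#' or by feature index, with an optional genome-wide significance line.
#'
#' @param assoc an association table from [pearson_scan()].
#' @param meta optional tibble with `snp_id` (or `probe_id`), `chr`, `pos`.
#' @param threshold optional p-value drawn as a horizontal reference line.
#' @return a ggplot object.
#' @export
plot_manhattan <- function(assoc, meta = NULL, threshold = NULL) {
  df <- assoc |> mutate(neg_log10_p = -log10(p))
  if (!is.null(meta)) {
    idcol <- intersect(c("snp_id", "probe_id"), names(meta))[1]
    meta <- meta |> rename(feature_id = !!idcol)
    df <- df |>
      inner_join(meta |> select(feature_id, chr, pos), by = "feature_id") |>
      arrange(chr, pos) |>
      mutate(position = row_number(),
             chr_parity = factor(as.integer(chr) %% 2))
    p_out <- ggplot2::ggplot(df, ggplot2::aes(position, neg_log10_p,
                                              colour = chr_parity)) +
      ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
      ggplot2::scale_colour_manual(values = c("#444444", "#2166ac")) +
      ggplot2::labs(x = "genomic order", y = expression(-log[10](p)))
  } else {
    df <- df |> arrange(feature_id) |> mutate(position = row_number())
    p_out <- ggplot2::ggplot(df, ggplot2::aes(position, neg_log10_p)) +
      ggplot2::geom_point(size = 0.6) +
      ggplot2::labs(x = "feature index", y = expression(-log[10](p)))
  }
  if (!is.null(threshold)) {
    p_out <- p_out + ggplot2::geom_hline(yintercept = -log10(threshold),
                                         linetype = "dashed", colour = "red")
  }
  p_out + ggplot2::theme_minimal()
}

#' Histogram of AUC phenotypes per drug
#'
#' @param auc output of [derive_auc_phenotypes()].
#' @param bins histogram bin count.
#' @return a ggplot object.
#' @export
plot_auc_distribution <- function(auc, bins = 30) {
  ggplot2::ggplot(auc, ggplot2::aes(auc)) +
    ggplot2::geom_histogram(bins = bins, fill = "#2166ac", colour = "white") +
    ggplot2::facet_wrap(~drug) +
    ggplot2::labs(x = "AUC (viability fraction x log10 nM)", y = "cell lines") +
    ggplot2::theme_minimal()
}
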