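#' Stutter ratio distributions by locus and platform
#'
#' Boxplots of the non-excluded percentage stutter ratios at each locus,
#' CE against MPS side by side.
#'
#' @param observations Stutter tibble (both platforms).
#' @param stutter_type Which stutter type to plot (default minus).
#' @return A ggplot object.
#' @export
plot_stutter_ratios <- function(observations,
                                stutter_type = "minus_one_repeat") {
  obs <- observations |>
    filter(!.data$excluded, .data$stutter_type == !!stutter_type)
  ggplot2::ggplot(obs, ggplot2::aes(
    x = .data$locus, y = .data$ratio_pct, fill = .data$platform
  )) +
    ggplot2::geom_boxplot(outlier.size = 0.6, linewidth = 0.3) +
    ggplot2::labs(
      x = NULL, y = "stutter ratio (% of parent signal)", fill = NULL
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Intra-locus balance by locus and platform
#'
#' Boxplots of multicopy heterozygote balance (minor/major signal, %)
#' with the platform thresholds drawn as dashed lines.
#'
#' @param balance Balance tibble from [compute_balance()] (both
#'   platforms may be mixed).
#' @param thresholds A [threshold_config()] for the reference lines.
#' @return A ggplot object.
#' @export
plot_intra_locus_balance <- function(balance,
                                     thresholds = threshold_config()) {
  ref <- tibble(
    platform = c("CE", "MPS"),
    threshold = c(
      thresholds$ilb_threshold_ce, thresholds$ilb_threshold_mps
    )
  )
  ggplot2::ggplot(balance, ggplot2::aes(
    x = .data$locus, y = .data$ilb_pct, fill = .data$platform
  )) +
    ggplot2::geom_boxplot(outlier.size = 0.6, linewidth = 0.3) +
    ggplot2::geom_hline(
      data = ref,
      ggplot2::aes(yintercept = .data$threshold, colour = .data$platform),
      linetype = "dashed", show.legend = FALSE
    ) +
    ggplot2::labs(
      x = NULL, y = "intra-locus balance (minor/major, %)", fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Concordance status map
#'
#' Tile map of concordance status over samples and loci; useful to spot
#' the isolated grey-zone or inconclusive records in a large run.
#'
#' @param concordance Concordance tibble from [compare_calls()].
#' @return A ggplot object.
#' @export
plot_concordance_map <- function(concordance) {
  ggplot2::ggplot(concordance, ggplot2::aes(
    x = .data$locus, y = .data$sample_id, fill = .data$status
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(
      concordant = "grey85",
      apparent_discordant_grey_zone = "#e78ac3",
      excluded_inconclusive = "#8da0cb",
      discordant = "#fc8d62"
    )) +
    ggplot2::labs(x = NULL, y = NULL, fill = "status") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 45, hjust = 1),
      axis.text.y = ggplot2::element_blank()
    )
}

#' @exportS3Method ggplot2::autoplot
autoplot.ystr_concordance <- function(object,
                                      type = c(
                                        "stutter", "balance", "concordance"
                                      ), ...) {
  type <- match.arg(type)
  switch(type,
    stutter = plot_stutter_ratios(object$stutters),
    balance = plot_intra_locus_balance(object$balance),
    concordance = plot_concordance_map(object$concordance)
  )
}
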