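# ggplot2 views of the two result types.

#' Plot per-stage attrition of a cascade run
#'
#' @param object A `cascade_result` from [run_cascade()].
#' @param ... Unused.
#' @return A ggplot: variants kept and removed at each stage, in cascade
#'   order.
#' @export
autoplot.cascade_result <- function(object, ...) {
  df <- object$summary |>
    tidyr::pivot_longer(c("n_removed", "n_kept"), names_to = "outcome",
                        values_to = "n") |>
    dplyr::mutate(
      stage = factor(.data$stage, levels = CASCADE_STAGES),
      outcome = ifelse(.data$outcome == "n_kept", "kept", "removed")
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n,
                                   fill = .data$outcome)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_manual(values = c(kept = "#2c7fb8",
                                          removed = "#d95f0e")) +
    ggplot2::labs(x = NULL, y = "variants entering stage",
                  fill = NULL, title = "Prioritization cascade attrition") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot case/control genotype frequencies
#'
#' @param object A `genotype_counts` table.
#' @param ... Unused.
#' @return A ggplot of per-arm genotype frequency (%) bars.
#' @export
autoplot.genotype_counts <- function(object, ...) {
  df <- genotype_frequencies(object) |>
    tidyr::pivot_longer(dplyr::starts_with("pct_"), names_to = "genotype",
                        values_to = "pct") |>
    dplyr::mutate(genotype = factor(
      sub("^pct_", "", .data$genotype),
      levels = c("hom_ref", "het", "hom_alt")
    ))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$genotype, y = .data$pct,
                                   fill = .data$arm)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "genotype frequency (%)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot replication genotype frequencies across variants and populations
#'
#' @param replication The tibble returned by [run_replication()].
#' @return A faceted ggplot of per-arm genotype frequencies.
#' @export
plot_replication_frequencies <- function(replication) {
  df <- replication |>
    dplyr::select("variant", "population",
                  dplyr::starts_with("pct_")) |>
    tidyr::pivot_longer(dplyr::starts_with("pct_"),
                        names_to = c("genotype", "arm"),
                        names_pattern = "pct_(hom_ref|het|hom_alt)_(case|control)",
                        values_to = "pct") |>
    dplyr::mutate(genotype = factor(.data$genotype,
                                    levels = c("hom_ref", "het", "hom_alt")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$genotype, y = .data$pct,
                                   fill = .data$arm)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(population ~ variant) +
    ggplot2::labs(x = NULL, y = "genotype frequency (%)", fill = NULL) +
    ggplot2::theme_minimal()
}
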