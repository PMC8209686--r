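#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_step geom_col
#'   geom_boxplot scale_fill_viridis_c labs facet_wrap theme_minimal
NULL

#' Heatmap of a prevalence matrix
#'
#' @param object A [build_prevalence_matrix()] result.
#' @param ... Unused.
#' @return A ggplot object: junctions by cohorts, fill = prevalence.
#' @export
autoplot.prevalence_matrix <- function(object, ...) {
  long <- as_tibble(object) |>
    mutate(junction = junction_key(.data$chrom, .data$start, .data$end, .data$strand)) |>
    pivot_longer(-c("junction_id", "chrom", "start", "end", "strand", "junction"),
                 names_to = "cohort", values_to = "prevalence")
  ggplot(long, aes(x = .data$cohort, y = .data$junction, fill = .data$prevalence)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, 1)) +
    labs(x = NULL, y = NULL, fill = "prevalence") +
    theme_minimal()
}

#' Step plot of Kaplan-Meier curves
#'
#' @param object A [km_survival()] result.
#' @param ... Unused.
#' @export
autoplot.km_curve <- function(object, ...) {
  d <- bind_rows(
    as_tibble(object),
    as_tibble(object) |> distinct(.data$group) |>
      mutate(time = 0, n_risk = NA_integer_, n_event = 0L, n_censor = 0L, surv = 1)
  ) |> arrange(.data$group, .data$time)
  ggplot(d, aes(x = .data$time, y = .data$surv, colour = .data$group)) +
    geom_step() +
    labs(x = "days", y = "S(t)", colour = NULL) +
    theme_minimal()
}

#' Bar plot of set-overlap abundances (upset-style)
#'
#' @param summary Output of [upset_summary()].
#' @return A ggplot: per cohort, percent of stage-2+ junctions per exclusive
#'   set combination (log10 scale is left to the caller).
#' @export
plot_upset_summary <- function(summary) {
  d <- summary |> filter(.data$kind == "overlap")
  ggplot(d, aes(x = .data$label, y = .data$percent)) +
    geom_col() +
    facet_wrap(~cohort) +
    labs(x = NULL, y = "% of junctions not in core normals") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bar plot of junction novelty stages per cohort
#'
#' @param novelty Output of [assign_novelty()].
#' @export
plot_novelty_summary <- function(novelty) {
  d <- novelty |> count(.data$cohort, .data$stage)
  ggplot(d, aes(x = .data$cohort, y = .data$n, fill = .data$stage)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = "junctions") +
    theme_minimal()
}
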