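# Plot helpers for the main result types. The trajectory-model curves have
# their own autoplot() method in gbtm.R.

#' Plot the eligibility attrition cascade
#'
#' @param result A `cohort_result` from [apply_eligibility()].
#' @return A ggplot bar chart of patients remaining after each criterion.
#' @export
plot_attrition <- function(result) {
  df <- result$attrition
  df$criterion <- factor(df$criterion, levels = rev(df$criterion))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_remaining,
                                   y = .data$criterion)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_remaining),
                       hjust = -0.15, size = 3) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0, .12))) +
    ggplot2::labs(x = "patients remaining", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-patient binary adherence series as a tile map
#'
#' Rows are patients ordered by MPR; columns are follow-up bins.
#'
#' @param adherence Output of [compute_adherence()].
#' @param max_patients Cap on the number of rows drawn.
#' @return A ggplot.
#' @export
plot_adherence_series <- function(adherence, max_patients = 500) {
  adherence <- dplyr::arrange(adherence, dplyr::desc(.data$mpr))
  if (nrow(adherence) > max_patients) {
    adherence <- adherence[seq_len(max_patients), ]
  }
  df <- tibble::tibble(
    patient = rep(seq_len(nrow(adherence)),
                  each = length(adherence$series[[1]])),
    bin = rep(seq_along(adherence$series[[1]]), nrow(adherence)),
    adherent = unlist(adherence$series) == 1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$patient,
                                   fill = .data$adherent)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac",
                                          `FALSE` = "#f7f7f7")) +
    ggplot2::labs(x = "follow-up bin (4 weeks)",
                  y = "patients (by decreasing MPR)",
                  fill = "bin adherent") +
    ggplot2::theme_minimal()
}

#' Plot stratified outcome means by adherence group
#'
#' @param strata Output of [stratify_outcomes()].
#' @param outcomes Optional subset of outcome names to draw.
#' @return A ggplot of group means, faceted by outcome.
#' @export
plot_outcome_strata <- function(strata, outcomes = NULL) {
  if (!is.null(outcomes)) {
    strata <- strata[strata$outcome %in% outcomes, ]
  }
  ggplot2::ggplot(strata, ggplot2::aes(x = .data$group, y = .data$mean,
                                       fill = .data$is_reference)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~outcome, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac",
                                          `FALSE` = "grey55")) +
    ggplot2::labs(x = NULL, y = "group mean") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
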