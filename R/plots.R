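.OUTCOME_LABELS <- c(
  READY = "match readily identified",
  FOUND_IN_SEARCH = "match found in search",
  UFS = "unnecessarily failed search",
  NO_MATCH_EXISTS = "no matching donor"
)

#' Stacked outcome shares per scenario
#'
#' @param tidy Tidy outcome table (`scenario`, `rep`, `outcome`,
#'   `share`), e.g. from [run_scenario()] or [scenario_grid()].
#' @return A ggplot.
#' @export
plot_outcome_shares <- function(tidy) {
  means <- tidy |>
    dplyr::summarise(share = mean(.data$share), .by = c("scenario", "outcome")) |>
    dplyr::mutate(outcome = factor(.data$outcome, levels = names(.OUTCOME_LABELS),
                                   labels = .OUTCOME_LABELS))
  ggplot2::ggplot(means,
                  ggplot2::aes(x = .data$scenario, y = .data$share,
                               fill = .data$outcome)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "share of patients", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' UFS share against the typing-request budget, by strategy
#'
#' @param sweep Budget-sweep table (`strategy`, `rep`, `budget`,
#'   `ufs_share`) from [scenario_grid()].
#' @return A ggplot.
#' @export
plot_budget_sweep <- function(sweep) {
  agg <- sweep |>
    dplyr::summarise(mean = mean(.data$ufs_share), sd = stats::sd(.data$ufs_share),
                     .by = c("strategy", "budget"))
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$budget, y = .data$mean,
                                    colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "typing-request budget", y = "UFS share",
                  colour = "strategy") +
    ggplot2::theme_minimal()
}

#' Typing-request success rates by rank and donor profile
#'
#' @param tbl Table from [request_success_by_rank()].
#' @return A ggplot.
#' @export
plot_request_success <- function(tbl) {
  ggplot2::ggplot(tbl, ggplot2::aes(x = factor(.data$rank), y = .data$success,
                                    fill = factor(.data$profile))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "request rank", y = "success rate",
                  fill = "donor profile") +
    ggplot2::theme_minimal()
}

#' @method autoplot outcome_summary
#' @export
autoplot.outcome_summary <- function(object, ...) {
  plot_outcome_shares(object$tidy)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
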