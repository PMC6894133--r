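# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' Tidy an encrypted identification study
#'
#' @param x An `he_study` from [run_study()].
#' @param ... Unused.
#' @return The per-month identification curve as a tibble.
#' @export
tidy.he_study <- function(x, ...) as_tibble(x$curve)

#' @rdname tidy.he_study
#' @return `glance()` returns a one-row summary: cohort size, total
#'   identified, milestone months (first month with 10 or more, month all
#'   identified) and total computation seconds.
#' @export
glance.he_study <- function(x, ...) {
  tibble(
    n_patients = x$n_patients,
    total_identified = max(x$curve$count),
    month_first_10 = suppressWarnings(milestone_months(x$curve, 10)),
    month_all = suppressWarnings(milestone_months(x$curve, "all")),
    lambda = x$params$lambda,
    ring_dimension = x$params$n,
    compute_seconds = sum(x$timing$seconds))
}

#' Plot the survival-time distribution of a simulated cohort
#'
#' Histogram of survival times in days; the exceptional-responder subgroup
#' elevates the right tail of the distribution.
#'
#' @param object An `he_cohort` tibble.
#' @param bin_days Bin width in days.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.he_cohort <- function(object, bin_days = 30, ...) {
  h <- survival_histogram(object, bin_days = bin_days, by_group = TRUE)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_start_days + bin_days / 2,
                                  y = .data$n, fill = .data$group)) +
    ggplot2::geom_col(width = bin_days) +
    ggplot2::labs(x = "survival time (days)", y = "patients",
                  fill = "responder group",
                  title = "Simulated survival distribution") +
    ggplot2::theme_minimal()
}

#' Plot an identification curve
#'
#' Step curve of the cumulative number of exceptional responders identified
#' by homomorphic monthly counting.
#'
#' @param object An `identification_curve` tibble.
#' @param milestones Counts to annotate (default 10 and the final total).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.identification_curve <- function(object, milestones = c(10, "all"), ...) {
  pl <- ggplot2::ggplot(object, ggplot2::aes(x = .data$month, y = .data$count)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::labs(x = "study month", y = "exceptional responders identified",
                  title = "Identification of exceptional responders") +
    ggplot2::theme_minimal()
  for (k in milestones) {
    m <- suppressWarnings(milestone_months(object, k))
    if (!is.na(m)) {
      pl <- pl + ggplot2::geom_vline(xintercept = m, linetype = "dashed",
                                     colour = "grey40")
    }
  }
  pl
}
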