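#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the membership functions of one domain
#'
#' @param vocabulary A [fuzzy_vocabulary()].
#' @param domain Which crisp domain to draw.
#' @param n Grid resolution.
#' @return A ggplot.
#' @examples
#' plot_membership(domain = "time_of_day")
#' @export
plot_membership <- function(vocabulary = fuzzy_vocabulary(),
                            domain = c("time_of_day", "day_of_week",
                                       "distance_m", "activity_level"),
                            n = 501) {
  domain <- rlang::arg_match(domain)
  grid <- membership_grid(vocabulary, domain, n)
  xlab <- switch(domain,
                 time_of_day = "time of day [h]",
                 day_of_week = "day of week [0 = Sunday]",
                 distance_m = "distance from anchor [m]",
                 activity_level = "summed selected activity probability")
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$x, y = .data$mu,
                                     colour = .data$term)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = xlab, y = expression(mu(x)), colour = NULL) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fuzzy_set <- function(object, n = 501, ...) {
  xmax <- if (object$cyclic) object$period else
    max(object$breakpoints$x) * 1.25
  xs <- seq(0, xmax, length.out = n)
  df <- tibble::tibble(x = xs, mu = eval_membership(object, xs))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$mu)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(title = object$name, x = object$domain,
                  y = expression(mu(x))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.situfuzz_accuracy <- function(object, ...) {
  ggplot2::ggplot(object$by_situation,
                  ggplot2::aes(x = .data$situation, y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$overall$percent,
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "% correct among fired ticks",
                  subtitle = sprintf("overall %.2f%%",
                                     object$overall$percent)) +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.situfuzz_loop <- function(object, ...) {
  df <- tidy.situfuzz_loop(object)
  df$situations[df$situations == ""] <- "(none)"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time,
                                        y = .data$situations)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$degree), size = 0.8) +
    ggplot2::labs(x = NULL, y = "current situation set",
                  colour = "degree") +
    ggplot2::theme_minimal()
  if (nrow(object$events) > 0) {
    p <- p + ggplot2::geom_vline(
      data = object$events,
      ggplot2::aes(xintercept = .data$time,
                   linetype = .data$event))
  }
  p
}

#' @export
autoplot.situfuzz_confirmations <- function(object, ...) {
  ggplot2::ggplot(object$by_participant,
                  ggplot2::aes(x = factor(.data$participant),
                               y = .data$percent)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(yintercept = object$overall$percent,
                        linetype = "dashed") +
    ggplot2::labs(x = "participant", y = "% confirmed correct",
                  subtitle = sprintf("overall %.2f%%",
                                     round(object$overall$percent, 2))) +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal()
}
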