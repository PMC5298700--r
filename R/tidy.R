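#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an accuracy result
#'
#' @param x A [evaluate_accuracy()] result.
#' @param ... Unused.
#' @return The per-situation breakdown as a tibble.
#' @export
tidy.situfuzz_accuracy <- function(x, ...) {
  x$by_situation
}

#' @rdname tidy.situfuzz_accuracy
#' @export
glance.situfuzz_accuracy <- function(x, ...) {
  x$overall
}

#' Tidy a confirmation analysis
#'
#' @param x An [analyze_confirmations()] result.
#' @param ... Unused.
#' @return The per-participant tibble.
#' @export
tidy.situfuzz_confirmations <- function(x, ...) {
  x$by_participant
}

#' @rdname tidy.situfuzz_confirmations
#' @export
glance.situfuzz_confirmations <- function(x, ...) {
  x$overall
}

#' Tidy a simulated inference loop
#'
#' @param x A [run_inference_loop()] result.
#' @param ... Unused.
#' @return The per-tick tibble, with situations flattened to a
#'   `;`-separated string.
#' @export
tidy.situfuzz_loop <- function(x, ...) {
  dplyr::mutate(x$ticks,
                situations = purrr::map_chr(.data$situations, paste,
                                            collapse = ";"))
}

#' @rdname tidy.situfuzz_loop
#' @export
glance.situfuzz_loop <- function(x, ...) {
  tibble::tibble(
    ticks = nrow(x$ticks),
    suspended_ticks = sum(x$ticks$suspended),
    transitions = nrow(x$history),
    unavailable_events = sum(x$events$event == "unavailable"),
    available_events = sum(x$events$event == "available"))
}
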