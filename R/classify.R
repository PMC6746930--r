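#' Classify a polyploidy event from its P-index values
#'
#' Averages the P-index values obtained for one event (possibly from several
#' checked-genome/reference combinations) and calls the event an
#' allopolyploidy when the mean strictly exceeds the threshold (default 0.3;
#' a value of exactly 0.3 is called auto). The threshold separates balanced
#' gene loss (auto-like) from consistently one-sided loss (allo-like); it is
#' a working boundary, not an absolute division.
#'
#' @param values Numeric vector of P-index values, each in \[0, 1\].
#' @param threshold Classification threshold (default 0.3).
#' @param label Event label carried into the output.
#' @return A one-row tibble: `event_label`, `n_values`, `values`
#'   (list-column), `event_pindex` (the mean), `verdict` (`"allo"` or
#'   `"auto"`), `threshold`.
#' @examples
#' classify_pindex(0.17) # auto
#' classify_pindex(0.70) # allo
#' @export
classify_pindex <- function(values, threshold = 0.3, label = "") {
  if (length(values) == 0) abort("no P-index values supplied")
  if (any(!is.finite(values)) || any(values < 0 | values > 1)) {
    abort("P-index values must lie in [0, 1]")
  }
  m <- mean(values)
  tibble(
    event_label = label,
    n_values = length(values),
    values = list(values),
    event_pindex = m,
    verdict = if (m > threshold) "allo" else "auto",
    threshold = threshold
  )
}

#' Classify every event in an event table
#'
#' Applies [classify_pindex()] to each numbered event of an event table
#' (mean over the event's rows) and summarizes the allo/auto split.
#'
#' @param events An `event_tbl` (see [read_event_table()],
#'   [polyploidy_events()]).
#' @param threshold Classification threshold (default 0.3).
#' @return A tibble of class `event_classification` with one row per event
#'   (`event`, `event_name`, `n_values`, `event_pindex`, `verdict`,
#'   `printed_nature`), plus attributes `threshold`, `n_allo`, `n_auto`,
#'   `percent_allo`; see also [glance()] on the result.
#' @examples
#' cls <- classify_event_table(polyploidy_events())
#' glance(cls) # 21 allo, 3 auto, 87.5% allo
#' @export
classify_event_table <- function(events, threshold = 0.3) {
  events <- as_tibble(events)
  if (nrow(events) == 0) abort("empty event table")
  if (any(events$pindex < 0 | events$pindex > 1)) {
    abort("P-index values must lie in [0, 1]")
  }
  out <- events |>
    group_by(.data$event) |>
    summarise(
      event_name = first(.data$event_name),
      n_values = n(),
      event_pindex = mean(.data$pindex),
      printed_nature = first(.data$printed_nature),
      .groups = "drop"
    ) |>
    mutate(verdict = ifelse(.data$event_pindex > threshold,
                            "allo", "auto")) |>
    select("event", "event_name", "n_values", "event_pindex",
           "verdict", "printed_nature") |>
    arrange(.data$event)
  attr(out, "threshold") <- threshold
  attr(out, "n_allo") <- sum(out$verdict == "allo")
  attr(out, "n_auto") <- sum(out$verdict == "auto")
  attr(out, "percent_allo") <- 100 * mean(out$verdict == "allo")
  class(out) <- c("event_classification", class(out))
  out
}

#' @export
#' @method glance event_classification
glance.event_classification <- function(x, ...) {
  tibble(
    n_events = nrow(x),
    n_allo = attr(x, "n_allo"),
    n_auto = attr(x, "n_auto"),
    percent_allo = attr(x, "percent_allo"),
    threshold = attr(x, "threshold")
  )
}

#' @export
print.event_classification <- function(x, ...) {
  cat("<event classification> threshold", attr(x, "threshold"), "->",
      attr(x, "n_allo"), "allo /", attr(x, "n_auto"), "auto (",
      format(attr(x, "percent_allo"), digits = 3), "% allo )\n")
  NextMethod()
}

#' @export
#' @method autoplot event_classification
autoplot.event_classification <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(factor(.data$event),
                                                  .data$event_pindex),
                               y = .data$event_pindex,
                               fill = .data$verdict)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"),
                        linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "polyploidy event", y = "event mean P-index",
                  fill = "verdict")
}
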