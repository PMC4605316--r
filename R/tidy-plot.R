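# broom-style tidiers and ggplot2 helpers for result objects.

#' @describeIn run_pipeline Tidy the pipeline result: one row per sequence
#'   with the final status and evidence columns (drops attributes).
#' @param x An `rsrna_pipeline` object.
#' @param ... Unused.
#' @export
tidy.rsrna_pipeline <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "rsrna_pipeline")
  attr(out, "stages") <- NULL
  attr(out, "sites") <- NULL
  attr(out, "manifest") <- NULL
  tibble::as_tibble(out)
}

#' @describeIn run_pipeline One-row summary of the run: stage survivor
#'   counts and the final candidate count.
#' @export
glance.rsrna_pipeline <- function(x, ...) {
  st <- attr(x, "stages")
  out <- tibble::as_tibble(setNames(as.list(st$n), st$stage))
  out$n_records <- nrow(x)
  out
}

#' Stage-by-stage survivor counts of a pipeline run
#'
#' @param x An `rsrna_pipeline` object.
#' @return Tibble with `stage` and `n`.
#' @export
stage_counts <- function(x) {
  stopifnot(inherits(x, "rsrna_pipeline"))
  attr(x, "stages")
}

#' Validated consensus sites of a pipeline run
#'
#' @param x An `rsrna_pipeline` object.
#' @return Site tibble with evidence flags.
#' @export
pipeline_sites <- function(x) {
  stopifnot(inherits(x, "rsrna_pipeline"))
  attr(x, "sites")
}

#' Plot a recurrence spectrum
#'
#' Number of sRNAs present in at least k conditions, with the
#' interaction-associated fraction overlaid.
#'
#' @param object An `rsrna_spectrum` tibble from
#'   [recurrence_spectrum_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rsrna_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$n_srnas), fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(
      y = .data$frac_associated * max(.data$n_srnas)),
      color = "firebrick", linewidth = 1) +
    ggplot2::scale_y_continuous(
      name = "sRNAs present in >= k conditions",
      sec.axis = ggplot2::sec_axis(~ . / max(object$n_srnas),
                                   name = "fraction AGO/CLASH-associated")) +
    ggplot2::labs(x = "recurrence level k (conditions)") +
    ggplot2::theme_minimal()
}

#' Plot a repeat-consensus meta-profile
#'
#' @param object An `rsrna_profile` tibble from [consensus_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rsrna_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$weight)) +
    ggplot2::geom_col(width = 1, fill = "steelblue") +
    ggplot2::labs(x = paste0(object$family[1], " consensus position"),
                  y = "sRNA 5' end weight") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Print a hairpin structure
#'
#' @param x An `rsrna_hairpin` object.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
print.rsrna_hairpin <- function(x, ...) {
  cat(sprintf("hairpin: %d paired bases; precursor [%d,%d); loop [%d,%d)\n",
              x$n_pairs, x$precursor[1], x$precursor[2],
              x$loop[1], x$loop[2]))
  invisible(x)
}
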