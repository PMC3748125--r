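# ggplot2 helpers for the evaluation outputs.

#' Split-VI plot
#'
#' False-merge term H(U|S) on the x-axis against false-split term H(S|U) on
#' the y-axis, one path per run.  Agglomeration moves points toward the
#' bottom-right: false merges move mostly rightward, true merges mostly
#' downward; diagonal isoclines are levels of total VI.
#'
#' @param curves a [split_vi_curve()] tibble, optionally with a `run`
#'   column distinguishing several curves.
#' @param mark_threshold draw a point at this threshold (default 0.5, the
#'   canonical operating point); `NULL` for none.
#' @return a ggplot object.
#' @export
plot_split_vi <- function(curves, mark_threshold = 0.5) {
  has_run <- "run" %in% names(curves)
  aes_base <- if (has_run) {
    ggplot2::aes(x = .data$under, y = .data$over, colour = .data$run)
  } else {
    ggplot2::aes(x = .data$under, y = .data$over)
  }
  p <- ggplot2::ggplot(curves, aes_base) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "false merges: H(U|S) [bits]",
                  y = "false splits: H(S|U) [bits]") +
    ggplot2::theme_minimal()
  if (!is.null(mark_threshold)) {
    marked <- dplyr::filter(curves, abs(.data$threshold - mark_threshold) < 1e-9)
    if (nrow(marked)) {
      p <- p + ggplot2::geom_point(data = marked, shape = 1, size = 3)
    }
  }
  p
}

#' VI breakdown plot
#'
#' Conditional entropy of each segment against its probability mass, for
#' both directions of the VI.  Hyperbolae p * h = const are isoclines of
#' contribution to the total; the top-right points are the segments that
#' dominate the error.
#'
#' @param report a [vi()] report.
#' @param top_k label the `top_k` largest contributors per side.
#' @return a ggplot object.
#' @export
plot_vi_breakdown <- function(report, top_k = 5L) {
  stopifnot(inherits(report, "vi_report"))
  df <- tidy.vi_report(report)
  lab <- df |>
    dplyr::group_by(.data$side) |>
    dplyr::slice_max(.data$contribution, n = top_k, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$contribution > 0)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$p, y = .data$h)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$contribution), alpha = 0.6) +
    ggplot2::facet_wrap(~.data$side) +
    ggplot2::labs(x = "segment mass p", y = "conditional entropy [bits]",
                  size = "p · h") +
    ggplot2::theme_minimal()
  if (nrow(lab)) {
    p <- p + ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$id),
                                vjust = -0.6, size = 3)
  }
  p
}

#' @rdname plot_vi_breakdown
#' @param object a `"vi_report"`.
#' @param ... unused.
#' @export
autoplot.vi_report <- function(object, ...) plot_vi_breakdown(object)

#' Merge-history profile
#'
#' Merge-time policy score against merge step.  Scores need not be
#' monotone: re-evaluation after a merge may lower a neighbor's score.
#'
#' @param object a `"merge_history"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.merge_history <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$step, y = .data$score)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "merge step", y = "score at merge") +
    ggplot2::theme_minimal()
}
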