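#' Plot the candidate-count profile of an (l, d) instance
#'
#' Bar chart (log scale) of the exact number of candidate motifs shared by
#' a pair of l-mers as a function of their Hamming distance `h = 0..2d`.
#' The steep growth toward small `h` is what makes reference-sequence
#' selection worthwhile: pairing against near-copies of an l-mer explodes
#' the candidate space.
#'
#' @param l Motif length in bases.
#' @param d Maximum mutations per instance.
#' @return A ggplot object.
#' @export
plot_candidate_counts <- function(l, d) {
  tab <- candidate_count_table(l, d)
  ggplot2::ggplot(tab, ggplot2::aes(x = factor(.data$h), y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Hamming distance between the pair (h)",
      y = "candidate motifs shared (log scale)",
      title = sprintf("Ball-intersection sizes for the (%d, %d) instance",
                      l, d)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn pair_search Scatter of motif scores: consensus score vs
#'   relative entropy, one point per reported motif.
#' @param object A `pair_search` object.
#' @export
autoplot.pair_search <- function(object, ...) {
  mot <- object$motifs
  if (!all(c("consensus_score", "relative_entropy") %in% names(mot))) {
    stop("search was run with score = FALSE; nothing to plot",
         call. = FALSE)
  }
  ggplot2::ggplot(mot, ggplot2::aes(x = .data$consensus_score,
                                    y = .data$relative_entropy)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "consensus score", y = "relative entropy (bits)",
                  title = sprintf("%d reported (%d, %d) motifs",
                                  nrow(mot), object$params$l,
                                  object$params$d)) +
    ggplot2::theme_minimal()
}

#' @describeIn simulate_planted Map of implant positions across sequences.
#' @param object A `planted_dataset` object.
#' @export
autoplot.planted_dataset <- function(object, ...) {
  man <- object$manifest
  p <- object$params
  ggplot2::ggplot(man, ggplot2::aes(y = .data$id)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = p$n, yend = .data$id),
                          colour = "grey80") +
    ggplot2::geom_segment(ggplot2::aes(x = .data$position,
                                       xend = .data$position + p$l,
                                       yend = .data$id),
                          linewidth = 3, colour = "firebrick") +
    ggplot2::labs(x = "position (bases)", y = NULL,
                  title = sprintf("Implanted (%d, %d) motif occurrences",
                                  p$l, p$d)) +
    ggplot2::theme_minimal()
}
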