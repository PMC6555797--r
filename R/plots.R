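#' Plot a progeny genotype distribution
#'
#' Bar chart of class probabilities, faceted by locus.
#'
#' @param object A [cross_progeny()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kp_progeny <- function(object, ...) {
  loci <- attr(object, "loci")
  long <- dplyr::bind_rows(lapply(loci, function(l) {
    marginal_locus(object, l)
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$prob)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~locus, scales = "free_x") +
    ggplot2::labs(x = "genotype class", y = "expected frequency") +
    ggplot2::theme_minimal()
}

#' Plot driver-allele frequency trajectories
#'
#' Deterministic trajectories are drawn as a single line; Wright-Fisher runs
#' as one semi-transparent line per replicate.
#'
#' @param object A [run_trajectory()] or [wright_fisher_sim()] result.
#' @param locus,allele Allele to track (required).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kp_trajectory <- function(object, locus, allele, ...) {
  freq <- driver_frequency(object, locus, allele)
  p <- ggplot2::ggplot(freq,
                       ggplot2::aes(x = .data$generation, y = .data$freq))
  if ("replicate" %in% names(freq)) {
    p <- p + ggplot2::geom_line(
      ggplot2::aes(group = .data$replicate), alpha = 0.35,
      colour = "firebrick"
    )
  } else {
    p <- p + ggplot2::geom_line(colour = "firebrick")
  }
  p +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = "generation",
      y = sprintf("frequency of %s at %s", allele, locus)
    ) +
    ggplot2::theme_minimal()
}

#' @export
plot.kp_progeny <- function(x, ...) print(autoplot.kp_progeny(x, ...))

#' @export
plot.kp_trajectory <- function(x, locus, allele, ...) {
  print(autoplot.kp_trajectory(x, locus, allele, ...))
}
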