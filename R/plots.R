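#' Chapter-median bar plot for a disease survey
#'
#' Bars show the median joint attribution fraction per retained disease
#' chapter, with bar width proportional to the number of surveyed diseases in
#' the chapter.
#'
#' @param object A `disease_survey` from [run_survey()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot disease_survey
autoplot.disease_survey <- function(object, ...) {
  ch <- object$chapters
  if (nrow(ch) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0,
                               label = "no chapters retained") +
             ggplot2::theme_void())
  }
  ch$chapter <- factor(ch$chapter, levels = ch$chapter)
  ggplot2::ggplot(ch, ggplot2::aes(x = .data$chapter, y = .data$median_af,
                                   width = .data$n_diseases /
                                     max(.data$n_diseases) * 0.9)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "disease chapter",
                  y = "median attribution fraction") +
    ggplot2::theme_minimal()
}

#' Ranked attribution-fraction plot
#'
#' Diseases ordered by their joint attribution fraction, with reference lines
#' at the tier thresholds 0.5, 0.35 and 0.2; negative values indicate
#' protective associations.
#'
#' @param survey A `disease_survey`.
#' @return A ggplot object.
#' @export
plot_af_ranking <- function(survey) {
  inc <- survey$included
  ggplot2::ggplot(inc, ggplot2::aes(x = .data$rank_af, y = .data$af)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = 0.5, colour = "red",
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0.35, colour = "orange",
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0.2, colour = "gold",
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::labs(x = "rank by attribution fraction",
                  y = "attribution fraction") +
    ggplot2::theme_minimal()
}
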