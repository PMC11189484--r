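utils::globalVariables(c("sample_id", "telomere_length", "cv", "mean_bp"))

#' Violin plot of telomere length distributions
#'
#' @param lengths_by_sample data.frame with `sample_id` and
#'   `telomere_length` (bp).
#' @return A ggplot object.
#' @export
plot_length_violin <- function(lengths_by_sample) {
  ggplot2::ggplot(lengths_by_sample,
                  ggplot2::aes(x = sample_id, y = telomere_length / 1000)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.12, outlier.shape = NA) +
    ggplot2::labs(x = NULL, y = "Telomere length (kb)") +
    ggplot2::theme_classic()
}

#' CV versus mean telomere length scatter
#'
#' The dispersion-based TMM view: each point is a sample; the dashed
#' lines mark the ALT (CV 0.8) and telomerase (CV 0.55) thresholds.
#'
#' @param summaries data.frame with `sample_id`, `mean_bp` and `cv`.
#' @param alt_cv,tert_cv Classifier thresholds drawn as guides.
#' @return A ggplot object.
#' @export
plot_cv_vs_mean <- function(summaries, alt_cv = 0.8, tert_cv = 0.55) {
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = mean_bp / 1000, y = cv)) +
    ggplot2::geom_hline(yintercept = c(tert_cv, alt_cv),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Mean telomere length (kb)",
                  y = "Coefficient of variation") +
    ggplot2::theme_classic()
}
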