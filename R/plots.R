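#' Plot methods for result objects
#'
#' `autoplot()` gives the standard diagnostic view of each result type:
#' a volcano-style plot for differential expression (signed log2 fold
#' against -log10 p for the ANOVA route, against the d statistic for the
#' SAM route), Delta-I against event coverage for splice scans, category
#' bars per treatment for response calls, and set-size bars for a top-list
#' overlap.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name diaretseq-autoplot
NULL

#' @rdname diaretseq-autoplot
#' @method autoplot de_result
#' @export
autoplot.de_result <- function(object, ...) {
  df <- tidy(object)
  if (attr(object, "route") == "anova") {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$signed_log2,
                                     y = -log10(.data$p_value),
                                     colour = .data$passes)) +
      ggplot2::geom_point(alpha = 0.6, na.rm = TRUE) +
      ggplot2::labs(x = "signed log2 fold (case vs control)",
                    y = "-log10 p (one-way ANOVA)",
                    colour = "passes")
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$signed_log2,
                                     y = .data$statistic,
                                     colour = .data$passes)) +
      ggplot2::geom_point(alpha = 0.6, na.rm = TRUE) +
      ggplot2::labs(x = "signed log2 fold (case vs control)",
                    y = "SAM d statistic", colour = "passes")
  }
}

#' @rdname diaretseq-autoplot
#' @method autoplot splice_scan
#' @export
autoplot.splice_scan <- function(object, ...) {
  df <- tidy(object) %>% filter(!.data$excluded)
  p <- attr(object, "params")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$coverage, y = .data$delta_i,
                                   colour = .data$passes)) +
    ggplot2::geom_point(alpha = 0.7, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * p$delta_cutoff,
                        linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "mean junction coverage per sample",
                  y = expression(Delta * I), colour = "passes")
}

#' @rdname diaretseq-autoplot
#' @method autoplot response_calls
#' @export
autoplot.response_calls <- function(object, ...) {
  df <- tidy(object) %>%
    mutate(category = factor(.data$category, levels = response_categories()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category)) +
    ggplot2::geom_bar() +
    ggplot2::facet_wrap(~treatment) +
    ggplot2::labs(x = NULL, y = "transcripts") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname diaretseq-autoplot
#' @method autoplot overlap_summary
#' @export
autoplot.overlap_summary <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$set, y = .data$n_features)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "features")
}

#' Observed-versus-expected SAM quantile plot
#'
#' Plots the sorted observed d statistics against the expected order
#' statistics under permutation (the SAM calling plot); under a global null
#' the points fall on the identity line.
#'
#' @param sam A `de_result` from [sam_de()].
#' @return A ggplot object.
#' @export
plot_sam_quantiles <- function(sam) {
  perm_d <- attr(sam, "perm_d")
  if (is.null(perm_d)) abort("not a sam_de() result (no permutation record)")
  df <- tibble(observed = sort(sam$statistic),
               expected = rowMeans(apply(perm_d, 2, sort)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "expected d (permutation)", y = "observed d")
}
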