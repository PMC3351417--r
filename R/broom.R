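#' Tidy and glance methods
#'
#' `tidy()` returns the per-feature (or per-event) results as a plain
#' tibble; `glance()` returns a one-row summary with the run's parameters
#' and call counts.
#'
#' @param x A `de_result`, `splice_scan`, `overlap_summary`,
#'   `response_calls` or `splice_response_sets` object.
#' @param ... Unused.
#' @return A tibble.
#' @name diaretseq-tidiers
NULL

strip_result <- function(x, drop_class) {
  class(x) <- setdiff(class(x), drop_class)
  attr(x, "params") <- NULL
  attr(x, "route") <- NULL
  attr(x, "perm_labels") <- NULL
  attr(x, "perm_d") <- NULL
  attr(x, "delta_table") <- NULL
  attr(x, "s0") <- NULL
  as_tibble(x)
}

#' @rdname diaretseq-tidiers
#' @method tidy de_result
#' @export
tidy.de_result <- function(x, ...) strip_result(x, "de_result")

#' @rdname diaretseq-tidiers
#' @method glance de_result
#' @export
glance.de_result <- function(x, ...) {
  p <- attr(x, "params")
  tibble(route = attr(x, "route"),
         n_features = nrow(x), n_pass = sum(x$passes, na.rm = TRUE),
         fc_cutoff = p$fc_cutoff,
         p_cutoff = p$p_cutoff %||% NA_real_,
         fdr_cutoff = p$fdr_cutoff %||% NA_real_,
         s0 = p$s0 %||% NA_real_,
         contrast = paste(p$contrast, collapse = " vs "))
}

#' @rdname diaretseq-tidiers
#' @method tidy splice_scan
#' @export
tidy.splice_scan <- function(x, ...) strip_result(x, "splice_scan")

#' @rdname diaretseq-tidiers
#' @method glance splice_scan
#' @export
glance.splice_scan <- function(x, ...) {
  p <- attr(x, "params")
  tibble(n_events = nrow(x), n_pass = sum(x$passes, na.rm = TRUE),
         n_excluded = sum(x$excluded, na.rm = TRUE),
         rpkm_cutoff = p$rpkm_cutoff, delta_cutoff = p$delta_cutoff,
         fdr_cutoff = p$fdr_cutoff,
         contrast = paste(p$contrast, collapse = " vs "))
}

#' @rdname diaretseq-tidiers
#' @method tidy overlap_summary
#' @export
tidy.overlap_summary <- function(x, ...) {
  tibble(set = c("only_a", "shared", "only_b"),
         n_features = c(x$only_a, x$shared, x$only_b))
}

#' @rdname diaretseq-tidiers
#' @method glance overlap_summary
#' @export
glance.overlap_summary <- function(x, ...) {
  tibble(n = x$n, shared = x$shared, only_a = x$only_a, only_b = x$only_b)
}

#' @rdname diaretseq-tidiers
#' @method tidy response_calls
#' @export
tidy.response_calls <- function(x, ...) strip_result(x, "response_calls")

#' @rdname diaretseq-tidiers
#' @method glance response_calls
#' @export
glance.response_calls <- function(x, ...) {
  p <- attr(x, "params")
  counts <- table(factor(x$category, levels = response_categories()))
  bind_cols(tibble(n_calls = nrow(x), tau = p$tau, margin = p$margin),
            as_tibble(as.list(counts)))
}

#' @rdname diaretseq-tidiers
#' @method tidy splice_response_sets
#' @export
tidy.splice_response_sets <- function(x, ...) x$membership

#' @rdname diaretseq-tidiers
#' @method glance splice_response_sets
#' @export
glance.splice_response_sets <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$category_counts, names_from = "category",
                             values_from = "n_events")
  bind_cols(tibble(n_events = nrow(x$membership)), wide)
}
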