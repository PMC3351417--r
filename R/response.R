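#' Response categories
#'
#' @return The five mutually exclusive categories a (disease, treatment)
#'   fold pair can fall in.
#' @export
response_categories <- function() {
  c("positive", "negative", "unresponsive", "side_effect", "unaffected")
}

#' Classify a treatment's effect on one transcript
#'
#' Formalizes the study's taxonomy of drug effects. With d the signed log2
#' fold of disease vs normal, t the signed log2 fold of treated vs normal,
#' theta = log2(tau) the changed/unchanged threshold and m a margin on the
#' |log2| scale:
#'
#' * disease-altered (|d| >= theta):
#'   `positive` if |t| < |d| - m (reversal toward normalcy),
#'   `negative` if |t| > |d| + m (change beyond the diabetic level),
#'   `unresponsive` otherwise;
#' * disease-unchanged (|d| < theta):
#'   `side_effect` if |t| >= theta (therapy alters an otherwise unchanged
#'   transcript), `unaffected` otherwise.
#'
#' "Toward normalcy" is strict shrinkage of |log2 fold| regardless of sign:
#' an overshoot past normal still counts as positive unless it exceeds |d|.
#' The rule is symmetric under a joint sign flip of (d, t) and, for any
#' finite inputs, yields exactly one category.
#'
#' @param d,t Signed log2 fold changes (disease vs N, treated vs N).
#' @param tau Fold-ratio threshold separating changed from unchanged
#'   (default 1.5, the study's differential-expression cutoff).
#' @param margin Non-negative margin m distinguishing responsive from
#'   unresponsive (default 0).
#' @return Character vector of categories.
#' @export
#' @examples
#' classify_response(log2(19.8), log2(3.6))    # positive
#' classify_response(-log2(1.2), -log2(2.2))   # side_effect
classify_response <- function(d, t, tau = 1.5, margin = 0) {
  if (tau < 1) abort("tau must be >= 1")
  if (margin < 0) abort("margin must be >= 0")
  theta <- log2(tau)
  if (any(!is.finite(d)) || any(!is.finite(t))) {
    abort("classify_response() needs finite d and t")
  }
  changed <- abs(d) >= theta
  out <- character(length(d))
  out[changed & (abs(t) < abs(d) - margin)] <- "positive"
  out[changed & (abs(t) > abs(d) + margin)] <- "negative"
  out[changed & out == ""] <- "unresponsive"
  out[!changed & (abs(t) >= theta)] <- "side_effect"
  out[!changed & out == ""] <- "unaffected"
  out
}

#' Classify both treatments for every transcript of a fold table
#'
#' Applies [classify_response()] to each feature for T1 (RAGE inhibitor)
#' and T2 (p38 MAPK inhibitor).
#'
#' @param folds Tibble with `feature_id` and signed log2 columns `d_log2`,
#'   `t1_log2`, `t2_log2` (the layout of [read_fold_table()]).
#' @param tau,margin See [classify_response()].
#' @return A `response_calls` tibble: two rows per feature (`treatment` in
#'   `"T1"`, `"T2"`) with `d`, `t`, `category`.
#' @export
classify_response_table <- function(folds, tau = 1.5, margin = 0) {
  need <- c("feature_id", "d_log2", "t1_log2", "t2_log2")
  if (!all(need %in% names(folds))) {
    abort(paste0("fold table needs columns: ", paste(need, collapse = ", ")))
  }
  out <- tidyr::pivot_longer(
    folds %>% select(all_of(need)),
    cols = c("t1_log2", "t2_log2"),
    names_to = "treatment", values_to = "t"
  ) %>%
    mutate(treatment = ifelse(.data$treatment == "t1_log2", "T1", "T2"),
           d = .data$d_log2,
           category = classify_response(.data$d_log2, .data$t, tau, margin)) %>%
    select("feature_id", "treatment", "d", "t", "category")
  attr(out, "params") <- list(tau = tau, margin = margin)
  class(out) <- c("response_calls", class(out))
  out
}

#' Summary counts per response category
#'
#' @param calls A `response_calls` tibble.
#' @return Tibble of counts by `treatment` and `category`.
#' @export
response_summary <- function(calls) {
  calls %>%
    count(.data$treatment, .data$category) %>%
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L)
}

#' Multi-treatment comparison of splice-event calls
#'
#' Partitions the union of passing events from the three contrasts (D vs N,
#' D_T1 vs N, D_T2 vs N) into the treatment-response categories of the
#' study's four-set comparison: an event passing in D:N but in neither
#' treated contrast is responsive to both drugs; still passing in both is
#' unresponsive; passing only in a treated contrast is exacerbated by that
#' drug. Every event in the union lands in exactly one category.
#'
#' @param d_events,t1_events,t2_events `splice_scan` results (or any tibble
#'   with `event_id` and `passes`) for the three contrasts.
#' @return A `splice_response_sets` list: `membership` (per-event flags and
#'   category), `category_counts`, `region_counts` (the seven membership
#'   regions of the three passing sets).
#' @export
splice_response_sets <- function(d_events, t1_events, t2_events) {
  pass_ids <- function(x) unique(x$event_id[x$passes])
  in_d <- pass_ids(d_events)
  in_t1 <- pass_ids(t1_events)
  in_t2 <- pass_ids(t2_events)
  all_ids <- sort(union(union(in_d, in_t1), in_t2))
  membership <- tibble(
    event_id = all_ids,
    in_d = all_ids %in% in_d,
    in_t1 = all_ids %in% in_t1,
    in_t2 = all_ids %in% in_t2
  ) %>%
    mutate(category = dplyr::case_when(
      in_d & !in_t1 & !in_t2 ~ "responsive_to_T1_and_T2",
      in_d & !in_t1 & in_t2 ~ "responsive_to_T1",
      in_d & in_t1 & !in_t2 ~ "responsive_to_T2",
      in_d & in_t1 & in_t2 ~ "unresponsive_to_T1_and_T2",
      !in_d & in_t1 & !in_t2 ~ "exacerbated_by_T1",
      !in_d & !in_t1 & in_t2 ~ "exacerbated_by_T2",
      !in_d & in_t1 & in_t2 ~ "exacerbated_by_T1_and_T2"
    ))
  category_counts <- membership %>% count(.data$category, name = "n_events")
  region_counts <- membership %>%
    count(.data$in_d, .data$in_t1, .data$in_t2, name = "n_events")
  structure(list(membership = membership, category_counts = category_counts,
                 region_counts = region_counts),
            class = "splice_response_sets")
}

#' @export
print.splice_response_sets <- function(x, ...) {
  cat("Splice-event response comparison across", nrow(x$membership),
      "events:\n")
  print(x$category_counts)
  invisible(x)
}
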