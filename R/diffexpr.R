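#' Differential expression by per-feature one-way ANOVA
#'
#' The transcript-route analysis: one-way fixed-effects ANOVA on
#' log2(RPKM + offset) values across the included groups (two groups for a
#' pairwise contrast), with a fold-change cutoff applied to RPKM-scale group
#' means. A feature passes under the `"and"` rule when ratio >= `fc_cutoff`
#' AND p <= `p_cutoff`; under `"or"` when either holds.
#'
#' @param expr Expression tibble, RPKM scale (logged internally) or log2
#'   scale as produced by [log_transform()].
#' @param design Design tibble.
#' @param contrast `c(case, control)` used for the reported fold change.
#' @param groups Groups included in the ANOVA; defaults to the contrast
#'   (pairwise test).
#' @param fc_cutoff,p_cutoff Selection cutoffs (defaults 1.5 and 0.05).
#' @param combine `"and"` (default, stricter) or `"or"`, the rule combining
#'   the two cutoffs.
#' @param offset Log offset when `expr` is on RPKM scale.
#' @return A `de_result` tibble (route `"anova"`): `feature_id`, RPKM group
#'   means, `ratio`, `direction`, `signed_log2`, `statistic` (F), `p_value`,
#'   `passes`, `defined`. Features with zero within-group variance in all
#'   groups get `p_value = NA` and are flagged.
#' @export
anova_de <- function(expr, design, contrast = c("D", "N"), groups = contrast,
                     fc_cutoff = 1.5, p_cutoff = 0.05,
                     combine = c("and", "or"), offset = 1.0) {
  combine <- arg_match(combine)
  validate_design(design)
  design <- design %>% filter(.data$group %in% groups)
  if (any(table(factor(design$group, levels = groups)) < 2)) {
    abort("anova_de() needs >= 2 replicates in every included group")
  }
  mats <- expr_on_both_scales(expr, offset)
  samples <- intersect(design$sample_id, sample_ids(expr))
  g <- factor(design$group[match(samples, design$sample_id)], levels = groups)
  lv <- as.matrix(mats$log2[, samples, drop = FALSE])

  f_p <- t(vapply(seq_len(nrow(lv)), function(i) {
    y <- lv[i, ]
    res <- tryCatch(
      stats::oneway.test(y ~ g, var.equal = TRUE),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$statistic)) c(NA_real_, NA_real_)
    else c(unname(res$statistic), unname(res$p.value))
  }, numeric(2)))

  fc <- fold_change(mats$rpkm, design, contrast)
  p <- f_p[, 2]
  pass_fc <- !is.na(fc$ratio) & fc$ratio >= fc_cutoff
  pass_p <- !is.na(p) & p <= p_cutoff
  passes <- if (combine == "and") pass_fc & pass_p else pass_fc | pass_p
  out <- fc %>%
    mutate(statistic = f_p[, 1], p_value = p,
           passes = passes & .data$defined,
           route = "anova")
  new_de_result(out, route = "anova",
                params = list(contrast = contrast, groups = groups,
                              fc_cutoff = fc_cutoff, p_cutoff = p_cutoff,
                              combine = combine, offset = offset))
}

expr_on_both_scales <- function(expr, offset) {
  sc <- expr_scale(expr)
  if (is.null(sc) || sc == "rpkm") {
    expr <- set_expr_scale(expr, "rpkm")
    list(rpkm = expr, log2 = log_transform(expr, offset))
  } else if (sc == "log2") {
    list(rpkm = unlog_transform(expr), log2 = expr)
  } else {
    abort(paste0("unknown expression scale: ", sc))
  }
}

new_de_result <- function(tbl, route, params) {
  attr(tbl, "route") <- route
  attr(tbl, "params") <- params
  class(tbl) <- c("de_result", class(tbl))
  tbl
}

#' Group-label permutations for a two-group contrast
#'
#' Enumerates (or samples) assignments of the contrast's samples to the case
#' group. The observed labeling is always included; exhaustive enumeration
#' covers all choose(n, n1) assignments (20 for a 3-vs-3 design).
#'
#' @param n Total samples in the contrast.
#' @param n1 Samples assigned to the case group.
#' @param n_perm `"exhaustive"` or a number of permutations; a request
#'   exceeding the number of distinct assignments falls back to exhaustive
#'   with a message.
#' @param seed RNG seed, mandatory when sampling a subset.
#' @return Logical matrix, one row per labeling, `TRUE` marking case samples;
#'   first row is the observed labeling (first `n1` positions).
#' @export
permutation_labels <- function(n, n1, n_perm = "exhaustive", seed = NULL) {
  total <- choose(n, n1)
  exhaustive <- identical(n_perm, "exhaustive") ||
    (is.numeric(n_perm) && n_perm >= total)
  if (is.numeric(n_perm) && n_perm >= total && n_perm > total) {
    inform(paste0("requested ", n_perm, " permutations but only ", total,
                  " distinct labelings exist; using exhaustive enumeration"))
  }
  if (exhaustive) {
    idx <- combn(n, n1)
    m <- matrix(FALSE, ncol(idx), n)
    for (j in seq_len(ncol(idx))) m[j, idx[, j]] <- TRUE
    observed <- which(apply(m, 1, function(r) all(which(r) == seq_len(n1))))
    m <- m[c(observed, setdiff(seq_len(nrow(m)), observed)), , drop = FALSE]
    return(m)
  }
  if (n_perm < 1) abort("n_perm must be >= 1")
  if (is.null(seed)) abort("seed is mandatory when sampling permutations")
  set.seed(seed)
  seen <- new.env(parent = emptyenv())
  rows <- list(seq_len(n1))
  assign(paste(seq_len(n1), collapse = ","), TRUE, envir = seen)
  while (length(rows) < n_perm) {
    cand <- sort(sample.int(n, n1))
    key <- paste(cand, collapse = ",")
    if (!exists(key, envir = seen)) {
      assign(key, TRUE, envir = seen)
      rows[[length(rows) + 1]] <- cand
    }
  }
  m <- matrix(FALSE, length(rows), n)
  for (j in seq_along(rows)) m[j, rows[[j]]] <- TRUE
  m
}

#' SAM d-statistic
#'
#' The moderated difference statistic of significance analysis of
#' microarrays: d = (mean_case - mean_control) / (s + s0), with s the pooled
#' standard error of the difference and s0 a variance-stabilizing fudge
#' constant. With s0 = 0 and equal group sizes d reduces to the ordinary
#' pooled-variance t statistic.
#'
#' @param x Numeric matrix, features x samples.
#' @param case Logical or integer index of case samples.
#' @param s0 Fudge constant.
#' @return List with `d`, `s` (per-feature pooled SE), `diff` (mean
#'   difference).
#' @export
sam_d_stat <- function(x, case, s0 = 0) {
  x <- as.matrix(x)
  if (is.logical(case)) case <- which(case)
  ctrl <- setdiff(seq_len(ncol(x)), case)
  n1 <- length(case); n2 <- length(ctrl)
  if (n1 < 2 || n2 < 2) abort("sam_d_stat() needs >= 2 samples per side")
  m1 <- rowMeans(x[, case, drop = FALSE])
  m2 <- rowMeans(x[, ctrl, drop = FALSE])
  ss1 <- rowSums((x[, case, drop = FALSE] - m1)^2)
  ss2 <- rowSums((x[, ctrl, drop = FALSE] - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  list(d = (m1 - m2) / (s + s0), s = s, diff = m1 - m2)
}

sam_s0 <- function(s, diff, s0_rule) {
  if (s0_rule == "median") return(median(s))
  # percentile search: pick the percentile of s minimizing the coefficient
  # of variation of the spread of d across windows of s
  alphas <- seq(0, 1, by = 0.05)
  qs <- quantile(s, alphas, names = FALSE)
  breaks <- unique(quantile(s, seq(0, 1, length.out = 11), names = FALSE))
  bin <- cut(s, breaks = breaks, include.lowest = TRUE)
  cvs <- vapply(qs, function(s0c) {
    d <- diff / (s + s0c)
    v <- tapply(d, bin, mad)
    v <- v[is.finite(v) & v > 0]
    if (length(v) < 2) return(Inf)
    sd(v) / mean(v)
  }, numeric(1))
  qs[which.min(cvs)]
}

#' Differential expression by SAM permutation analysis
#'
#' The gene-route analysis: SAM d-statistics on log2(RPKM + offset) with a
#' permutation-estimated false discovery rate. Features are ranked against
#' the expected order statistics of d under group-label permutation; for a
#' stringency Delta, a feature is called when its observed d departs from
#' the expected value by at least Delta, and the FDR at Delta is the median
#' permutation false-call count divided by the observed call count (pi0
#' fixed at 1, conservative). Per-feature q is the (monotonized) FDR at the
#' largest Delta still calling the feature. A feature passes when
#' q <= `fdr_cutoff` AND fold ratio >= `fc_cutoff`.
#'
#' @inheritParams anova_de
#' @param fdr_cutoff FDR threshold (default 0.25).
#' @param n_perm `"exhaustive"` (default) or a permutation count; sampling a
#'   subset requires `seed`.
#' @param s0_rule `"median"` (s0 = median of the per-feature standard
#'   errors, the default) or `"percentile"` (coefficient-of-variation search
#'   over percentiles of s).
#' @param s0 Explicit fudge constant, overriding `s0_rule`.
#' @param seed RNG seed for sampled permutations.
#' @return A `de_result` tibble (route `"sam"`): `feature_id`, group means,
#'   `ratio`, `direction`, `signed_log2`, `statistic` (d), `s`, `q_value`,
#'   `passes`. Attributes: `s0`, `perm_labels` (labeling matrix),
#'   `perm_d` (features x labelings matrix of permuted d), `delta_table`.
#' @export
sam_de <- function(expr, design, contrast = c("D", "N"), fc_cutoff = 1.5,
                   fdr_cutoff = 0.25, n_perm = "exhaustive",
                   s0_rule = c("median", "percentile"), s0 = NULL,
                   seed = NULL, offset = 1.0) {
  s0_rule <- arg_match(s0_rule)
  validate_design(design)
  mats <- expr_on_both_scales(expr, offset)
  case_samples <- design$sample_id[design$group == contrast[1]]
  ctrl_samples <- design$sample_id[design$group == contrast[2]]
  case_samples <- intersect(case_samples, sample_ids(expr))
  ctrl_samples <- intersect(ctrl_samples, sample_ids(expr))
  n1 <- length(case_samples); n2 <- length(ctrl_samples)
  if (n1 < 2 || n2 < 2) abort("sam_de() needs >= 2 replicates per group")
  x <- as.matrix(mats$log2[, c(case_samples, ctrl_samples), drop = FALSE])

  base <- sam_d_stat(x, seq_len(n1), s0 = 0)
  if (is.null(s0)) s0 <- sam_s0(base$s, base$diff, s0_rule)
  obs <- sam_d_stat(x, seq_len(n1), s0 = s0)

  labels <- permutation_labels(n1 + n2, n1, n_perm = n_perm, seed = seed)
  perm_d <- apply(labels, 1, function(case) sam_d_stat(x, case, s0 = s0)$d)
  if (is.null(dim(perm_d))) perm_d <- matrix(perm_d, nrow = nrow(x))

  ord <- order(obs$d)
  d_sorted <- obs$d[ord]
  dbar <- rowMeans(apply(perm_d, 2, sort))
  dev <- d_sorted - dbar

  deltas <- sort(unique(abs(dev)))
  deltas <- deltas[deltas > 0]
  n_feat <- nrow(x)
  delta_table <- purrr::map_dfr(deltas, function(delta) {
    up <- which(dev >= delta)
    down <- which(dev <= -delta)
    n_called <- length(up) + length(down)
    if (n_called == 0) {
      return(tibble(delta = delta, n_called = 0L, false_median = 0,
                    cut_up = Inf, cut_low = -Inf, fdr = 0))
    }
    cut_up <- if (length(up)) min(d_sorted[up]) else Inf
    cut_low <- if (length(down)) max(d_sorted[down]) else -Inf
    false_counts <- colSums(perm_d >= cut_up) + colSums(perm_d <= cut_low)
    tibble(delta = delta, n_called = n_called,
           false_median = median(false_counts),
           cut_up = cut_up, cut_low = cut_low,
           fdr = min(1, median(false_counts) / n_called))
  })
  # monotonize conservatively: estimated FDR non-increasing in Delta, never
  # below any raw estimate at a more stringent Delta
  delta_table$fdr <- rev(cummax(rev(delta_table$fdr)))

  # per-feature q: FDR at the largest Delta at which the feature is called
  dev_feature <- numeric(n_feat)
  dev_feature[ord] <- abs(dev)
  q <- vapply(dev_feature, function(dv) {
    ok <- delta_table$delta <= dv
    if (!any(ok)) 1 else min(delta_table$fdr[ok][sum(ok)], 1)
  }, numeric(1))

  fc <- fold_change(mats$rpkm, design, contrast)
  passes <- !is.na(q) & q <= fdr_cutoff & !is.na(fc$ratio) &
    fc$ratio >= fc_cutoff & fc$defined
  out <- fc %>%
    mutate(statistic = obs$d, s = obs$s, q_value = q,
           passes = passes, route = "sam")
  res <- new_de_result(out, route = "sam",
                       params = list(contrast = contrast, fc_cutoff = fc_cutoff,
                                     fdr_cutoff = fdr_cutoff, s0 = s0,
                                     s0_rule = s0_rule, offset = offset,
                                     n_perm = nrow(labels)))
  attr(res, "s0") <- s0
  attr(res, "perm_labels") <- labels
  attr(res, "perm_d") <- perm_d
  attr(res, "delta_table") <- delta_table
  res
}

#' Overlap between the top-n feature lists of two analyses
#'
#' Ranks each result by decreasing effect magnitude and compares the two
#' top-n id sets, the comparison used to contrast the SAM and ANOVA routes
#' (the study reports 81 of the top 100 shared).
#'
#' @param list_a,list_b `de_result` tibbles (or any tibble with `feature_id`
#'   and the ranking column).
#' @param n List size to compare (default 100).
#' @param rank_key `"abs_log2"` (|signed log2 fold|, default) or
#'   `"abs_statistic"`. Ties break by feature id, lexicographic.
#' @return An `overlap_summary` list: `n`, `only_a`, `only_b`, `shared`,
#'   `shared_ids`, `top_a`, `top_b`.
#' @export
top_n_overlap <- function(list_a, list_b, n = 100,
                          rank_key = c("abs_log2", "abs_statistic")) {
  rank_key <- arg_match(rank_key)
  top_ids <- function(tbl) {
    key <- switch(rank_key,
                  abs_log2 = abs(tbl$signed_log2),
                  abs_statistic = abs(tbl$statistic))
    key[is.na(key)] <- -Inf
    tbl$feature_id[order(-key, tbl$feature_id)][seq_len(min(n, nrow(tbl)))]
  }
  a <- top_ids(list_a)
  b <- top_ids(list_b)
  shared <- intersect(a, b)
  structure(
    list(n = n, only_a = length(setdiff(a, b)), only_b = length(setdiff(b, a)),
         shared = length(shared), shared_ids = shared, top_a = a, top_b = b),
    class = "overlap_summary"
  )
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("Top-", x$n, " overlap: ", x$shared, " shared, ",
      x$only_a, " only in A, ", x$only_b, " only in B\n", sep = "")
  invisible(x)
}

#' Recompute the pass flag of a DE result from its stored fields
#'
#' `passes` is a pure function of the stored statistics and the cutoffs
#' recorded in the result's parameters; this re-derives it, used to verify
#' results carry no hidden state.
#'
#' @param de A `de_result` tibble.
#' @return Logical vector.
#' @export
recompute_passes <- function(de) {
  p <- attr(de, "params")
  route <- attr(de, "route")
  pass_fc <- !is.na(de$ratio) & de$ratio >= p$fc_cutoff & de$defined
  if (route == "sam") {
    pass_fc & !is.na(de$q_value) & de$q_value <= p$fdr_cutoff
  } else {
    pass_p <- !is.na(de$p_value) & de$p_value <= p$p_cutoff
    if (p$combine == "and") pass_fc & pass_p else (pass_fc | pass_p) & de$defined
  }
}
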