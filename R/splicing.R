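#' Junction fractions relative to gene-wide feature abundance
#'
#' For each splice junction j of a gene g in sample s, the junction fraction
#' is the junction's read count divided by the mean count over all junction
#' and exon features of that gene in that sample:
#' \deqn{f_{js} = c_{js} / \bar c_{gs}}
#' Genes with zero total coverage in a sample yield undefined fractions
#' (`NA`), flagged rather than imputed. The normalizer cancels exactly in
#' within-gene inclusion ratios.
#'
#' @param junction_counts Junction count tibble (`feature_id` =
#'   `chrom:donor-acceptor`).
#' @param exon_counts Exon count tibble (`feature_id` = `<transcript>:e<k>`).
#' @param models Gene-model tibble assigning features to genes.
#' @param extra_junction_genes Optional tibble (`junction_id`, `gene_id`)
#'   assigning junctions absent from the models (e.g. exon-skip junctions)
#'   to genes.
#' @return Long tibble: `feature_id`, `gene_id`, `kind`
#'   ("junction"/"exon"), `sample_id`, `count`, `f`.
#' @export
junction_fraction <- function(junction_counts, exon_counts, models,
                              extra_junction_genes = NULL) {
  jx_map <- transcript_junctions(models) %>%
    distinct(.data$junction_id, .data$gene_id)
  if (!is.null(extra_junction_genes)) {
    jx_map <- bind_rows(jx_map, rename(extra_junction_genes,
                                       junction_id = 1, gene_id = 2)) %>%
      distinct(.data$junction_id, .data$gene_id)
  }
  ex_map <- exon_table(models) %>% distinct(.data$exon_id, .data$gene_id)

  long <- bind_rows(
    junction_counts %>%
      inner_join(jx_map, by = c(feature_id = "junction_id")) %>%
      mutate(kind = "junction"),
    exon_counts %>%
      inner_join(ex_map, by = c(feature_id = "exon_id")) %>%
      mutate(kind = "exon")
  ) %>%
    tidyr::pivot_longer(cols = -c("feature_id", "gene_id", "kind"),
                        names_to = "sample_id", values_to = "count")
  long %>%
    group_by(.data$gene_id, .data$sample_id) %>%
    mutate(f = if (mean(.data$count) > 0) .data$count / mean(.data$count)
               else NA_real_) %>%
    ungroup()
}

#' Exon-inclusion ratio from junction fractions
#'
#' I = f_incl / (f_incl + f_excl), in [0, 1]. With both fractions zero (no
#' coverage of either isoform) the ratio is undefined (`NA`).
#'
#' @param f_incl,f_excl Non-negative combined junction fractions supporting
#'   the inclusion and exclusion isoforms.
#' @return Inclusion ratio vector in [0, 1].
#' @export
inclusion_ratio <- function(f_incl, f_excl) {
  if (any(f_incl < 0, na.rm = TRUE) || any(f_excl < 0, na.rm = TRUE)) {
    abort("junction fractions must be >= 0")
  }
  denom <- f_incl + f_excl
  ifelse(!is.na(denom) & denom > 0, f_incl / denom, NA_real_)
}

#' Difference in exon inclusion between two conditions
#'
#' Delta-I = mean of per-sample inclusion ratios in the case group minus the
#' control-group mean, in [-1, 1]. A Delta-I of 0.2 corresponds to a 20
#' percentage-point change in exon inclusion.
#'
#' @param i_case,i_control Per-sample inclusion ratios (NAs dropped).
#' @return Scalar Delta-I.
#' @export
delta_i <- function(i_case, i_control) {
  mean(i_case, na.rm = TRUE) - mean(i_control, na.rm = TRUE)
}

per_sample_inclusion <- function(fractions, catalog, samples,
                                 combine = c("mean", "sum")) {
  combine <- arg_match(combine)
  comb_fun <- if (combine == "mean") mean else sum
  f_wide <- fractions %>%
    filter(.data$sample_id %in% samples) %>%
    select("feature_id", "sample_id", "f")
  purrr::map_dfr(seq_len(nrow(catalog)), function(i) {
    ev <- catalog[i, ]
    fi <- f_wide %>% filter(.data$feature_id %in% ev$inclusion_junctions[[1]])
    fe <- f_wide %>% filter(.data$feature_id %in% ev$exclusion_junctions[[1]])
    purrr::map_dfr(samples, function(s) {
      f_in <- fi$f[fi$sample_id == s]
      f_ex <- fe$f[fe$sample_id == s]
      tibble(
        event_id = ev$event_id, gene_id = ev$gene_id, sample_id = s,
        f_incl = if (length(f_in)) comb_fun(f_in) else NA_real_,
        f_excl = if (length(f_ex)) comb_fun(f_ex) else NA_real_
      )
    })
  }) %>%
    mutate(i = inclusion_ratio(.data$f_incl, .data$f_excl))
}

#' Reciprocal-isoform Delta-I scan over a cassette-event catalog
#'
#' The ASPIRE-style analysis: events are gated on gene expression
#' (RPKM >= `rpkm_cutoff` in at least one sample of the contrast), per-sample
#' inclusion ratios are computed from junction fractions, Delta-I is the
#' case-minus-control mean, a permutation p-value uses |Delta-I| as the
#' statistic under group-label shuffling (exhaustive when at most
#' `max_exhaustive` labelings exist), and Benjamini-Hochberg FDR is applied
#' across events. An event passes when |Delta-I| >= `delta_cutoff` AND
#' FDR <= `fdr_cutoff`.
#'
#' Events with zero junction coverage in either group, or with undefined
#' inclusion in more than half the samples of either group, are excluded
#' (`excluded` column, with reason).
#'
#' @param junction_counts,exon_counts Count tibbles.
#' @param catalog Reciprocal-pair catalog (see [validate_catalog()]).
#' @param expr RPKM-scale expression tibble keyed by gene or transcript ids
#'   matching `catalog$gene_id` (used only for the expression gate; pass
#'   `NULL` to skip gating).
#' @param models Gene-model tibble.
#' @param design Design tibble.
#' @param contrast `c(case, control)` group pair.
#' @param rpkm_cutoff Expression gate (default 3.0).
#' @param delta_cutoff |Delta-I| threshold (default 0.2).
#' @param fdr_cutoff BH FDR threshold (default 0.25).
#' @param n_perm `"exhaustive"` or a count (see [permutation_labels()]).
#' @param max_exhaustive Enumerate exhaustively when the number of distinct
#'   labelings is at most this (default 500).
#' @param combine How multiple inclusion junctions are combined before the
#'   ratio: `"mean"` (default) or `"sum"` of their fractions.
#' @param seed RNG seed for sampled permutations.
#' @return A `splice_scan` tibble: `event_id`, `gene_id`, `i_bar_case`,
#'   `i_bar_control`, `delta_i`, `coverage` (mean per-sample junction count
#'   of the event over contrast samples), `p_value`, `fdr`, `passes`,
#'   `excluded`, `exclude_reason`.
#' @export
aspire_scan <- function(junction_counts, exon_counts, catalog, expr, models,
                        design, contrast, rpkm_cutoff = 3.0,
                        delta_cutoff = 0.2, fdr_cutoff = 0.25,
                        n_perm = "exhaustive", max_exhaustive = 500,
                        combine = c("mean", "sum"), seed = NULL) {
  combine <- arg_match(combine)
  validate_catalog(catalog)
  validate_design(design)
  case_samples <- intersect(design$sample_id[design$group == contrast[1]],
                            sample_ids(junction_counts))
  ctrl_samples <- intersect(design$sample_id[design$group == contrast[2]],
                            sample_ids(junction_counts))
  n1 <- length(case_samples); n2 <- length(ctrl_samples)
  if (n1 < 1 || n2 < 1) abort("aspire_scan() needs >= 1 sample per side")
  samples <- c(case_samples, ctrl_samples)

  if (!is.null(expr)) {
    gate_ids <- filter_expressed(
      set_expr_scale(expr[, c("feature_id", samples)], "rpkm"), rpkm_cutoff)
    gated <- catalog %>% filter(.data$gene_id %in% gate_ids)
  } else {
    gated <- catalog
  }
  if (nrow(gated) == 0) {
    return(new_splice_scan(empty_splice_scan(), contrast, rpkm_cutoff,
                           delta_cutoff, fdr_cutoff))
  }

  extra <- tibble(
    junction_id = unlist(gated$exclusion_junctions),
    gene_id = rep(gated$gene_id, lengths(gated$exclusion_junctions))
  )
  fractions <- junction_fraction(junction_counts, exon_counts, models,
                                 extra_junction_genes = extra)
  inc <- per_sample_inclusion(fractions, gated, samples, combine = combine)

  jx_counts_long <- junction_counts %>%
    tidyr::pivot_longer(-"feature_id", names_to = "sample_id",
                        values_to = "count") %>%
    filter(.data$sample_id %in% samples)

  labels <- NULL
  total_lab <- choose(n1 + n2, n1)
  use_exhaustive <- identical(n_perm, "exhaustive") ||
    (is.numeric(n_perm) && n_perm >= total_lab)
  if (use_exhaustive && total_lab > max_exhaustive) use_exhaustive <- FALSE
  labels <- if (use_exhaustive) {
    permutation_labels(n1 + n2, n1, "exhaustive")
  } else {
    np <- if (identical(n_perm, "exhaustive")) max_exhaustive else n_perm
    permutation_labels(n1 + n2, n1, np, seed = seed)
  }

  rows <- purrr::map_dfr(unique(gated$event_id), function(eid) {
    ev_inc <- inc %>% filter(.data$event_id == eid)
    ev <- gated[gated$event_id == eid, ]
    ev_jx <- c(ev$inclusion_junctions[[1]], ev$exclusion_junctions[[1]])
    cov_tbl <- jx_counts_long %>%
      filter(.data$feature_id %in% ev_jx) %>%
      group_by(.data$sample_id) %>% summarise(total = sum(.data$count))
    coverage <- mean(cov_tbl$total[match(samples, cov_tbl$sample_id)])
    cov_case <- sum(cov_tbl$total[cov_tbl$sample_id %in% case_samples])
    cov_ctrl <- sum(cov_tbl$total[cov_tbl$sample_id %in% ctrl_samples])

    i_by_sample <- ev_inc$i[match(samples, ev_inc$sample_id)]
    i_case <- i_by_sample[seq_len(n1)]
    i_ctrl <- i_by_sample[n1 + seq_len(n2)]
    reason <- NA_character_
    if (cov_case == 0 || cov_ctrl == 0) {
      reason <- "zero junction coverage in a group"
    } else if (sum(is.na(i_case)) > n1 / 2 || sum(is.na(i_ctrl)) > n2 / 2) {
      reason <- "inclusion undefined in > half of a group"
    }
    if (!is.na(reason)) {
      return(tibble(event_id = eid, gene_id = ev$gene_id,
                    i_bar_case = NA_real_, i_bar_control = NA_real_,
                    delta_i = NA_real_, coverage = coverage,
                    p_value = NA_real_, fdr = NA_real_, passes = FALSE,
                    excluded = TRUE, exclude_reason = reason))
    }
    obs <- delta_i(i_case, i_ctrl)
    perm_stats <- apply(labels, 1, function(case_idx) {
      abs(delta_i(i_by_sample[case_idx], i_by_sample[!case_idx]))
    })
    p <- mean(perm_stats >= abs(obs) - 1e-12)
    tibble(event_id = eid, gene_id = ev$gene_id,
           i_bar_case = mean(i_case, na.rm = TRUE),
           i_bar_control = mean(i_ctrl, na.rm = TRUE),
           delta_i = obs, coverage = coverage, p_value = p,
           fdr = NA_real_, passes = FALSE,
           excluded = FALSE, exclude_reason = NA_character_)
  })

  ok <- !rows$excluded
  rows$fdr[ok] <- p.adjust(rows$p_value[ok], method = "BH")
  rows$passes <- ok & !is.na(rows$delta_i) &
    abs(rows$delta_i) >= delta_cutoff & rows$fdr <= fdr_cutoff
  rows$passes[is.na(rows$passes)] <- FALSE
  new_splice_scan(rows, contrast, rpkm_cutoff, delta_cutoff, fdr_cutoff)
}

empty_splice_scan <- function() {
  tibble(event_id = character(), gene_id = character(),
         i_bar_case = numeric(), i_bar_control = numeric(),
         delta_i = numeric(), coverage = numeric(), p_value = numeric(),
         fdr = numeric(), passes = logical(), excluded = logical(),
         exclude_reason = character())
}

new_splice_scan <- function(tbl, contrast, rpkm_cutoff, delta_cutoff,
                            fdr_cutoff) {
  attr(tbl, "params") <- list(contrast = contrast, rpkm_cutoff = rpkm_cutoff,
                              delta_cutoff = delta_cutoff,
                              fdr_cutoff = fdr_cutoff)
  class(tbl) <- c("splice_scan", class(tbl))
  tbl
}
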