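#' RPKM: reads per kilobase of exon model per million mapped reads
#'
#' For feature f in sample s with raw count C, exon-model length L (bases)
#' and per-sample total mapped reads N:
#' \deqn{RPKM = 10^9 C / (N L)}
#' N is the alignment total supplied in `lib_sizes`, not the column sum of
#' the (possibly filtered) count table.
#'
#' @param counts Count tibble: `feature_id` plus one column per sample.
#' @param lengths Feature lengths in bases: a named numeric vector or a
#'   tibble with `feature_id`/`transcript_id` and `length`.
#' @param lib_sizes Named numeric vector of total mapped reads per sample
#'   (names = sample columns of `counts`).
#' @return An expression tibble of the same shape, RPKM scale (attribute
#'   `scale = "rpkm"`).
#' @export
#' @examples
#' counts <- tibble::tibble(feature_id = "t1", s1 = 10)
#' rpkm(counts, c(t1 = 1000), c(s1 = 1e6))  # RPKM 10
rpkm <- function(counts, lengths, lib_sizes) {
  validate_count_matrix(counts)
  lengths <- as_length_vector(lengths)
  samples <- sample_ids(counts)
  if (!all(samples %in% names(lib_sizes))) {
    abort(paste0("missing library size for sample(s): ",
                 paste(setdiff(samples, names(lib_sizes)), collapse = ", ")))
  }
  if (any(lib_sizes[samples] <= 0)) abort("library sizes must be > 0")
  missing_len <- setdiff(counts$feature_id, names(lengths))
  if (length(missing_len) > 0) {
    abort(paste0("missing exon-model length for feature(s): ",
                 paste(head(missing_len, 3), collapse = ", ")))
  }
  L <- lengths[counts$feature_id]
  if (any(L <= 0)) abort("exon-model lengths must be > 0")
  out <- counts
  for (s in samples) {
    out[[s]] <- unname(1e9 * counts[[s]] / (lib_sizes[[s]] * L))
  }
  set_expr_scale(out, "rpkm")
}

as_length_vector <- function(lengths) {
  if (is.data.frame(lengths)) {
    idcol <- intersect(c("feature_id", "transcript_id", "exon_id", "gene_id"),
                       names(lengths))[1]
    if (is.na(idcol) || !"length" %in% names(lengths)) {
      abort("length table needs an id column and a 'length' column")
    }
    lengths <- setNames(lengths$length, lengths[[idcol]])
  }
  if (is.null(names(lengths))) abort("lengths must be named by feature id")
  lengths
}

#' Expression-scale bookkeeping
#'
#' Expression tibbles carry a `scale` attribute (`"rpkm"` or `"log2"`) and,
#' after log transformation, the `offset` used, so the transform is
#' invertible.
#'
#' @param expr An expression tibble.
#' @return The scale string, or `NULL` if untagged.
#' @export
expr_scale <- function(expr) attr(expr, "expr_scale", exact = TRUE)

set_expr_scale <- function(expr, scale, offset = NULL) {
  attr(expr, "expr_scale") <- scale
  if (!is.null(offset)) attr(expr, "log_offset") <- offset
  expr
}

#' @rdname expr_scale
#' @export
log_offset <- function(expr) attr(expr, "log_offset", exact = TRUE)

#' Log-transform an RPKM expression matrix
#'
#' Values become log2(RPKM + offset). The default offset of 1.0 maps
#' RPKM 0 to 0 and keeps all transformed values non-negative.
#'
#' @param expr RPKM-scale expression tibble.
#' @param offset Positive pseudo-expression added before the log.
#' @return Expression tibble on log2 scale.
#' @export
log_transform <- function(expr, offset = 1.0) {
  if (offset <= 0) abort("offset must be > 0")
  sc <- expr_scale(expr)
  if (!is.null(sc) && sc != "rpkm") abort("log_transform() expects RPKM-scale input")
  out <- expr
  for (s in sample_ids(expr)) out[[s]] <- log2(expr[[s]] + offset)
  set_expr_scale(out, "log2", offset = offset)
}

#' Invert a log transform using the stored offset
#'
#' @param expr log2-scale expression tibble produced by [log_transform()].
#' @return RPKM-scale expression tibble.
#' @export
unlog_transform <- function(expr) {
  offset <- log_offset(expr)
  if (is.null(offset)) abort("no stored offset; was this produced by log_transform()?")
  out <- expr
  for (s in sample_ids(expr)) out[[s]] <- pmax(2^expr[[s]] - offset, 0)
  set_expr_scale(out, "rpkm")
}

#' Select expressed features by an RPKM cutoff
#'
#' The comparison is inclusive (`>= cutoff`). Rules: `any_sample` keeps a
#' feature whose expression reaches the cutoff in at least one sample (the
#' default), `all_samples` requires every sample, `group_mean` requires at
#' least one group whose mean reaches the cutoff.
#'
#' @param expr RPKM-scale expression tibble.
#' @param cutoff RPKM threshold (e.g. 1.0 for the stringent transcript
#'   filter, 0.5 for the gene-level route, 3.0 upstream of splicing).
#' @param rule Filtering rule.
#' @param design Sample design tibble; required for `rule = "group_mean"`.
#' @return Character vector of retained feature ids, input order preserved.
#' @export
filter_expressed <- function(expr, cutoff,
                             rule = c("any_sample", "all_samples", "group_mean"),
                             design = NULL) {
  rule <- arg_match(rule)
  sc <- expr_scale(expr)
  if (!is.null(sc) && sc != "rpkm") abort("filter_expressed() expects RPKM scale")
  vals <- count_values(expr)
  keep <- switch(rule,
    any_sample = apply(vals, 1, max) >= cutoff,
    all_samples = apply(vals, 1, min) >= cutoff,
    group_mean = {
      if (is.null(design)) abort("rule 'group_mean' needs a design")
      gm <- purrr::map(split(design$sample_id, design$group), function(s) {
        rowMeans(vals[, intersect(s, colnames(vals)), drop = FALSE])
      })
      Reduce(`|`, purrr::map(gm, ~ .x >= cutoff))
    }
  )
  expr$feature_id[keep]
}

#' Summarize exon-level expression to gene level
#'
#' For each gene, takes the average (or maximum) exon RPKM per sample and
#' returns log2(summary + offset), the gene-level expression used by the
#' gene-route analysis.
#'
#' @param exon_expr RPKM-scale exon expression tibble; exon ids must be the
#'   canonical `<transcript>:e<k>` ids of [exon_table()].
#' @param models Gene-model tibble mapping exons to genes.
#' @param mode `"average"` or `"maximum"` over a gene's exons.
#' @param offset Log offset, as in [log_transform()].
#' @return Gene-level expression tibble on log2 scale (`feature_id` = gene).
#' @export
gene_exon_summary <- function(exon_expr, models, mode = c("average", "maximum"),
                              offset = 1.0) {
  mode <- arg_match(mode)
  ex <- exon_table(models) %>% select("exon_id", "gene_id")
  unknown <- setdiff(exon_expr$feature_id, ex$exon_id)
  if (length(unknown) > 0) {
    abort(paste0("exon id(s) not in models: ", paste(head(unknown, 3), collapse = ", ")))
  }
  samples <- sample_ids(exon_expr)
  joined <- exon_expr %>%
    left_join(ex, by = c(feature_id = "exon_id")) %>%
    group_by(.data$gene_id) %>%
    summarise(across(all_of(samples),
                     if (mode == "average") mean else max),
              .groups = "drop") %>%
    rename(feature_id = "gene_id")
  for (s in samples) joined[[s]] <- log2(joined[[s]] + offset)
  set_expr_scale(joined, "log2", offset = offset)
}
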