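#' Parse directional fold-change notation
#'
#' Published fold tables report magnitudes >= 1 with a separate down flag,
#' e.g. `"19.8"` (up) or `"1.5 (down)"`. The signed log2 fold is
#' +log2(ratio) for up and -log2(ratio) for down.
#'
#' @param x Character vector of fold strings.
#' @return Tibble with `ratio`, `direction` ("up"/"down"), `signed_log2`.
#' @export
#' @examples
#' parse_directional_fold(c("19.8", "1.5 (down)"))
parse_directional_fold <- function(x) {
  x <- trimws(x)
  down <- grepl("\\(down\\)", x)
  num <- suppressWarnings(as.numeric(sub("\\s*\\(down\\)\\s*$", "", x)))
  if (anyNA(num)) {
    abort(paste0("unparseable fold value: ", x[which(is.na(num))[1]]))
  }
  if (any(num < 1)) abort("directional fold ratios must be >= 1")
  tibble(
    ratio = num,
    direction = ifelse(down, "down", "up"),
    signed_log2 = ifelse(down, -log2(num), log2(num))
  )
}

#' Format a signed log2 fold in directional notation
#'
#' @param signed_log2 Numeric vector of signed log2 fold changes.
#' @param digits Rounding for display.
#' @return Character vector like `"2.4"` / `"1.5 (down)"`.
#' @export
format_directional_fold <- function(signed_log2, digits = 2) {
  ratio <- round(2^abs(signed_log2), digits)
  ifelse(signed_log2 < 0, paste0(ratio, " (down)"), as.character(ratio))
}

#' Read a transcribed fold-change table
#'
#' Fixture tables (see `system.file("extdata", package = "diaretseq")`) carry
#' three contrasts per transcript: diabetic (D), RAGE-inhibitor-treated
#' (D_T1) and p38-inhibitor-treated (D_T2), each versus nondiabetic (N), in
#' directional notation.
#'
#' @param path TSV with columns `gene_symbol`, `gene_name`, `d_vs_n`,
#'   `t1_vs_n`, `t2_vs_n`.
#' @return Tibble with `feature_id`, `gene_name`, and for each contrast
#'   (`d`, `t1`, `t2`) columns `<c>_ratio`, `<c>_direction`, `<c>_log2`.
#' @export
read_fold_table <- function(path) {
  df <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  need <- c("gene_symbol", "d_vs_n", "t1_vs_n", "t2_vs_n")
  if (!all(need %in% names(df))) {
    abort(paste0("fold table needs columns: ", paste(need, collapse = ", ")))
  }
  out <- tibble(feature_id = df$gene_symbol,
                gene_name = if ("gene_name" %in% names(df)) df$gene_name else NA_character_)
  for (cc in c("d", "t1", "t2")) {
    p <- parse_directional_fold(df[[paste0(cc, "_vs_n")]])
    out[[paste0(cc, "_ratio")]] <- p$ratio
    out[[paste0(cc, "_direction")]] <- p$direction
    out[[paste0(cc, "_log2")]] <- p$signed_log2
  }
  out
}

#' List or copy the bundled fold-change fixture tables
#'
#' Eight transcribed fold-change tables for transcript families of the
#' STZ-diabetic mouse retina study (crystallins, Wnt signaling,
#' microvasculature, inflammatory, apoptosis, neuronal, photoreceptor,
#' UDP-glucuronosyltransferase) ship with the package.
#'
#' @param dir If not `NULL`, copy the fixture TSVs there.
#' @return Named character vector of fixture paths.
#' @export
fold_table_fixtures <- function(dir = NULL) {
  src <- system.file("extdata", package = "diaretseq")
  files <- list.files(src, pattern = "\\.tsv$", full.names = TRUE)
  names(files) <- sub("\\.tsv$", "", basename(files))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    ok <- file.copy(files, dir, overwrite = TRUE)
    if (!all(ok)) abort("failed to copy fixture tables")
    files <- setNames(file.path(dir, basename(files)), names(files))
  }
  files
}

#' Group-mean fold change between two groups
#'
#' Fold changes are computed on RPKM-scale group means: the ratio is
#' max(m_case/m_control, m_control/m_case) (always >= 1) with direction "up"
#' when the case mean exceeds the control mean. A pseudocount may be added
#' to both means as a floor; with both group means zero the fold is
#' undefined and the feature is flagged (`defined = FALSE`).
#'
#' @param expr RPKM-scale expression tibble.
#' @param design Design tibble (`sample_id`, `group`).
#' @param contrast Length-2 character vector `c(case, control)`.
#' @param pseudocount Non-negative floor added to both group means.
#' @return Tibble with `feature_id`, `mean_case`, `mean_control`, `ratio`,
#'   `direction`, `signed_log2`, `defined`.
#' @export
fold_change <- function(expr, design, contrast, pseudocount = 0) {
  stopifnot(length(contrast) == 2)
  validate_design(design)
  sc <- expr_scale(expr)
  if (!is.null(sc) && sc != "rpkm") {
    abort("fold_change() expects RPKM-scale expression")
  }
  m1 <- group_means(expr, design, contrast[1])
  m2 <- group_means(expr, design, contrast[2])
  a <- m1 + pseudocount
  b <- m2 + pseudocount
  defined <- (a > 0) | (b > 0)
  ratio <- rep(NA_real_, length(a))
  up <- a >= b
  ratio[defined & up] <- (a / b)[defined & up]
  ratio[defined & !up] <- (b / a)[defined & !up]
  ratio[defined & (a == 0 | b == 0)] <- Inf
  ratio[defined & a == b] <- 1
  tibble(
    feature_id = expr$feature_id,
    mean_case = m1, mean_control = m2,
    ratio = ratio,
    direction = ifelse(defined, ifelse(up, "up", "down"), NA_character_),
    signed_log2 = ifelse(defined, ifelse(up, log2(ratio), -log2(ratio)), NA_real_),
    defined = defined
  )
}

group_means <- function(expr, design, group) {
  samples <- intersect(design$sample_id[design$group == group], sample_ids(expr))
  if (length(samples) == 0) abort(paste0("no samples in group ", group))
  rowMeans(count_values(expr)[, samples, drop = FALSE])
}
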