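#' Read a feature-by-sample count or expression matrix from TSV
#'
#' First column is the feature identifier, the header names the samples, and
#' every other cell is numeric. Duplicate feature ids and non-numeric cells
#' are errors (with row/column coordinates), never silently coerced.
#' Gzip-compressed files are read transparently.
#'
#' @param path Path to a TSV (optionally .gz) file.
#' @param integer_counts If `TRUE`, additionally require integral,
#'   non-negative values.
#' @return A tibble whose first column is `feature_id`.
#' @export
read_count_matrix <- function(path, integer_counts = FALSE) {
  raw <- suppressWarnings(
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE))
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(paste0("malformed table ", path, ": row ", probs$row[1], ", ",
                 probs$expected[1], " expected but ", probs$actual[1], " found"))
  }
  if (ncol(raw) < 1) abort("count matrix must have a feature id column")
  names(raw)[1] <- "feature_id"
  if (anyDuplicated(raw$feature_id)) {
    dup <- raw$feature_id[duplicated(raw$feature_id)][1]
    abort(paste0("duplicate feature id in ", path, ": ", dup))
  }
  out <- raw
  for (j in seq(2, length.out = ncol(raw) - 1)) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) & !is.na(raw[[j]]))
    if (length(bad) > 0) {
      abort(paste0("non-numeric cell at row ", bad[1], ", column '",
                   names(raw)[j], "' in ", path))
    }
    if (anyNA(v)) abort(paste0("missing value in column '", names(raw)[j], "'"))
    out[[j]] <- v
  }
  validate_count_matrix(out, integer_counts = integer_counts)
  out
}

validate_count_matrix <- function(counts, integer_counts = FALSE) {
  if (!is.data.frame(counts) || names(counts)[1] != "feature_id") {
    abort("expected a tibble with first column 'feature_id'")
  }
  vals <- count_values(counts)
  if (any(vals < 0)) abort("negative count encountered")
  if (integer_counts && any(vals != round(vals))) {
    abort("non-integer count encountered")
  }
  invisible(counts)
}

#' @rdname read_count_matrix
#' @param x A results or count tibble.
#' @return `write_results()` returns `path` invisibly. Column order and
#'   number formatting are deterministic so outputs are diffable.
#' @export
write_results <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Sample columns of a count/expression tibble
#'
#' @param counts A tibble with `feature_id` first.
#' @return Character vector of sample column names.
#' @export
sample_ids <- function(counts) {
  setdiff(names(counts), c("feature_id"))
}

count_values <- function(counts) {
  as.matrix(counts[, sample_ids(counts), drop = FALSE])
}

#' Read per-sample splice-junction counts
#'
#' The junction-count dialect is a TSV with columns `chrom`, `donor_end`,
#' `acceptor_start` followed by one integer count column per sample. Junction
#' identity is exact-coordinate `(chrom, donor_end, acceptor_start)`;
#' duplicate rows are an error rather than being summed, and negative counts
#' are rejected.
#'
#' @param path Path to a TSV (optionally .gz) file.
#' @return A tibble with `feature_id` (`chrom:donor_end-acceptor_start`) and
#'   one column per sample, rows in file order.
#' @export
read_junction_counts <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(),
    donor_end = readr::col_integer(),
    acceptor_start = readr::col_integer(),
    .default = readr::col_double()
  ), progress = FALSE)
  need <- c("chrom", "donor_end", "acceptor_start")
  if (!all(need %in% names(df))) {
    abort("junction counts need columns chrom, donor_end, acceptor_start")
  }
  ids <- junction_id(df$chrom, df$donor_end, df$acceptor_start)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate junction row: ", ids[duplicated(ids)][1]))
  }
  out <- tibble(feature_id = ids) %>%
    dplyr::bind_cols(df[, setdiff(names(df), need), drop = FALSE])
  validate_count_matrix(out, integer_counts = TRUE)
  out
}

#' Write junction counts in the dialect read_junction_counts() expects
#'
#' @param counts Junction count tibble (`feature_id` = `chrom:donor-acceptor`).
#' @param path Output path.
#' @export
write_junction_counts <- function(counts, path) {
  parts <- parse_junction_ids(counts$feature_id)
  out <- dplyr::bind_cols(parts, counts[, sample_ids(counts), drop = FALSE])
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

parse_junction_ids <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  bad <- which(lengths(m) != 4)
  if (length(bad) > 0) abort(paste0("malformed junction id: ", ids[bad[1]]))
  tibble(
    chrom = purrr::map_chr(m, 2),
    donor_end = as.integer(purrr::map_chr(m, 3)),
    acceptor_start = as.integer(purrr::map_chr(m, 4))
  )
}

#' Read and validate a sample design table
#'
#' A design assigns each sample to one of the four study groups: N
#' (nondiabetic), D (diabetic), D_T1 (diabetic + RAGE inhibitor), D_T2
#' (diabetic + p38 MAPK inhibitor).
#'
#' @param path TSV with columns `sample_id`, `group`, `replicate_index`.
#' @return A design tibble.
#' @export
read_design <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    group = readr::col_character(),
    replicate_index = readr::col_integer()
  ), progress = FALSE)
  validate_design(df)
  df
}

validate_design <- function(design, require_full = FALSE) {
  if (!all(c("sample_id", "group") %in% names(design))) {
    abort("design needs columns sample_id and group")
  }
  bad <- setdiff(unique(design$group), study_groups())
  if (length(bad) > 0) {
    abort(paste0("unknown group(s) in design: ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(design$sample_id)) abort("duplicate sample_id in design")
  if (require_full && !all(study_groups() %in% design$group)) {
    abort("a full design must contain all four groups: N, D, D_T1, D_T2")
  }
  invisible(design)
}

#' The four study groups
#'
#' @return `c("N", "D", "D_T1", "D_T2")`.
#' @export
study_groups <- function() c("N", "D", "D_T1", "D_T2")

#' Validate a reciprocal-isoform pair catalog
#'
#' Each catalog row describes one cassette-exon event: the inclusion
#' junctions support the exon-included isoform, the exclusion junctions the
#' exon-skipped isoform. The two sets must be disjoint.
#'
#' @param catalog Tibble with `event_id`, `gene_id`, and list-columns
#'   `inclusion_junctions`, `exclusion_junctions` of junction ids.
#' @return The catalog, invisibly.
#' @export
validate_catalog <- function(catalog) {
  need <- c("event_id", "gene_id", "inclusion_junctions", "exclusion_junctions")
  if (!all(need %in% names(catalog))) {
    abort(paste0("catalog needs columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(catalog$event_id)) abort("duplicate event_id in catalog")
  overlap <- purrr::map2_lgl(catalog$inclusion_junctions,
                             catalog$exclusion_junctions,
                             ~ length(intersect(.x, .y)) > 0)
  if (any(overlap)) {
    abort(paste0("event ", catalog$event_id[which(overlap)[1]],
                 ": inclusion and exclusion junction sets overlap"))
  }
  invisible(catalog)
}

#' Read/write a reciprocal-pair catalog as TSV
#'
#' Junction id sets are serialized comma-separated.
#'
#' @param path TSV path.
#' @return `read_pair_catalog()` returns a catalog tibble.
#' @export
read_pair_catalog <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  out <- tibble(
    event_id = df$event_id,
    gene_id = df$gene_id,
    inclusion_junctions = strsplit(df$inclusion_junctions, ",", fixed = TRUE),
    exclusion_junctions = strsplit(df$exclusion_junctions, ",", fixed = TRUE)
  )
  validate_catalog(out)
  out
}

#' @rdname read_pair_catalog
#' @param catalog A catalog tibble.
#' @export
write_pair_catalog <- function(catalog, path) {
  validate_catalog(catalog)
  out <- tibble(
    event_id = catalog$event_id,
    gene_id = catalog$gene_id,
    inclusion_junctions = purrr::map_chr(catalog$inclusion_junctions, paste,
                                         collapse = ","),
    exclusion_junctions = purrr::map_chr(catalog$exclusion_junctions, paste,
                                         collapse = ",")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
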