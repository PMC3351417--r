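#' Gene models: transcript exon structures on a genome
#'
#' A gene-model table holds one row per transcript with its exon intervals in
#' 0-based half-open genomic coordinates (the native refFlat convention).
#' Splice junctions of a contiguous transcript are derived from consecutive
#' exon boundaries: a transcript with k exons has k - 1 junctions, each the
#' pair (donor_end, acceptor_start).
#'
#' Columns: `gene_id`, `transcript_id`, `chrom`, `strand` ("+" or "-"),
#' `tx_start`, `tx_end`, `cds_start`, `cds_end`, and list-columns
#' `exon_starts`, `exon_ends` (sorted, non-overlapping integer vectors).
#'
#' @param models A gene-model tibble.
#' @return `validate_gene_models()` returns its input invisibly, erroring on
#'   any invariant violation (unsorted or overlapping exons, end <= start).
#' @export
validate_gene_models <- function(models) {
  required <- c("gene_id", "transcript_id", "chrom", "strand",
                "exon_starts", "exon_ends")
  missing_cols <- setdiff(required, names(models))
  if (length(missing_cols) > 0) {
    abort(paste0("gene models lack column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(models$transcript_id)) {
    abort("duplicate transcript_id in gene models")
  }
  for (i in seq_len(nrow(models))) {
    s <- models$exon_starts[[i]]
    e <- models$exon_ends[[i]]
    id <- models$transcript_id[i]
    if (length(s) != length(e) || length(s) == 0) {
      abort(paste0("transcript ", id, ": exon start/end lengths differ or empty"))
    }
    if (any(e <= s)) abort(paste0("transcript ", id, ": exon end <= start"))
    if (is.unsorted(s, strictly = TRUE) && length(s) > 1) {
      abort(paste0("transcript ", id, ": exons not sorted by start"))
    }
    if (length(s) > 1 && any(s[-1] < e[-length(e)])) {
      abort(paste0("transcript ", id, ": overlapping exons"))
    }
  }
  invisible(models)
}

#' Read transcript models from a refFlat file
#'
#' Parses the UCSC refFlat dialect: 11 tab-separated columns (geneName, name,
#' chrom, strand, txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts,
#' exonEnds), 0-based starts, exclusive ends, comma-terminated exon lists.
#' Gzip-compressed files are read transparently.
#'
#' @param path Path to a refFlat (optionally .gz) file.
#' @return A gene-model tibble (see [validate_gene_models()]).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".refflat")
#' writeLines("g1\tt1\tchr1\t+\t100\t400\t100\t400\t2\t100,300,\t200,400,", tf)
#' read_refflat(tf)
read_refflat <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(empty_gene_models())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 11)) {
    bad <- which(nf != 11)[1]
    abort(paste0("refFlat parse error at line ", bad, ": expected 11 columns, found ",
                 nf[bad]))
  }
  parse_list <- function(x) as.integer(strsplit(x, ",", fixed = TRUE)[[1]])
  rows <- purrr::imap(fields, function(f, i) {
    n_exon <- suppressWarnings(as.integer(f[9]))
    starts <- parse_list(f[10])
    ends <- parse_list(f[11])
    if (is.na(n_exon) || length(starts) != n_exon || length(ends) != n_exon) {
      abort(paste0("refFlat parse error at line ", i,
                   ": exonCount disagrees with exon list lengths"))
    }
    ord <- order(starts)
    tibble(
      gene_id = f[1], transcript_id = f[2], chrom = f[3], strand = f[4],
      tx_start = as.integer(f[5]), tx_end = as.integer(f[6]),
      cds_start = as.integer(f[7]), cds_end = as.integer(f[8]),
      exon_starts = list(starts[ord]), exon_ends = list(ends[ord])
    )
  })
  validate_gene_models(bind_rows(rows))
}

empty_gene_models <- function() {
  tibble(
    gene_id = character(), transcript_id = character(), chrom = character(),
    strand = character(), tx_start = integer(), tx_end = integer(),
    cds_start = integer(), cds_end = integer(),
    exon_starts = list(), exon_ends = list()
  )
}

#' Write gene models in refFlat format
#'
#' @param models A gene-model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_refflat <- function(models, path) {
  validate_gene_models(models)
  fmt_list <- function(x) paste0(paste(x, collapse = ","), ",")
  lines <- purrr::map_chr(seq_len(nrow(models)), function(i) {
    paste(models$gene_id[i], models$transcript_id[i], models$chrom[i],
          models$strand[i], models$tx_start[i], models$tx_end[i],
          models$cds_start[i], models$cds_end[i],
          length(models$exon_starts[[i]]),
          fmt_list(models$exon_starts[[i]]), fmt_list(models$exon_ends[[i]]),
          sep = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read transcript models from a GTF file
#'
#' Imports Ensembl-dialect GTF via rtracklayer and assembles exon features
#' grouped by transcript_id into the same gene-model tibble [read_refflat()]
#' produces. GTF is 1-based inclusive; coordinates are converted to the
#' package-internal 0-based half-open frame.
#'
#' @param path Path to a GTF (optionally .gz) file.
#' @return A gene-model tibble.
#' @export
read_gtf_models <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("read_gtf_models() requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  dfr <- as.data.frame(gr)
  dfr <- dfr[dfr$type == "exon", , drop = FALSE]
  if (nrow(dfr) == 0) return(empty_gene_models())
  df <- tibble(
    chrom = as.character(dfr$seqnames),
    strand = as.character(dfr$strand),
    start0 = as.integer(dfr$start) - 1L,
    end0 = as.integer(dfr$end),
    gene_id = as.character(dfr$gene_id),
    transcript_id = as.character(dfr$transcript_id)
  )
  df$strand[!df$strand %in% c("+", "-")] <- "+"
  out <- df %>%
    group_by(.data$gene_id, .data$transcript_id, .data$chrom, .data$strand) %>%
    summarise(
      exon_starts = list(sort(.data$start0)),
      exon_ends = list(.data$end0[order(.data$start0)]),
      tx_start = min(.data$start0), tx_end = max(.data$end0),
      .groups = "drop"
    ) %>%
    mutate(cds_start = .data$tx_start, cds_end = .data$tx_end) %>%
    select("gene_id", "transcript_id", "chrom", "strand", "tx_start",
           "tx_end", "cds_start", "cds_end", "exon_starts", "exon_ends")
  validate_gene_models(out)
}

#' Exon-model lengths
#'
#' The exon-model length of a transcript is the summed length of its exon
#' intervals, the L term of the RPKM formula.
#'
#' @param models A gene-model tibble.
#' @return A tibble with `transcript_id`, `gene_id`, `length` (bases).
#' @export
exon_model_lengths <- function(models) {
  tibble(
    transcript_id = models$transcript_id,
    gene_id = models$gene_id,
    length = purrr::map2_int(models$exon_ends, models$exon_starts,
                             ~ sum(.x - .y))
  )
}

#' Per-exon table of a gene-model set
#'
#' Expands gene models to one row per exon with a canonical exon identifier
#' `<transcript_id>:e<index>` (index in genomic start order).
#'
#' @param models A gene-model tibble.
#' @return Tibble with `exon_id`, `transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `length`.
#' @export
exon_table <- function(models) {
  purrr::map_dfr(seq_len(nrow(models)), function(i) {
    s <- models$exon_starts[[i]]
    e <- models$exon_ends[[i]]
    tibble(
      exon_id = paste0(models$transcript_id[i], ":e", seq_along(s)),
      transcript_id = models$transcript_id[i],
      gene_id = models$gene_id[i],
      chrom = models$chrom[i],
      start = s, end = e, length = e - s
    )
  })
}

#' Splice junctions implied by contiguous transcripts
#'
#' Junction identity is `(chrom, donor_end, acceptor_start)` without strand;
#' strand is carried on the gene. Canonical identifier:
#' `chrom:donor_end-acceptor_start`.
#'
#' @param models A gene-model tibble.
#' @return Tibble with `junction_id`, `transcript_id`, `gene_id`, `chrom`,
#'   `donor_end`, `acceptor_start`.
#' @export
transcript_junctions <- function(models) {
  purrr::map_dfr(seq_len(nrow(models)), function(i) {
    s <- models$exon_starts[[i]]
    e <- models$exon_ends[[i]]
    k <- length(s)
    if (k < 2) {
      return(tibble(junction_id = character(), transcript_id = character(),
                    gene_id = character(), chrom = character(),
                    donor_end = integer(), acceptor_start = integer()))
    }
    donor <- e[-k]
    acceptor <- s[-1]
    tibble(
      junction_id = junction_id(models$chrom[i], donor, acceptor),
      transcript_id = models$transcript_id[i],
      gene_id = models$gene_id[i],
      chrom = models$chrom[i],
      donor_end = donor, acceptor_start = acceptor
    )
  })
}

#' Canonical junction identifier
#'
#' @param chrom Chromosome name.
#' @param donor_end 0-based-exclusive end of the donor exon.
#' @param acceptor_start 0-based start of the acceptor exon.
#' @return `chrom:donor_end-acceptor_start` character vector.
#' @export
junction_id <- function(chrom, donor_end, acceptor_start) {
  paste0(chrom, ":", donor_end, "-", acceptor_start)
}

#' Convert genomic interval display coordinates
#'
#' Internal coordinates are 0-based half-open; display coordinates are
#' 1-based inclusive. The two functions are exact inverses.
#'
#' @param start,end Interval bounds.
#' @return A list with converted `start` and `end`.
#' @export
to_display_coords <- function(start, end) list(start = start + 1L, end = end)

#' @rdname to_display_coords
#' @export
from_display_coords <- function(start, end) list(start = start - 1L, end = end)
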