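# Small in-code fixtures shared across test files.

# a three-transcript annotation: single-exon, two-exon, and a three-exon
# transcript carrying a cassette exon
tiny_models <- function() {
  validate_gene_models(tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    transcript_id = c("tA", "tB", "tC"),
    chrom = "chr1",
    strand = c("+", "-", "+"),
    tx_start = c(100L, 1000L, 5000L),
    tx_end = c(200L, 2000L, 7000L),
    cds_start = c(100L, 1000L, 5000L),
    cds_end = c(200L, 2000L, 7000L),
    exon_starts = list(100L, c(1000L, 1800L), c(5000L, 5500L, 6500L)),
    exon_ends = list(200L, c(1200L, 2000L), c(5200L, 5700L, 7000L))
  ))
}

# reciprocal pair for tC's middle exon: inclusion = flanking junctions,
# exclusion = skip junction
tiny_catalog <- function() {
  validate_catalog(tibble::tibble(
    event_id = "gC:cass2",
    gene_id = "gC",
    inclusion_junctions = list(c("chr1:5200-5500", "chr1:5700-6500")),
    exclusion_junctions = list("chr1:5200-6500")
  ))
}

two_group_design <- function(n = 3, groups = c("D", "N")) {
  tibble::tibble(
    sample_id = paste0(rep(groups, each = n), "_", rep(seq_len(n), length(groups))),
    group = rep(groups, each = n),
    replicate_index = rep(seq_len(n), length(groups))
  )
}

# independent brute-force SAM d over all label assignments (the oracle;
# deliberately re-derives the statistic from first principles)
brute_force_sam_d <- function(x, n1, s0) {
  x <- as.matrix(x)
  n <- ncol(x)
  combos <- utils::combn(n, n1)
  vapply(seq_len(ncol(combos)), function(j) {
    case <- combos[, j]
    ctrl <- setdiff(seq_len(n), case)
    apply(x, 1, function(y) {
      m1 <- mean(y[case]); m2 <- mean(y[ctrl])
      sp2 <- (sum((y[case] - m1)^2) + sum((y[ctrl] - m2)^2)) /
        (length(case) + length(ctrl) - 2)
      se <- sqrt(sp2 * (1 / length(case) + 1 / length(ctrl)))
      (m1 - m2) / (se + s0)
    })
  }, numeric(nrow(x)))
}

# a one-gene junction/exon dataset with explicit per-sample inclusion and
# exclusion counts (one inclusion junction for exactness)
one_event_counts <- function(incl, excl, exon = NULL, samples = names(incl)) {
  if (is.null(samples)) samples <- paste0("s", seq_along(incl))
  jx <- tibble::tibble(feature_id = c("chr1:5200-5500", "chr1:5200-6500"))
  ex <- tibble::tibble(feature_id = "tC:e1")
  for (i in seq_along(samples)) {
    jx[[samples[i]]] <- unname(c(incl[i], excl[i]))
    ex[[samples[i]]] <- unname(if (is.null(exon)) incl[i] + excl[i] else exon[i])
  }
  list(junction = jx, exon = ex)
}

one_event_catalog <- function() {
  validate_catalog(tibble::tibble(
    event_id = "gC:ev1", gene_id = "gC",
    inclusion_junctions = list("chr1:5200-5500"),
    exclusion_junctions = list("chr1:5200-6500")
  ))
}

one_event_models <- function() {
  validate_gene_models(tibble::tibble(
    gene_id = "gC", transcript_id = "tC", chrom = "chr1", strand = "+",
    tx_start = 5000L, tx_end = 5700L, cds_start = 5000L, cds_end = 5700L,
    exon_starts = list(c(5000L, 5500L)), exon_ends = list(c(5200L, 5700L))
  ))
}
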