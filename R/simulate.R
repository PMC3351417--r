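#' Simulation configuration
#'
#' The generator emulates the study design: 4 groups (N, D, D_T1, D_T2) x 3
#' biological replicates, negative-binomial transcript counts, planted
#' disease fold changes with treatment-response patterns, and planted
#' cassette-exon events with specified inclusion shifts. The default library
#' size of 1e6 reads per sample is a scaled-down stand-in for the study's
#' 13.8-20.9 million aligned reads.
#'
#' @param n_transcripts Number of simulated transcripts (one per gene).
#' @param n_replicates Biological replicates per group (default 3).
#' @param library_size Target aligned reads per sample.
#' @param frac_de Fraction of transcripts with a planted disease effect.
#' @param log2fc_grid Disease |log2 fold| values planted (default
#'   0.585 = 1.5-fold, 1, 2 = 4-fold, 4.3).
#' @param dispersion Negative-binomial dispersion phi (variance =
#'   mu + phi mu^2), constant per transcript.
#' @param n_cassette_events Transcripts carrying a cassette exon.
#' @param delta_i_grid Planted |Delta-I| inclusion shifts.
#' @param frac_side_effect Fraction of transcripts unchanged by disease but
#'   altered by a treatment (side-effect-only pattern).
#' @param junction_span Effective junction span in bases tying junction read
#'   depth to exon depth (default 50).
#' @param expr_meanlog,expr_sdlog Log-normal parameters of relative
#'   expression for ordinary transcripts.
#' @param cassette_meanlog,cassette_sdlog Log-normal parameters for
#'   cassette-carrying transcripts; the high default stratum mimics the
#'   retina's dominant transcripts so junction coverage supports splicing
#'   analysis at the scaled-down library size.
#' @param seed Mandatory RNG seed; all stages derive their streams from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_transcripts = 2000, n_replicates = 3,
                       library_size = 1e6, frac_de = 0.1,
                       log2fc_grid = c(0.585, 1, 2, 4.3),
                       dispersion = 0.05, n_cassette_events = 100,
                       delta_i_grid = c(0.2, 0.3, 0.4),
                       frac_side_effect = 0.05, junction_span = 50,
                       expr_meanlog = log(50), expr_sdlog = 1.0,
                       cassette_meanlog = log(2000), cassette_sdlog = 0.6,
                       seed) {
  if (missing(seed) || is.null(seed)) abort("sim_config() requires a seed")
  cfg <- list(n_transcripts = n_transcripts, n_replicates = n_replicates,
              library_size = library_size, frac_de = frac_de,
              log2fc_grid = log2fc_grid, dispersion = dispersion,
              n_cassette_events = n_cassette_events,
              delta_i_grid = delta_i_grid,
              frac_side_effect = frac_side_effect,
              junction_span = junction_span,
              expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
              cassette_meanlog = cassette_meanlog,
              cassette_sdlog = cassette_sdlog,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_transcripts >= 1, cfg$n_replicates >= 2,
            cfg$library_size > 0, cfg$dispersion >= 0,
            cfg$junction_span > 0, cfg$n_cassette_events >= 0)
  if (cfg$frac_de < 0 || cfg$frac_de > 1) abort("frac_de must be in [0, 1]")
  if (cfg$frac_side_effect < 0 || cfg$frac_side_effect > 1) {
    abort("frac_side_effect must be in [0, 1]")
  }
  if (cfg$n_cassette_events > cfg$n_transcripts) {
    abort("n_cassette_events cannot exceed n_transcripts")
  }
  if (any(cfg$delta_i_grid <= 0) || any(cfg$delta_i_grid > 0.5)) {
    abort("delta_i_grid values must lie in (0, 0.5] (baseline inclusion 0.5)")
  }
  if (any(cfg$log2fc_grid <= 0)) abort("log2fc_grid values must be > 0")
  invisible(cfg)
}

#' Sample design for a simulated experiment
#'
#' @param config A [sim_config()].
#' @return Design tibble: `sample_id` (e.g. `"D_2"`), `group`,
#'   `replicate_index`; all four groups, `n_replicates` each.
#' @export
simulate_design <- function(config) {
  tidyr::expand_grid(group = study_groups(),
                     replicate_index = seq_len(config$n_replicates)) %>%
    mutate(sample_id = paste0(.data$group, "_", .data$replicate_index)) %>%
    select("sample_id", "group", "replicate_index")
}

#' Simulate gene models and a reciprocal-pair catalog
#'
#' Each transcript gets 2-12 exons of length 50-300 bases on a synthetic
#' chromosome. The first `n_cassette_events` transcripts (which always get
#' at least 3 exons) carry a cassette exon: its two flanking junctions
#' support the inclusion isoform and the skip junction joining the flanking
#' exons supports the exclusion isoform. Deterministic given the seed.
#'
#' @param config A [sim_config()].
#' @return List with `models` (gene-model tibble) and `catalog`
#'   (reciprocal-pair catalog; one event per cassette transcript).
#' @export
simulate_gene_models <- function(config) {
  set.seed(config$seed)
  n <- config$n_transcripts
  n_cass <- config$n_cassette_events
  cursor <- 10000L
  chrom <- "chrS1"
  rows <- vector("list", n)
  cat_rows <- vector("list", n_cass)
  for (i in seq_len(n)) {
    is_cass <- i <= n_cass
    n_exon <- if (is_cass) sample(3:12, 1) else sample(2:12, 1)
    ex_len <- sample(50:300, n_exon, replace = TRUE)
    introns <- sample(200:2000, n_exon - 1, replace = TRUE)
    starts <- integer(n_exon); ends <- integer(n_exon)
    pos <- cursor
    for (k in seq_len(n_exon)) {
      starts[k] <- pos
      ends[k] <- pos + ex_len[k]
      pos <- ends[k] + if (k < n_exon) introns[k] else 0L
    }
    cursor <- pos + sample(1000:5000, 1)
    tid <- sprintf("t%05d", i)
    gid <- sprintf("g%05d", i)
    rows[[i]] <- tibble(
      gene_id = gid, transcript_id = tid, chrom = chrom,
      strand = sample(c("+", "-"), 1),
      tx_start = starts[1], tx_end = ends[n_exon],
      cds_start = starts[1], cds_end = ends[n_exon],
      exon_starts = list(starts), exon_ends = list(ends)
    )
    if (is_cass) {
      k <- if (n_exon == 3) 2L else sample(2:(n_exon - 1), 1)
      incl <- junction_id(chrom, c(ends[k - 1], ends[k]),
                          c(starts[k], starts[k + 1]))
      excl <- junction_id(chrom, ends[k - 1], starts[k + 1])
      cat_rows[[i]] <- tibble(
        event_id = paste0(gid, ":cass", k), gene_id = gid,
        cassette_exon = k,
        inclusion_junctions = list(incl), exclusion_junctions = list(excl)
      )
    }
  }
  models <- validate_gene_models(bind_rows(rows))
  catalog <- if (n_cass > 0) validate_catalog(bind_rows(cat_rows)) else
    tibble(event_id = character(), gene_id = character(),
           cassette_exon = integer(), inclusion_junctions = list(),
           exclusion_junctions = list())
  list(models = models, catalog = catalog)
}

#' Plant the ground truth of a simulation
#'
#' Allocates disease differential-expression patterns, per-treatment
#' response patterns, and cassette-exon inclusion shifts, and rescales base
#' expression so expected per-sample counts sum to the target library size.
#'
#' Treatment patterns act multiplicatively on the disease log2 fold d:
#' full_reversal -> 0, partial_reversal -> 0.4 d, exacerbation -> 1.6 d,
#' none -> d (unresponsive), side_effect_only -> d = 0 with a treated log2
#' fold drawn from the grid. Disease effects are planted on non-cassette
#' transcripts only, decoupling expression and splicing truth. Splice
#' patterns over events: 20% null, 40% responsive (disease shift reversed by
#' both drugs), 20% unresponsive (shift persists under both), 10%
#' exacerbated by T1 only, 10% by T2 only; baseline inclusion is 0.5.
#'
#' @param config A [sim_config()].
#' @param models,catalog Output of [simulate_gene_models()].
#' @return A `truth_ledger`: list of `transcripts` (base_expression on RPKM
#'   scale, dispersion, de_pattern, disease_log2fc, pattern/log2fc per
#'   treatment) and `events` (splice_pattern, planted inclusion per group,
#'   `planted_delta` = I_D - I_N).
#' @export
simulate_truth <- function(config, models, catalog) {
  set.seed(config$seed + 1L)
  n <- config$n_transcripts
  lens <- exon_model_lengths(models)
  is_cass <- models$gene_id %in% catalog$gene_id

  base <- numeric(n)
  base[is_cass] <- stats::rlnorm(sum(is_cass), config$cassette_meanlog,
                                 config$cassette_sdlog)
  base[!is_cass] <- stats::rlnorm(sum(!is_cass), config$expr_meanlog,
                                  config$expr_sdlog)

  n_de <- round(config$frac_de * n)
  n_side <- round(config$frac_side_effect * n)
  pool <- which(!is_cass)
  if (length(pool) < n_de + n_side) {
    abort("not enough non-cassette transcripts for the requested DE and side-effect fractions")
  }
  de_idx <- sample(pool, n_de)
  side_idx <- sample(setdiff(pool, de_idx), n_side)

  de_pattern <- rep("null", n)
  d_lfc <- numeric(n)
  sign_de <- sample(c(-1, 1), n_de, replace = TRUE)
  d_lfc[de_idx] <- sample(config$log2fc_grid, n_de, replace = TRUE) * sign_de
  de_pattern[de_idx] <- ifelse(d_lfc[de_idx] > 0, "disease_up", "disease_down")

  trt_patterns <- c("full_reversal", "partial_reversal", "exacerbation", "none")
  pat_t1 <- rep("none", n); pat_t2 <- rep("none", n)
  pat_t1[de_idx] <- sample(trt_patterns, n_de, replace = TRUE)
  pat_t2[de_idx] <- sample(trt_patterns, n_de, replace = TRUE)
  side_which <- sample(c("T1", "T2", "both"), n_side, replace = TRUE)
  pat_t1[side_idx[side_which != "T2"]] <- "side_effect_only"
  pat_t2[side_idx[side_which != "T1"]] <- "side_effect_only"

  side_lfc <- function(k) {
    sample(config$log2fc_grid, k, replace = TRUE) *
      sample(c(-1, 1), k, replace = TRUE)
  }
  treated_lfc <- function(pattern, d) {
    out <- numeric(length(d))
    out[pattern == "none"] <- d[pattern == "none"]
    out[pattern == "partial_reversal"] <- 0.4 * d[pattern == "partial_reversal"]
    out[pattern == "exacerbation"] <- 1.6 * d[pattern == "exacerbation"]
    k <- sum(pattern == "side_effect_only")
    if (k > 0) out[pattern == "side_effect_only"] <- side_lfc(k)
    out  # full_reversal stays 0
  }
  # "none" on a null transcript means no change at all
  lfc_t1 <- treated_lfc(pat_t1, d_lfc)
  lfc_t2 <- treated_lfc(pat_t2, d_lfc)

  # rescale base expression so the design-wide expected read total per
  # sample equals the target library size (sum of RPKM x L_kb = 1e6,
  # averaged over the four groups' fold factors); planted fold ratios are
  # untouched by the common scale
  mass_kb <- base * lens$length / 1000
  group_mass <- mean(c(sum(mass_kb), sum(mass_kb * 2^d_lfc),
                       sum(mass_kb * 2^lfc_t1), sum(mass_kb * 2^lfc_t2)))
  base <- base * 1e6 / group_mass

  transcripts <- tibble(
    transcript_id = models$transcript_id,
    gene_id = models$gene_id,
    length = lens$length,
    base_expression = base,
    dispersion = config$dispersion,
    de_pattern = de_pattern,
    disease_log2fc = d_lfc,
    pattern_t1 = pat_t1, pattern_t2 = pat_t2,
    log2fc_t1 = lfc_t1, log2fc_t2 = lfc_t2
  )

  events <- if (nrow(catalog) > 0) {
    ne <- nrow(catalog)
    alloc <- rep(c("null", "responsive", "unresponsive",
                   "exacerbated_T1", "exacerbated_T2"),
                 times = round(ne * c(0.2, 0.4, 0.2, 0.1, 0.1)))
    alloc <- c(alloc, rep("null", max(0, ne - length(alloc))))[seq_len(ne)]
    alloc <- sample(alloc)
    delta <- sample(config$delta_i_grid, ne, replace = TRUE) *
      sample(c(-1, 1), ne, replace = TRUE)
    i_n <- rep(0.5, ne)
    i_d <- ifelse(alloc %in% c("responsive", "unresponsive"),
                  0.5 + delta, 0.5)
    i_t1 <- ifelse(alloc == "unresponsive", 0.5 + delta,
                   ifelse(alloc == "exacerbated_T1", 0.5 + delta, 0.5))
    i_t2 <- ifelse(alloc == "unresponsive", 0.5 + delta,
                   ifelse(alloc == "exacerbated_T2", 0.5 + delta, 0.5))
    tibble(event_id = catalog$event_id, gene_id = catalog$gene_id,
           splice_pattern = alloc,
           i_n = i_n, i_d = i_d, i_t1 = i_t1, i_t2 = i_t2,
           planted_delta = i_d - i_n)
  } else {
    tibble(event_id = character(), gene_id = character(),
           splice_pattern = character(), i_n = numeric(), i_d = numeric(),
           i_t1 = numeric(), i_t2 = numeric(), planted_delta = numeric())
  }

  structure(list(transcripts = transcripts, events = events),
            class = "truth_ledger")
}

rnbinom_disp <- function(n, mu, dispersion) {
  if (dispersion <= 0) return(rpois(n, mu))
  rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate count tables from planted truth
#'
#' Transcript counts are negative binomial with mean = base expression x
#' group fold factor x exon-model length (kb) x library scaling, at the
#' ledger's dispersion. Sequencing depth is fixed per sample: expected
#' per-sample totals are normalized to the target library size, so strong
#' upregulation crowds out the read counts of unchanged transcripts exactly
#' as on a real sequencer. Exon counts are an exact multinomial split of each
#' transcript count proportional to exon lengths (they sum to the transcript
#' count by construction). Junction counts are negative binomial at a depth
#' tied to transcript RPKM through the effective junction span; for cassette
#' events the inclusion junctions carry the group's planted inclusion
#' fraction I and the skip junction 1 - I. Per-sample library sizes are the
#' transcript-count column sums (the simulated features constitute the whole
#' library). Fully deterministic given config + seed.
#'
#' @param models,catalog Output of [simulate_gene_models()].
#' @param design Design tibble from [simulate_design()].
#' @param truth A `truth_ledger` from [simulate_truth()].
#' @param config The [sim_config()].
#' @return List: `transcript`, `exon`, `junction` count tibbles,
#'   `lib_sizes` (named), `design`.
#' @export
simulate_counts <- function(models, catalog, design, truth, config) {
  set.seed(config$seed + 2L)
  tr <- truth$transcripts
  if (!setequal(tr$transcript_id, models$transcript_id)) {
    abort("truth ledger does not cover the same transcripts as the models")
  }
  tr <- tr[match(models$transcript_id, tr$transcript_id), ]
  n <- nrow(tr)
  samples <- design$sample_id
  lfc_by_group <- cbind(N = 0, D = tr$disease_log2fc,
                        D_T1 = tr$log2fc_t1, D_T2 = tr$log2fc_t2)
  grp <- design$group[match(samples, design$sample_id)]

  rpkm_mat <- tr$base_expression * 2^lfc_by_group[, grp, drop = FALSE]
  colnames(rpkm_mat) <- samples
  # fixed sequencing depth: each sample yields the target number of reads,
  # so upregulated transcripts crowd out the counts of the others (as on a
  # real sequencer); expected column sums equal the target library size
  mass <- colSums(rpkm_mat * (tr$length / 1000))
  rpkm_mat <- sweep(rpkm_mat, 2, 1e6 / mass, `*`)
  mu_tx <- rpkm_mat * (tr$length / 1000) * (config$library_size / 1e6)

  tx_counts <- matrix(0, n, length(samples), dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    tx_counts[, j] <- rnbinom_disp(n, mu_tx[, j], config$dispersion)
  }

  # exact multinomial split of transcript counts over exons
  ex_tbl <- exon_table(models)
  ex_by_tx <- split(seq_len(nrow(ex_tbl)), ex_tbl$transcript_id)
  ex_counts <- matrix(0, nrow(ex_tbl), length(samples),
                      dimnames = list(NULL, samples))
  for (i in seq_len(n)) {
    rows <- ex_by_tx[[models$transcript_id[i]]]
    lens <- ex_tbl$length[rows]
    if (length(rows) == 1) {
      ex_counts[rows, ] <- tx_counts[i, ]
    } else {
      for (j in seq_along(samples)) {
        ex_counts[rows, j] <- rmultinom(1, tx_counts[i, j], prob = lens)
      }
    }
  }

  # junction means on the same RPKM scale through the effective span
  tj <- transcript_junctions(models)
  span_mu <- function(rpkm_vec) {
    rpkm_vec * config$junction_span / 1000 * (config$library_size / 1e6)
  }
  tx_row <- match(tj$transcript_id, models$transcript_id)
  jx_mu <- span_mu(rpkm_mat[tx_row, , drop = FALSE])
  jx_id <- tj$junction_id
  incl_frac <- matrix(1, nrow(tj), length(samples))
  skip_rows <- NULL
  if (nrow(catalog) > 0) {
    ev <- truth$events[match(catalog$event_id, truth$events$event_id), ]
    i_by_group <- cbind(N = ev$i_n, D = ev$i_d, D_T1 = ev$i_t1,
                        D_T2 = ev$i_t2)[, grp, drop = FALSE]
    for (e in seq_len(nrow(catalog))) {
      rows <- which(jx_id %in% catalog$inclusion_junctions[[e]] &
                      tj$gene_id == catalog$gene_id[e])
      incl_frac[rows, ] <- rep(i_by_group[e, ], each = length(rows))
    }
    # skip junctions: one extra feature per event
    skip_gene_tx <- match(catalog$gene_id, models$gene_id)
    skip_mu <- span_mu(rpkm_mat[skip_gene_tx, , drop = FALSE]) *
      (1 - i_by_group)
    skip_rows <- list(
      id = purrr::map_chr(catalog$exclusion_junctions, 1),
      mu = skip_mu
    )
  }
  jx_mu <- jx_mu * incl_frac
  all_ids <- c(jx_id, if (!is.null(skip_rows)) skip_rows$id)
  all_mu <- rbind(jx_mu, if (!is.null(skip_rows)) skip_rows$mu)
  jx_counts <- matrix(0, nrow(all_mu), length(samples),
                      dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    jx_counts[, j] <- rnbinom_disp(nrow(all_mu), all_mu[, j],
                                   config$dispersion)
  }

  lib_sizes <- colSums(tx_counts)
  list(
    transcript = bind_cols(tibble(feature_id = models$transcript_id),
                           as_tibble(tx_counts)),
    exon = bind_cols(tibble(feature_id = ex_tbl$exon_id),
                     as_tibble(ex_counts)),
    junction = bind_cols(tibble(feature_id = all_ids),
                         as_tibble(jx_counts)),
    lib_sizes = lib_sizes,
    design = design
  )
}

#' Simulate a complete dataset in one call
#'
#' Convenience wrapper chaining [simulate_gene_models()],
#' [simulate_design()], [simulate_truth()] and [simulate_counts()].
#'
#' @param config A [sim_config()].
#' @return List: `models`, `catalog`, `design`, `truth`, `counts`.
#' @export
simulate_dataset <- function(config) {
  gm <- simulate_gene_models(config)
  design <- simulate_design(config)
  truth <- simulate_truth(config, gm$models, gm$catalog)
  counts <- simulate_counts(gm$models, gm$catalog, design, truth, config)
  list(models = gm$models, catalog = gm$catalog, design = design,
       truth = truth, counts = counts)
}
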