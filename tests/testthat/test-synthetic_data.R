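test_that("the generator is fully deterministic given config + seed", {
  cfg <- sim_config(n_transcripts = 40, n_cassette_events = 5, seed = 4)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$counts$transcript, b$counts$transcript)
  expect_identical(a$counts$exon, b$counts$exon)
  expect_identical(a$counts$junction, b$counts$junction)
  expect_identical(a$truth$transcripts, b$truth$transcripts)
  expect_identical(a$models, b$models)
})

test_that("gene-model generation honors the configured sizes", {
  cfg1 <- sim_config(n_transcripts = 1, n_cassette_events = 0, seed = 1)
  one <- simulate_gene_models(cfg1)
  expect_equal(nrow(one$models), 1)
  expect_identical(simulate_gene_models(cfg1)$models, one$models)

  cfg5 <- sim_config(n_transcripts = 30, n_cassette_events = 5, seed = 2)
  gm <- simulate_gene_models(cfg5)
  expect_equal(nrow(gm$catalog), 5)
  expect_true(all(lengths(gm$catalog$inclusion_junctions) == 2))
  expect_true(all(lengths(gm$catalog$exclusion_junctions) == 1))
  ex_len <- purrr::map2(gm$models$exon_ends, gm$models$exon_starts, `-`)
  expect_true(all(unlist(ex_len) >= 50 & unlist(ex_len) <= 300))
  n_ex <- lengths(gm$models$exon_starts)
  expect_true(all(n_ex >= 2 & n_ex <= 12))

  # different seeds give different exon-length multisets
  lens_by_seed <- purrr::map(1:10, function(s) {
    m <- simulate_gene_models(sim_config(n_transcripts = 10,
                                         n_cassette_events = 0, seed = s))
    sort(unlist(purrr::map2(m$models$exon_ends, m$models$exon_starts, `-`)))
  })
  distinct <- length(unique(purrr::map_chr(lens_by_seed, paste, collapse = ",")))
  expect_gt(distinct, 8)
})

test_that("exon counts conserve transcript counts exactly", {
  cfg <- sim_config(n_transcripts = 30, n_cassette_events = 5, seed = 6)
  ds <- simulate_dataset(cfg)
  ex <- ds$counts$exon |>
    dplyr::mutate(transcript_id = sub(":e[0-9]+$", "", feature_id)) |>
    dplyr::group_by(transcript_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(ds$design$sample_id), sum))
  tx <- ds$counts$transcript[match(ex$transcript_id, ds$counts$transcript$feature_id), ]
  for (s in ds$design$sample_id) expect_identical(ex[[s]], tx[[s]])
})

test_that("per-sample totals land near the target library size", {
  cfg <- sim_config(n_transcripts = 1000, n_cassette_events = 50, seed = 8)
  ds <- simulate_dataset(cfg)
  sums <- colSums(count_values(ds$counts$transcript))
  expect_true(all(abs(sums - cfg$library_size) / cfg$library_size < 0.10))
  expect_identical(unname(ds$counts$lib_sizes), unname(sums))
})

test_that("replicate noise follows the negative-binomial mean-variance law", {
  cfg <- sim_config(n_transcripts = 500, n_cassette_events = 0,
                    frac_de = 0, frac_side_effect = 0, dispersion = 0.05,
                    seed = 10)
  ds <- simulate_dataset(cfg)
  tr <- ds$truth$transcripts
  mu <- tr$base_expression * tr$length / 1000 *
    cfg$library_size / 1e6
  cnt <- count_values(ds$counts$transcript)   # 12 null replicates each
  keep <- mu > 5
  v_obs <- apply(cnt[keep, ], 1, var)
  v_exp <- mu[keep] + cfg$dispersion * mu[keep]^2
  ratio <- mean(v_obs / v_exp)
  expect_lt(abs(ratio - 1), 0.15)
})

test_that("planted fold factors are recovered in the low-dispersion limit", {
  cfg <- sim_config(n_transcripts = 400, n_cassette_events = 0,
                    frac_de = 0.05, frac_side_effect = 0,
                    log2fc_grid = 1, dispersion = 0, seed = 7,
                    expr_meanlog = log(400), expr_sdlog = 0.3)
  ds <- simulate_dataset(cfg)
  tr <- ds$truth$transcripts
  de <- tr[tr$de_pattern != "null", ]
  cnt <- ds$counts$transcript
  d_cols <- paste0("D_", 1:3); n_cols <- paste0("N_", 1:3)
  ratios <- purrr::map_dbl(de$transcript_id, function(id) {
    row <- cnt[cnt$feature_id == id, ]
    r <- mean(as.numeric(row[, d_cols])) / mean(as.numeric(row[, n_cols]))
    r^sign(de$disease_log2fc[de$transcript_id == id])
  })
  expect_lt(abs(mean(ratios) - 2), 0.1)  # planted fold 2, tolerance 5%
})

test_that("null inclusion planting centers empirical delta-I at zero", {
  cfg <- sim_config(n_transcripts = 220, n_cassette_events = 200,
                    frac_de = 0, frac_side_effect = 0, seed = 7)
  gm <- simulate_gene_models(cfg)
  design <- simulate_design(cfg)
  truth <- simulate_truth(cfg, gm$models, gm$catalog)
  truth$events$i_d <- 0.5
  truth$events$i_t1 <- 0.5
  truth$events$i_t2 <- 0.5
  truth$events$planted_delta <- 0
  counts <- simulate_counts(gm$models, gm$catalog, design, truth, cfg)
  ev <- aspire_scan(counts$junction, counts$exon, gm$catalog, expr = NULL,
                    models = gm$models, design = design,
                    contrast = c("D", "N"))
  di <- ev$delta_i[!ev$excluded]
  expect_gt(length(di), 150)
  expect_lt(abs(mean(di)), 0.05)
})

test_that("config validation guards fractions, seeds, and id coverage", {
  expect_error(sim_config(seed = NULL), "seed")
  expect_error(sim_config(frac_de = 1.2, seed = 1), "frac_de")
  expect_error(sim_config(delta_i_grid = 0.7, seed = 1), "delta_i_grid")
  expect_error(sim_config(n_transcripts = 3, n_cassette_events = 5, seed = 1),
               "n_cassette_events")
  cfg <- sim_config(n_transcripts = 10, n_cassette_events = 0, seed = 1)
  gm <- simulate_gene_models(cfg)
  design <- simulate_design(cfg)
  truth <- simulate_truth(cfg, gm$models, gm$catalog)
  truth$transcripts$transcript_id[1] <- "bogus"
  expect_error(simulate_counts(gm$models, gm$catalog, design, truth, cfg),
               "truth ledger")
})

test_that("side-effect-only truth never coincides with a disease effect", {
  cfg <- sim_config(n_transcripts = 400, n_cassette_events = 10, seed = 12)
  truth <- simulate_dataset(cfg)$truth$transcripts
  side <- truth$pattern_t1 == "side_effect_only" |
    truth$pattern_t2 == "side_effect_only"
  expect_gt(sum(side), 0)
  expect_true(all(truth$de_pattern[side] == "null"))
  expect_true(all(truth$disease_log2fc[side] == 0))
  expect_true(all(truth$dispersion > 0))
})
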