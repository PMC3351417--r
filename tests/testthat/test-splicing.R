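test_that("junction fractions normalize by the gene-wide mean", {
  # one junction (count 10) + one exon (count 10): mean 10, f = 1
  cnt <- one_event_counts(incl = c(s1 = 10), excl = c(s1 = 0), exon = 10)
  # drop the exclusion row to get the single-junction case
  jx <- cnt$junction[1, ]
  fr <- junction_fraction(jx, cnt$exon, one_event_models())
  expect_equal(fr$f, c(1, 1))

  # equal counts everywhere -> every f = 1
  fr2 <- junction_fraction(cnt$junction[1, ], cnt$exon, one_event_models())
  expect_true(all(fr2$f == 1))

  # scaling all counts of the gene by k leaves f unchanged
  jx_k <- jx; jx_k$s1 <- jx_k$s1 * 7
  ex_k <- cnt$exon; ex_k$s1 <- ex_k$s1 * 7
  fr_k <- junction_fraction(jx_k, ex_k, one_event_models())
  expect_equal(fr_k$f, fr$f)

  # zero total coverage -> undefined fractions, flagged
  jx0 <- jx; jx0$s1 <- 0
  ex0 <- cnt$exon; ex0$s1 <- 0
  fr0 <- junction_fraction(jx0, ex0, one_event_models())
  expect_true(all(is.na(fr0$f)))
})

test_that("inclusion ratio covers symmetry, boundary, and cancellation", {
  expect_equal(inclusion_ratio(0.3, 0.3), 0.5)
  expect_equal(inclusion_ratio(0.4, 0), 1)
  expect_true(is.na(inclusion_ratio(0, 0)))
  expect_error(inclusion_ratio(-1, 2), ">= 0")
  # gene-mean normalizer cancels: I from raw counts equals I from fractions
  counts <- c(incl = 70, excl = 30, exon = 260)
  m <- mean(counts)
  expect_equal(inclusion_ratio(70 / m, 30 / m), 0.7, tolerance = 1e-15)
})

test_that("delta-I is the case-minus-control mean inclusion difference", {
  expect_equal(delta_i(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(delta_i(70 / 100, 50 / 100), 0.2)
  expect_equal(delta_i(c(0.3, 0.5), c(0.6, 0.8)), -0.3)
  # antisymmetry
  x <- c(0.2, 0.4, 0.9); y <- c(0.1, 0.5, 0.5)
  expect_equal(delta_i(x, y), -delta_i(y, x))
})

test_that("the worked single-pair example yields delta-I 0.2 end to end", {
  cnt <- one_event_counts(incl = c(case = 70, ctrl = 50),
                          excl = c(case = 30, ctrl = 50))
  design <- tibble::tibble(sample_id = c("case", "ctrl"),
                           group = c("D", "N"), replicate_index = 1L)
  ev <- aspire_scan(cnt$junction, cnt$exon, one_event_catalog(),
                    expr = NULL, models = one_event_models(),
                    design = design, contrast = c("D", "N"))
  expect_equal(ev$delta_i, 0.2, tolerance = 1e-12)
  expect_equal(ev$i_bar_case, 0.7, tolerance = 1e-12)
  expect_equal(ev$i_bar_control, 0.5, tolerance = 1e-12)
})

test_that("exhaustive 3v3 splicing permutation p matches brute force", {
  set.seed(5)
  incl <- c(D_1 = 80, D_2 = 75, D_3 = 82, N_1 = 50, N_2 = 55, N_3 = 47)
  excl <- c(D_1 = 20, D_2 = 25, D_3 = 18, N_1 = 50, N_2 = 45, N_3 = 53)
  cnt <- one_event_counts(incl = incl, excl = excl)
  design <- two_group_design(3)
  ev <- aspire_scan(cnt$junction, cnt$exon, one_event_catalog(),
                    expr = NULL, models = one_event_models(),
                    design = design, contrast = c("D", "N"))
  # brute force over all 20 assignments of samples to the case side
  i_sample <- incl / (incl + excl)
  combos <- utils::combn(6, 3)
  stats <- apply(combos, 2, function(case) {
    abs(mean(i_sample[case]) - mean(i_sample[-case]))
  })
  obs <- abs(mean(i_sample[1:3]) - mean(i_sample[4:6]))
  expect_equal(ev$p_value, mean(stats >= obs - 1e-12), tolerance = 1e-12)
})

test_that("events with missing coverage are excluded with a reason", {
  incl <- c(D_1 = 0, D_2 = 0, D_3 = 0, N_1 = 50, N_2 = 55, N_3 = 47)
  excl <- c(D_1 = 0, D_2 = 0, D_3 = 0, N_1 = 50, N_2 = 45, N_3 = 53)
  # exon keeps gene coverage nonzero so fractions are defined but the event
  # has zero junction coverage in D
  cnt <- one_event_counts(incl = incl, excl = excl, exon = rep(100, 6))
  ev <- aspire_scan(cnt$junction, cnt$exon, one_event_catalog(),
                    expr = NULL, models = one_event_models(),
                    design = two_group_design(3), contrast = c("D", "N"))
  expect_true(ev$excluded)
  expect_match(ev$exclude_reason, "zero junction coverage")
  expect_false(ev$passes)
})

test_that("the expression gate removes events on low-RPKM genes", {
  cnt <- one_event_counts(incl = c(D_1 = 70, D_2 = 70, N_1 = 50, N_2 = 50),
                          excl = c(D_1 = 30, D_2 = 30, N_1 = 50, N_2 = 50))
  design <- tibble::tibble(sample_id = c("D_1", "D_2", "N_1", "N_2"),
                           group = c("D", "D", "N", "N"),
                           replicate_index = c(1L, 2L, 1L, 2L))
  low <- tibble::tibble(feature_id = "gC", D_1 = 1, D_2 = 1, N_1 = 1, N_2 = 1)
  high <- tibble::tibble(feature_id = "gC", D_1 = 5, D_2 = 5, N_1 = 5, N_2 = 5)
  ev_low <- aspire_scan(cnt$junction, cnt$exon, one_event_catalog(),
                        expr = low, models = one_event_models(),
                        design = design, contrast = c("D", "N"),
                        rpkm_cutoff = 3.0)
  ev_high <- aspire_scan(cnt$junction, cnt$exon, one_event_catalog(),
                         expr = high, models = one_event_models(),
                         design = design, contrast = c("D", "N"),
                         rpkm_cutoff = 3.0)
  expect_equal(nrow(ev_low), 0)
  expect_equal(nrow(ev_high), 1)
})

test_that("delta-I estimates are near-unbiased at high coverage", {
  cfg <- sim_config(n_transcripts = 520, n_cassette_events = 500,
                    delta_i_grid = c(0.2, 0.3, 0.4), frac_de = 0,
                    frac_side_effect = 0, library_size = 4e6, seed = 9)
  ds <- simulate_dataset(cfg)
  ev <- aspire_scan(ds$counts$junction, ds$counts$exon, ds$catalog,
                    expr = NULL, models = ds$models, design = ds$design,
                    contrast = c("D", "N"))
  cmp <- dplyr::inner_join(tidy(ev), ds$truth$events, by = "event_id") |>
    dplyr::filter(!excluded, coverage >= 100)
  expect_gt(nrow(cmp), 400)
  bias <- mean(cmp$delta_i - cmp$planted_delta)
  expect_lt(abs(bias), 0.02)
  # the reported event-level FDR is monotone in p and bounded in [0, 1]
  ord <- order(cmp$p_value)
  expect_true(all(diff(cmp$fdr[ord]) >= -1e-12))
  expect_true(all(cmp$fdr >= cmp$p_value - 1e-12 & cmp$fdr <= 1))
})
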