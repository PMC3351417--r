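rpkm_expr <- function(mat, samples = NULL) {
  out <- tibble::as_tibble(mat, .name_repair = "minimal")
  if (!is.null(samples)) names(out) <- samples
  out <- dplyr::bind_cols(tibble::tibble(feature_id = paste0("f", seq_len(nrow(mat)))), out)
  diaretseq:::set_expr_scale(out, "rpkm")
}

test_that("fold changes follow the magnitude-plus-direction convention", {
  design <- two_group_design(1)
  e <- rpkm_expr(cbind(c(19.8, 0.5, 3, 0), c(1, 1, 3, 0)),
                 samples = c("D_1", "N_1"))
  fc <- fold_change(e, design, c("D", "N"))
  expect_equal(fc$ratio[1], 19.8)
  expect_equal(fc$direction[1], "up")
  expect_equal(fc$ratio[2], 2.0)
  expect_equal(fc$direction[2], "down")
  expect_equal(fc$signed_log2[2], -1)
  expect_equal(fc$ratio[3], 1)
  expect_equal(fc$signed_log2[3], 0)
  expect_false(fc$defined[4])  # both means zero: undefined, excluded
})

test_that("two-group ANOVA F equals the squared pooled-variance t", {
  set.seed(11)
  design <- two_group_design(4)
  mat <- matrix(rnorm(50 * 8, mean = 5), 50, 8)
  e <- rpkm_expr(2^mat, samples = design$sample_id)
  de <- anova_de(e, design, c("D", "N"))
  tsq <- apply(log2(2^mat + 1), 1, function(y) {
    unname(t.test(y[1:4], y[5:8], var.equal = TRUE)$statistic)^2
  })
  expect_equal(de$statistic, tsq, tolerance = 1e-10)
})

test_that("ANOVA p-values are uniform under the null", {
  set.seed(21)
  design <- two_group_design(3)
  mat <- 2^matrix(rnorm(2000 * 6, mean = 6, sd = 0.6), 2000, 6)
  e <- rpkm_expr(mat, samples = design$sample_id)
  de <- anova_de(e, design, c("D", "N"))
  ks <- suppressWarnings(ks.test(de$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("ANOVA p-values are invariant to a location shift of log2 values", {
  set.seed(31)
  design <- two_group_design(3)
  mat <- matrix(rnorm(100 * 6, 5), 100, 6)
  base <- rpkm_expr(mat, samples = design$sample_id)
  base <- diaretseq:::set_expr_scale(base, "log2", offset = 1)
  shifted <- base
  for (s in design$sample_id) shifted[[s]] <- shifted[[s]] + 3.7
  shifted <- diaretseq:::set_expr_scale(shifted, "log2", offset = 1)
  expect_equal(anova_de(base, design, c("D", "N"))$p_value,
               anova_de(shifted, design, c("D", "N"))$p_value,
               tolerance = 1e-12)
})

test_that("zero-variance features are flagged rather than asserted", {
  design <- two_group_design(3)
  e <- rpkm_expr(matrix(4, 2, 6), samples = design$sample_id)
  de <- anova_de(e, design, c("D", "N"))
  expect_true(all(is.na(de$p_value)))
  expect_false(any(de$passes))
})

test_that("exhaustive 3v3 permutation d-statistics equal brute-force enumeration", {
  set.seed(41)
  design <- two_group_design(3)
  mat <- matrix(rnorm(30 * 6, 6), 30, 6)
  e <- rpkm_expr(2^mat, samples = design$sample_id)
  de <- sam_de(e, design, c("D", "N"), s0 = 0.1)
  labels <- attr(de, "perm_labels")
  expect_equal(nrow(labels), 20)  # choose(6, 3)
  perm_d <- attr(de, "perm_d")
  oracle <- brute_force_sam_d(log2(2^mat + 1), 3, s0 = 0.1)
  # same multiset of permuted d per feature, exactly
  expect_equal(t(apply(perm_d, 1, sort)), t(apply(oracle, 1, sort)),
               tolerance = 1e-14)
  # observed labeling is included and matches the observed statistic
  expect_equal(perm_d[, 1], de$statistic, tolerance = 1e-14)
})

test_that("with s0 = 0 the d ranking equals the t ranking", {
  set.seed(51)
  design <- two_group_design(4)
  mat <- matrix(rnorm(40 * 8, 6), 40, 8)
  e <- rpkm_expr(2^mat, samples = design$sample_id)
  de <- sam_de(e, design, c("D", "N"), s0 = 0)
  tstat <- apply(log2(2^mat + 1), 1, function(y) {
    unname(t.test(y[1:4], y[5:8], var.equal = TRUE)$statistic)
  })
  expect_equal(order(de$statistic), order(tstat))
  expect_equal(de$statistic, tstat, tolerance = 1e-12)
})

test_that("SAM results are invariant to sample order within groups", {
  set.seed(61)
  design <- two_group_design(3)
  mat <- matrix(rnorm(50 * 6, 6), 50, 6)
  e1 <- rpkm_expr(2^mat, samples = design$sample_id)
  e2 <- e1[, c("feature_id", "D_3", "D_1", "D_2", "N_2", "N_3", "N_1")]
  e2 <- diaretseq:::set_expr_scale(e2, "rpkm")
  de1 <- sam_de(e1, design, c("D", "N"))
  de2 <- sam_de(e2, design, c("D", "N"))
  expect_equal(de1$q_value, de2$q_value, tolerance = 1e-12)
  expect_equal(de1$statistic, de2$statistic, tolerance = 1e-12)
})

test_that("SAM FDR estimate is non-increasing as Delta grows", {
  set.seed(71)
  design <- two_group_design(3)
  mat <- matrix(rnorm(300 * 6, 6), 300, 6)
  mat[1:30, 1:3] <- mat[1:30, 1:3] + 2
  e <- rpkm_expr(2^mat, samples = design$sample_id)
  de <- sam_de(e, design, c("D", "N"))
  dt <- attr(de, "delta_table")
  expect_true(all(diff(dt$fdr) <= 1e-12))
  expect_true(all(dt$fdr >= 0 & dt$fdr <= 1))
})

test_that("a null SAM run tracks the expected quantiles (slope about 1)", {
  set.seed(81)
  design <- two_group_design(3)
  mat <- matrix(rnorm(1000 * 6, 6), 1000, 6)
  e <- rpkm_expr(2^mat, samples = design$sample_id)
  de <- sam_de(e, design, c("D", "N"))
  perm_d <- attr(de, "perm_d")
  expected <- rowMeans(apply(perm_d, 2, sort))
  slope <- unname(coef(lm(sort(de$statistic) ~ expected))[2])
  expect_lt(abs(slope - 1), 0.1)
})

test_that("requesting more permutations than exist falls back to exhaustive", {
  set.seed(91)
  expect_message(labels <- permutation_labels(6, 3, n_perm = 50),
                 "exhaustive")
  expect_equal(nrow(labels), 20)
  sub <- permutation_labels(8, 4, n_perm = 10, seed = 3)
  expect_equal(nrow(sub), 10)
  expect_equal(nrow(unique(as.data.frame(sub))), 10)
  expect_error(permutation_labels(8, 4, n_perm = 10), "seed")
})

test_that("pass flags are a pure function of stored fields", {
  set.seed(101)
  design <- two_group_design(3)
  mat <- matrix(rnorm(200 * 6, 6), 200, 6)
  mat[1:20, 1:3] <- mat[1:20, 1:3] + 2.5
  e <- rpkm_expr(2^mat, samples = design$sample_id)
  for (de in list(sam_de(e, design, c("D", "N")),
                  anova_de(e, design, c("D", "N")))) {
    expect_identical(unname(recompute_passes(de)), unname(de$passes))
  }
})

test_that("top-n overlap handles identical, disjoint, and reranked lists", {
  set.seed(111)
  a <- tibble::tibble(feature_id = paste0("f", 1:50),
                      signed_log2 = rnorm(50), statistic = rnorm(50))
  ov <- top_n_overlap(a, a, n = 20)
  expect_equal(ov$shared, 20)
  expect_equal(ov$only_a, 0)
  b <- dplyr::mutate(a, feature_id = paste0("g", 1:50))
  ov2 <- top_n_overlap(a, b, n = 20)
  expect_equal(ov2$shared, 0)
  expect_equal(ov2$only_a, 20)
  # determinism across reruns
  ov3 <- top_n_overlap(a, b, n = 20)
  expect_identical(ov2$shared_ids, ov3$shared_ids)
  # tidy/glance shape
  expect_equal(sum(tidy(ov)$n_features), 20)
  expect_equal(glance(ov2)$shared, 0)
})
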