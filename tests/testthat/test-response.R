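test_that("the classifier reproduces the published worked examples", {
  # strong disease induction reversed by both drugs -> positive
  expect_equal(classify_response(log2(19.8), log2(3.6)), "positive")
  expect_equal(classify_response(log2(19.8), log2(2.4)), "positive")
  # disease-unchanged transcript strongly altered by therapy -> side effect
  expect_equal(classify_response(-log2(1.2), -log2(2.2)), "side_effect")
  # disease-altered transcript pushed further from normal -> negative
  expect_equal(classify_response(-log2(1.5), -log2(2.4)), "negative")
  # identity case
  expect_equal(classify_response(0, 0), "unaffected")
  # exactly at the diabetic level -> unresponsive (margin 0)
  expect_equal(classify_response(1, 1), "unresponsive")
})

test_that("classification is exhaustive, exclusive, and sign-symmetric", {
  grid <- tidyr::expand_grid(
    d = c(-3, -1, -log2(1.5), -0.3, 0, 0.3, log2(1.5), 1, 3),
    t = c(-3, -1, -log2(1.5), -0.3, 0, 0.3, log2(1.5), 1, 3))
  cats <- classify_response(grid$d, grid$t)
  expect_true(all(cats %in% response_categories()))
  expect_equal(classify_response(-grid$d, -grid$t), cats)
  # scale consistency: a larger margin only moves calls into 'unresponsive'
  cats_m <- classify_response(grid$d, grid$t, margin = 0.4)
  moved <- cats != cats_m
  expect_true(all(cats_m[moved] == "unresponsive"))
})

test_that("all crystallin transcripts classify positive for both drugs", {
  tab <- read_fold_table(fold_table_fixtures()[["crystallins"]])
  expect_equal(nrow(tab), 13)
  calls <- classify_response_table(tab, tau = 1.5)
  expect_equal(nrow(calls), 26)
  expect_true(all(calls$category == "positive"))
})

test_that("an all-unity fold table classifies as unaffected", {
  tab <- tibble::tibble(feature_id = paste0("f", 1:5),
                        d_log2 = 0, t1_log2 = 0, t2_log2 = 0)
  calls <- classify_response_table(tab)
  expect_true(all(calls$category == "unaffected"))
})

test_that("every bundled fold table parses and classifies cleanly", {
  fixtures <- fold_table_fixtures()
  expect_setequal(names(fixtures),
                  c("crystallins", "wnt_signaling", "microvasculature",
                    "inflammatory", "apoptosis", "neuronal", "photoreceptor",
                    "glucuronosyltransferase"))
  for (f in fixtures) {
    tab <- read_fold_table(f)
    expect_true(all(tab$d_ratio >= 1))
    expect_true(all(abs(tab$d_log2) == log2(tab$d_ratio)))
    calls <- classify_response_table(tab)
    expect_equal(nrow(calls), 2 * nrow(tab))
    expect_true(all(calls$category %in% response_categories()))
  }
  # spot-check directional transcription against the printed values
  photo <- read_fold_table(fixtures[["photoreceptor"]])
  pde6h <- photo[photo$feature_id == "Pde6h", ]
  expect_equal(pde6h$d_ratio, 1.2)
  expect_equal(pde6h$d_direction, "down")
  expect_equal(pde6h$t2_ratio, 2.2)
  ugt <- read_fold_table(fixtures[["glucuronosyltransferase"]])
  expect_equal(nrow(ugt), 8)
})

test_that("directional fold notation round-trips", {
  x <- c("19.8", "1.5 (down)", "1", "2.4 (down)")
  p <- parse_directional_fold(x)
  expect_equal(p$ratio, c(19.8, 1.5, 1, 2.4))
  expect_equal(p$signed_log2[2], -log2(1.5))
  expect_equal(format_directional_fold(p$signed_log2),
               c("19.8", "1.5 (down)", "1", "2.4 (down)"))
  expect_error(parse_directional_fold("0.5"), ">= 1")
  expect_error(parse_directional_fold("abc"), "unparseable")
})

test_that("splice-event response sets partition the union of passing events", {
  mk <- function(ids, pass) tibble::tibble(event_id = ids, passes = pass)
  d <- mk(c("e1", "e2", "e3", "e4"), c(TRUE, TRUE, TRUE, TRUE))
  t1 <- mk(c("e2", "e3", "e5", "e7"), c(TRUE, TRUE, TRUE, TRUE))
  t2 <- mk(c("e3", "e4", "e6", "e7"), c(TRUE, TRUE, TRUE, TRUE))
  sets <- splice_response_sets(d, t1, t2)
  m <- sets$membership
  cat_of <- function(id) m$category[m$event_id == id]
  expect_equal(cat_of("e1"), "responsive_to_T1_and_T2")
  expect_equal(cat_of("e2"), "responsive_to_T2")
  expect_equal(cat_of("e3"), "unresponsive_to_T1_and_T2")
  expect_equal(cat_of("e4"), "responsive_to_T1")
  expect_equal(cat_of("e5"), "exacerbated_by_T1")
  expect_equal(cat_of("e6"), "exacerbated_by_T2")
  expect_equal(cat_of("e7"), "exacerbated_by_T1_and_T2")
  # partition: each event in exactly one category; sizes sum to the union
  expect_false(any(is.na(m$category)))
  expect_equal(sum(sets$category_counts$n_events), 7)
  expect_equal(sum(sets$region_counts$n_events), 7)
})
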