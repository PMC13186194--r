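# Correlation screening of gene-set collections.

make_screen_fixture <- function(seed = 1) {
  tc <- generate_timecourse(n_cells = 300, n_genes = 400, seed = seed)
  m <- normalize_matrix(tc$matrix, "cpm_log1p")
  st <- em_scores(m, tc$e_set, tc$m_set, method = "nnpca", K_m = 1, seed = seed)
  coll <- generate_screen_collection(tc$truth, n_sets = 12, seed = seed)
  list(tc = tc, m = m, emt = st$M1, coll = coll)
}

test_that("pearson_cor matches hand-computed values and rejects degenerate input", {
  x <- c(1, 2, 3)
  expect_equal(pearson_cor(x, 2 * x + 1), 1)
  expect_equal(pearson_cor(x, -x), -1)
  expect_equal(pearson_cor(x, c(1, 3, 2)), 0.5)
  expect_error(pearson_cor(x, c(2, 2, 2)), "constant")
  expect_error(pearson_cor(1:2, 1:2), "at least 3")
})

test_that("planted hits top the rankings and every set gets a status", {
  fx <- make_screen_fixture(seed = 3)
  res <- screen_collection(fx$m, fx$emt, fx$coll$collection, fx$tc$m_set,
                           seed = 3)
  expect_equal(nrow(res$records), length(fx$coll$collection))
  expect_true(all(res$records$status %in%
                    c("scored", "filtered_overlap", "skipped_min_genes")))
  expect_equal(res$top_positive$set[1], "PLANTED_POS_1")
  expect_equal(res$top_negative$set[1], "PLANTED_NEG_1")
  # scored records carry r in [-1, 1]; others carry none
  scored <- res$records$status == "scored"
  expect_true(all(abs(res$records$r[scored]) <= 1))
  expect_true(all(is.na(res$records$r[!scored])))
  # top lists are disjoint and correctly sorted
  expect_length(intersect(res$top_positive$set, res$top_negative$set), 0)
  expect_true(all(diff(res$top_positive$r) <= 0))
  expect_true(all(diff(res$top_negative$r) >= 0))
})

test_that("sets overlapping the reference beyond the threshold are filtered", {
  fx <- make_screen_fixture(seed = 2)
  # decoy: 50% reference M genes -> overlap 0.5 > 0.3 default
  decoy <- gene_set("DECOY", c(fx$tc$m_set$genes[1:20],
                               fx$tc$truth$background_genes[1:20]))
  coll <- gene_set_collection(c(fx$coll$collection$sets, list(decoy)))
  res <- screen_collection(fx$m, fx$emt, coll, fx$tc$m_set, seed = 2)
  rec <- res$records[res$records$set == "DECOY", ]
  expect_equal(rec$status, "filtered_overlap")
  expect_equal(rec$overlap, 0.5)
  expect_false("DECOY" %in% c(res$top_positive$set, res$top_negative$set))
  # raising the threshold admits it
  res2 <- screen_collection(fx$m, fx$emt, coll, fx$tc$m_set,
                            overlap_threshold = 0.6, seed = 2)
  expect_equal(res2$records$status[res2$records$set == "DECOY"], "scored")
})

test_that("top_n = 0 still yields the full record table", {
  fx <- make_screen_fixture(seed = 1)
  res <- screen_collection(fx$m, fx$emt, fx$coll$collection, fx$tc$m_set,
                           top_n = 0, seed = 1)
  expect_equal(nrow(res$top_positive), 0)
  expect_equal(nrow(res$top_negative), 0)
  expect_equal(nrow(res$records), length(fx$coll$collection))
})

test_that("negating the EMT score negates r and swaps the top lists", {
  fx <- make_screen_fixture(seed = 5)
  res <- screen_collection(fx$m, fx$emt, fx$coll$collection, fx$tc$m_set,
                           seed = 5)
  flipped <- screen_collection(fx$m, -fx$emt, fx$coll$collection, fx$tc$m_set,
                               seed = 5)
  ord <- match(res$records$set, flipped$records$set)
  expect_equal(flipped$records$r[ord], -res$records$r, tolerance = 1e-12)
  expect_equal(flipped$top_positive$set, res$top_negative$set)
  expect_equal(flipped$top_negative$set, res$top_positive$set)
})

test_that("screening the M set against its own M1 score is self-consistent", {
  fx <- make_screen_fixture(seed = 4)
  coll <- gene_set_collection(list(fx$tc$m_set))
  res <- screen_collection(fx$m, fx$emt, coll, fx$tc$m_set,
                           overlap_threshold = 1.0, seed = 4)
  expect_gte(res$records$r[1], 0.999)
})

test_that("undersized sets are recorded as skipped, never dropped", {
  fx <- make_screen_fixture(seed = 6)
  tiny <- gene_set("TINY", c("NOT_A_GENE_1", "NOT_A_GENE_2"))
  coll <- gene_set_collection(list(tiny, fx$coll$collection$sets[[1]]))
  res <- screen_collection(fx$m, fx$emt, coll, fx$tc$m_set, seed = 6)
  expect_equal(res$records$status[res$records$set == "TINY"],
               "skipped_min_genes")
  expect_equal(nrow(res$records), 2)
})

test_that("screen results export to TSV + JSON", {
  fx <- make_screen_fixture(seed = 7)
  res <- screen_collection(fx$m, fx$emt, fx$coll$collection, fx$tc$m_set,
                           seed = 7)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_screen(res, f)
  back <- data.table::fread(f, data.table = FALSE)
  expect_equal(nrow(back), nrow(res$records))
  js <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(js$params$overlap_threshold, 0.3)
  expect_equal(js$top_positive[[1]]$set, res$top_positive$set[1])
})
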