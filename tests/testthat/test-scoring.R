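# Per-sample scoring backends and the E/M score table.

named_expr <- function(vals, genes = paste0("G", seq_along(vals))) {
  names(vals) <- genes
  vals
}

test_that("ssGSEA equals the brute-force running-sum oracle exactly", {
  withr::with_seed(101, {
    for (i in 1:50) {
      x <- named_expr(round(runif(10, 0, 20), 3))
      in_set <- seq_len(10) %in% sample(10, sample(3:7, 1))
      if (sum(in_set) < 2 || sum(!in_set) < 2) next
      alpha <- sample(c(0, 0.25, 1), 1)
      expect_equal(score_ssgsea(x, in_set, alpha = alpha),
                   unname(oracle_ssgsea(x, in_set, alpha = alpha)),
                   tolerance = 1e-12)
    }
  })
})

test_that("ssGSEA with alpha = 0 matches the hand-computed step functions", {
  # 4 genes ranked d > c > b > a; set = top two expressed (d, c)
  x <- named_expr(c(a = 1, b = 2, c = 3, d = 4), c("a", "b", "c", "d"))
  in_set <- c(FALSE, FALSE, TRUE, TRUE)
  # positions: d(in) c(in) b(out) a(out)
  # P_in  = 1/2, 1, 1, 1 ; P_out = 0, 0, 1/2, 1
  # ES = 1/2 + 1 + 1/2 + 0 = 2
  expect_equal(score_ssgsea(x, in_set, alpha = 0), 2)
  expect_error(score_ssgsea(x, rep(TRUE, 4)), ">= 2 genes")
  # rank invariance: adding a constant leaves the ranking and alpha=0 ES alone
  expect_equal(score_ssgsea(x + 100, in_set, alpha = 0), 2)
})

test_that("AUCell matches the lattice-area oracle and its extremes", {
  # 10 genes, set genes sit at ranks 2 and 4, window k = 5
  x <- named_expr(seq(10, 1))           # G1 highest ... G10 lowest
  in_set <- seq_len(10) %in% c(2, 4)
  got <- score_aucell(x, in_set, top_fraction = 0.5)
  expect_equal(got, oracle_aucell(in_set, k = 5))
  expect_equal(got, 6 / 9)              # cum hits (0,1,1,2,2); perfect 1+2+2+2+2

  # perfect recovery: all set genes at the top of the ranking
  expect_equal(score_aucell(x, seq_len(10) %in% 1:3, top_fraction = 0.5), 1)
  # no set gene inside the window
  expect_equal(score_aucell(x, seq_len(10) %in% 9:10, top_fraction = 0.2), 0)
})

test_that("AUCell agrees with the oracle on random tie-free instances", {
  withr::with_seed(202, {
    for (i in 1:20) {
      x <- named_expr(rnorm(30))
      in_set <- seq_len(30) %in% sample(30, 6)
      k <- 6                             # top_fraction 0.2 of 30
      ord <- order(-x)
      expect_equal(score_aucell(x, in_set, top_fraction = 0.2),
                   oracle_aucell(in_set[ord], k))
    }
  })
})

test_that("SCSE is the percent share of total expression", {
  x <- named_expr(c(5, 5, 0, 0))
  expect_equal(score_scse(x, c(TRUE, TRUE, FALSE, FALSE)), 100)
  expect_equal(score_scse(x, c(FALSE, FALSE, TRUE, TRUE)), 0)
  expect_equal(score_scse(x, c(TRUE, FALSE, FALSE, FALSE)), 50)
  # scale invariance
  expect_equal(score_scse(x * 2, c(TRUE, FALSE, FALSE, FALSE)), 50)
  expect_warning(z <- score_scse(named_expr(c(0, 0)), c(TRUE, FALSE)), "zero total")
  expect_equal(z, 0)
})

test_that("JASMINE variants match their definitions on toy tables", {
  # 2x2 table a=3 expressed-in-set, b=1, c=5, d=5 -> OR = (3/1)/(5/5) = 3
  x <- named_expr(c(rep(1, 3), 0, rep(1, 5), rep(0, 5)))
  in_set <- c(rep(TRUE, 4), rep(FALSE, 10))
  expect_equal(score_jasmine(x, in_set, "odds_ratio"), 3)

  # set genes top-ranked among expressed genes maximizes mean rank
  x2 <- named_expr(c(10, 9, 5, 4, 3, 0))
  top_set <- c(TRUE, TRUE, rep(FALSE, 4))
  bottom_set <- c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE)
  expect_gt(score_jasmine(x2, top_set, "mean_rank"),
            score_jasmine(x2, bottom_set, "mean_rank"))
  # all set genes unexpressed contributes 0
  expect_equal(score_jasmine(x2, c(rep(FALSE, 5), TRUE), "mean_rank"), 0)
})

test_that("score_set yields documented shapes for every backend", {
  m <- random_count_matrix(n_genes = 30, n_samples = 12, seed = 3)
  nm <- normalize_matrix(m, "cpm_log1p")
  s <- gene_set("MYSET", paste0("G", 1:8))

  st <- score_set(nm, s, method = "nnpca", K = 2)
  expect_equal(names(st), c("sample_id", "MYSET_PC1", "MYSET_PC2"))
  expect_equal(nrow(st), 12)
  expect_length(attr(st, "meta")$varexp, 2)
  expect_s3_class(attr(st, "model"), "nnpca_model")

  for (meth in c("ssgsea", "aucell", "scse", "jasmine")) {
    sti <- score_set(nm, s, method = meth)
    expect_equal(names(sti), c("sample_id", paste0("MYSET_", meth)))
    expect_equal(sti$sample_id, nm$sample_ids)
  }
  expect_error(score_set(m, s, method = "nnpca"), "normalized")
  expect_error(score_set(m, s, method = "scse"), "normalized")
})

test_that("all backends are invariant to gene-row permutation", {
  m <- random_count_matrix(n_genes = 40, n_samples = 10, seed = 8)
  nm <- normalize_matrix(m, "cpm_log1p")
  s <- gene_set("SETP", paste0("G", c(2, 5, 9, 12, 20, 33)))
  perm <- withr::with_seed(4, sample(40))
  permuted <- expression_matrix(nm$values[perm, ], gene_ids = nm$gene_ids[perm],
                                sample_ids = nm$sample_ids, norm_tag = "lognorm")
  for (meth in c("nnpca", "ssgsea", "aucell", "scse", "jasmine")) {
    a <- score_set(nm, s, method = meth, seed = 2)
    b <- score_set(permuted, s, method = meth, seed = 2)
    # rank/sum backends are exactly invariant; the iterative nnPCA solve is
    # invariant up to its convergence tolerance (1e-8 on the loading)
    tol <- if (meth == "nnpca") 1e-6 else 1e-12
    expect_equal(a[[2]], b[[2]], tolerance = tol, label = meth)
  }
})

test_that("score tables are deterministic under a fixed seed", {
  m <- normalize_matrix(random_count_matrix(25, 10, seed = 5), "cpm_log1p")
  s <- gene_set("S", paste0("G", 1:10))
  for (meth in c("nnpca", "aucell")) {
    a <- score_set(m, s, method = meth, seed = 9)
    b <- score_set(m, s, method = meth, seed = 9)
    expect_identical(as.data.frame(a), as.data.frame(b))
  }
})

test_that("em_scores assembles E and ranked M columns per backend", {
  dv <- generate_divergent_programs(n_samples = 60, n_genes = 200, seed = 2)
  nm <- normalize_matrix(dv$matrix, "cpm_log1p")

  st <- em_scores(nm, dv$e_set, dv$m_set, method = "nnpca", K_m = 2, seed = 1)
  expect_equal(names(st), c("sample_id", "E", "M1", "M2"))
  ve <- attr(st, "meta")$varexp_m
  expect_true(all(diff(ve) <= 0))

  st2 <- em_scores(nm, dv$e_set, dv$m_set, method = "scse")
  expect_equal(names(st2), c("sample_id", "E", "M"))

  # scoring the same set as E and M makes E coincide with M1
  st3 <- em_scores(nm, dv$m_set, dv$m_set, method = "nnpca", K_m = 1, seed = 1)
  expect_equal(st3$E, st3$M1)
})

test_that("score tables round-trip to TSV with a JSON metadata sidecar", {
  m <- normalize_matrix(random_count_matrix(20, 6, seed = 6), "cpm_log1p")
  st <- score_set(m, gene_set("S", paste0("G", 1:6)), method = "scse")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_scores(st, f)
  back <- data.table::fread(f, data.table = FALSE)
  expect_equal(back[[2]], st[[2]], tolerance = 1e-12)
  meta <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(meta$method, "scse")
})
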