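# Shared fixture builders; everything is generated in code under fixed
# seeds so the suite carries no data files.

# Random gene-set collection for round-trip properties.
random_collection <- function(n_sets = 3, seed = 1) {
  withr::with_seed(seed, {
    sets <- lapply(seq_len(n_sets), function(i) {
      k <- sample(3:12, 1)
      gene_set(sprintf("SET_%02d", i),
               paste0("G", sample(1000, k)),
               description = sample(c("", "some description", "x y z"), 1))
    })
    gene_set_collection(sets, source_tag = "random")
  })
}

# Small random count matrix as an expression_matrix.
random_count_matrix <- function(n_genes = 8, n_samples = 5, seed = 1) {
  withr::with_seed(seed, {
    vals <- matrix(rpois(n_genes * n_samples, 20), n_genes, n_samples)
    expression_matrix(vals,
                      gene_ids = paste0("G", seq_len(n_genes)),
                      sample_ids = paste0("S", seq_len(n_samples)),
                      norm_tag = "raw")
  })
}

# Independent brute-force ssGSEA oracle: walks every rank position and
# accumulates the two ECDFs step by step. Shares nothing with the
# implementation beyond the tie rule (ties broken by gene name).
oracle_ssgsea <- function(x, in_set, alpha) {
  ord <- order(-x, names(x))
  xs <- x[ord]; ins <- in_set[ord]
  N <- length(x); m <- sum(ins)
  denom_in <- sum(abs(xs[ins])^alpha)
  es <- 0
  p_in <- 0; p_out <- 0
  for (i in seq_len(N)) {
    if (ins[i]) p_in <- p_in + abs(xs[i])^alpha / denom_in
    else p_out <- p_out + 1 / (N - m)
    es <- es + (p_in - p_out)
  }
  es
}

# Independent AUCell oracle: counts the lattice area cell by cell given an
# explicit ranking of the genes.
oracle_aucell <- function(ranking_in_set, k) {
  m <- min(k, sum(ranking_in_set))
  if (m == 0) return(0)
  area <- 0
  for (i in seq_len(k)) area <- area + sum(ranking_in_set[seq_len(i)])
  max_area <- 0
  for (i in seq_len(k)) max_area <- max_area + min(i, m)
  area / max_area
}

# Random nonnegative-direction search oracle for nnPCA: best Var(Xw) over
# n_dirs random nonnegative unit vectors plus the coordinate axes.
oracle_nnpca_var <- function(X, n_dirs = 1e5, seed = 1) {
  p <- ncol(X); n <- nrow(X)
  C <- crossprod(X) / (n - 1)
  W <- withr::with_seed(seed, matrix(abs(rnorm(p * n_dirs)), p, n_dirs))
  W <- cbind(W, diag(p))
  W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  max(colSums(W * (C %*% W)))
}
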