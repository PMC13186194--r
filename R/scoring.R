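# Per-sample gene-set scoring.
#
# Five backends: nnpca (the default; yields multiple ranked axes per set),
# plus the single-axis per-sample scorers ssgsea (weighted running sum),
# aucell (recovery-curve AUC), scse (normalized expression sum) and jasmine
# (rank of expressed set genes, optionally blended with an enrichment odds
# ratio). All backends are invariant to the order genes appear in the
# matrix.

#' ssGSEA enrichment score for one sample
#'
#' Genes are ranked by expression, descending (ties broken by gene name so
#' the statistic is deterministic). The score is the sum over all rank
#' positions of the difference between the weighted in-set ECDF (weights
#' `|x|^alpha`) and the unweighted out-of-set ECDF.
#'
#' @param x Named numeric vector: one sample's expression over all genes.
#' @param in_set Logical vector aligned to `x`: membership in the scored set.
#'   At least 2 genes in and 2 out of the set.
#' @param alpha Rank weight exponent (0 = unweighted steps).
#' @return Raw enrichment score (unbounded; cohort-wide rescaling is an
#'   explicit option of [score_set()]).
#' @export
score_ssgsea <- function(x, in_set, alpha = 0.25) {
  .check_sample_vec(x, in_set)
  assert_scalar_number(alpha, "alpha", lower = 0)
  m <- sum(in_set)
  n_out <- sum(!in_set)
  if (m < 2L || n_out < 2L) {
    stop("ssGSEA needs >= 2 genes inside and outside the set", call. = FALSE)
  }
  ord <- order(-x, names(x))
  ins <- in_set[ord]
  w <- abs(x[ord])^alpha * ins
  wsum <- sum(w)
  p_in <- if (wsum > 0) cumsum(w) / wsum else cumsum(ins) / m
  p_out <- cumsum(!ins) / n_out
  sum(p_in - p_out)
}

#' AUCell recovery-curve score for one sample
#'
#' Genes are ranked by expression, descending, with ties broken by a seeded
#' random permutation (recorded by the caller). The recovery curve counts
#' set genes among the top `k = ceiling(top_fraction * N)` ranks; the score
#' is the area under that curve normalized by the perfect-recovery area, so
#' it lies in `[0, 1]`.
#'
#' @param x Named numeric expression vector for one sample.
#' @param in_set Logical membership vector aligned to `x`.
#' @param top_fraction Fraction of the ranking that counts (default 0.05).
#' @param seed Seed for the tie-breaking permutation.
#' @return AUC in `[0, 1]`.
#' @export
score_aucell <- function(x, in_set, top_fraction = 0.05, seed = 1L) {
  .check_sample_vec(x, in_set)
  assert_scalar_number(top_fraction, "top_fraction", lower = 1e-12, upper = 1)
  N <- length(x)
  k <- ceiling(top_fraction * N)
  if (k < 1L) stop("top window is empty", call. = FALSE)
  # tie-break keyed on gene identity (a seeded permutation of the sorted
  # gene names), so scores do not depend on matrix row order
  tie_perm <- with_seed(seed, sample.int(N))
  tie_val <- tie_perm[match(names(x), sort(names(x)))]
  ord <- order(-x, tie_val)
  m <- min(k, sum(in_set))
  if (m == 0L) return(0)
  hits <- cumsum(in_set[ord][seq_len(k)])
  max_area <- sum(pmin(seq_len(k), m))
  sum(hits) / max_area
}

#' SCSE normalized-sum score for one sample
#'
#' One hundred times the set's share of the sample's total expression. A
#' zero-total sample scores 0 with a warning. Invariant to rescaling the
#' whole sample.
#'
#' @inheritParams score_ssgsea
#' @return Score in `[0, 100]` for nonnegative expression.
#' @export
score_scse <- function(x, in_set) {
  .check_sample_vec(x, in_set)
  tot <- sum(x)
  if (tot == 0) {
    warning("sample with zero total expression scored 0", call. = FALSE)
    return(0)
  }
  100 * sum(x[in_set]) / tot
}

#' JASMINE rank-based score for one sample (raw, unscaled)
#'
#' `mean_rank`: among genes expressed in the sample (`x > 0`), the mean
#' ascending rank of the expressed set genes divided by the number of
#' expressed genes; 0 when no set gene is expressed. `odds_ratio`: the
#' enrichment odds ratio of expressed vs unexpressed, set vs non-set genes,
#' with a Haldane 0.5 correction when any cell of the 2x2 table is zero.
#' [score_set()] min-max scales either variant across samples to form the
#' final column and averages the two scaled variants for
#' `variant = "combined"`.
#'
#' @inheritParams score_ssgsea
#' @param variant `"mean_rank"` or `"odds_ratio"`.
#' @return Raw per-sample value.
#' @export
score_jasmine <- function(x, in_set, variant = c("mean_rank", "odds_ratio")) {
  .check_sample_vec(x, in_set)
  variant <- match.arg(variant)
  expressed <- x > 0
  if (variant == "mean_rank") {
    n_expr <- sum(expressed)
    set_expr <- expressed & in_set
    if (n_expr == 0L || !any(set_expr)) return(0)
    r <- rank(x[expressed])
    mean(r[in_set[expressed]]) / n_expr
  } else {
    a <- sum(in_set & expressed)
    b <- sum(in_set & !expressed)
    cc <- sum(!in_set & expressed)
    d <- sum(!in_set & !expressed)
    if (min(a, b, cc, d) == 0L) {
      a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
    }
    (a / b) / (cc / d)
  }
}

.check_sample_vec <- function(x, in_set) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x)) {
    stop("`x` must be a numeric vector without NA", call. = FALSE)
  }
  if (!is.logical(in_set) || length(in_set) != length(x)) {
    stop("`in_set` must be a logical vector aligned to `x`", call. = FALSE)
  }
  if (is.null(names(x))) stop("`x` must be named by gene", call. = FALSE)
  invisible(TRUE)
}

.minmax <- function(v) {
  rng <- range(v)
  if (diff(rng) == 0) return(rep(0, length(v)))
  (v - rng[1]) / diff(rng)
}

#' Score one gene set across all samples
#'
#' Dispatches over the five backends. The nnPCA backend subsets the matrix
#' to the set, centers each gene, and fits `K` nonnegative axes, yielding
#' `K` columns named `<set>_PC1 ...` ordered by variance explained, with the
#' fitted model attached. The per-sample backends rank or sum each sample's
#' full expression vector and yield one column `<set>_<method>`.
#'
#' nnPCA and SCSE expect normalized (not raw-count) input; run
#' [normalize_matrix()] first. Rank-based backends accept either.
#'
#' @param m An `expression_matrix`.
#' @param s A `gene_set`.
#' @param method One of `"nnpca"`, `"ssgsea"`, `"aucell"`, `"scse"`,
#'   `"jasmine"`.
#' @param K Number of nnPCA axes (nnpca only).
#' @param alpha ssGSEA weight exponent.
#' @param top_fraction AUCell top-rank window.
#' @param jasmine_variant `"mean_rank"`, `"odds_ratio"` or `"combined"`
#'   (mean of the two min-max-scaled variants).
#' @param rescale If `TRUE`, min-max rescale the ssGSEA column across the
#'   dataset (makes scores dataset-dependent; off by default). JASMINE
#'   columns are always min-max scaled, following the published statistic.
#' @param min_genes Minimum matched set genes.
#' @param seed Seed controlling tie-breaking and nnPCA restarts.
#' @param restarts Extra random nnPCA restarts per axis.
#' @return A `score_table` data.frame (`sample_id` plus score columns) with
#'   attributes `meta` (backend, parameters, seed, varexp) and, for nnpca,
#'   `model` (the `nnpca_model`).
#' @export
score_set <- function(m, s,
                      method = c("nnpca", "ssgsea", "aucell", "scse", "jasmine"),
                      K = 1L, alpha = 0.25, top_fraction = 0.05,
                      jasmine_variant = c("mean_rank", "odds_ratio", "combined"),
                      rescale = FALSE, min_genes = 5L, seed = 1L,
                      restarts = 0L) {
  stopifnot(inherits(m, "expression_matrix"), inherits(s, "gene_set"))
  method <- match.arg(method)
  jasmine_variant <- match.arg(jasmine_variant)
  if (method %in% c("nnpca", "scse") && m$norm_tag == "raw") {
    stop("method '", method, "' expects normalized expression; run normalize_matrix() first",
         call. = FALSE)
  }
  sub <- subset_to_set(m, s, min_genes = min_genes)

  model <- NULL
  if (method == "nnpca") {
    X <- .centered_samples_by_genes(sub$matrix)
    model <- fit_nnpca(X, K = K, seed = seed, restarts = restarts)
    cols <- as.data.frame(model$scores)
    names(cols) <- paste0(s$name, "_PC", seq_len(K))
  } else {
    in_set <- toupper(m$gene_ids) %in% s$genes
    vals <- m$values
    per_sample <- function(fun) {
      vapply(seq_len(ncol(vals)), function(j) {
        x <- vals[, j]
        names(x) <- m$gene_ids
        fun(x)
      }, numeric(1))
    }
    col <- switch(method,
      ssgsea = {
        v <- per_sample(function(x) score_ssgsea(x, in_set, alpha = alpha))
        if (rescale) .minmax(v) else v
      },
      aucell = per_sample(function(x) score_aucell(x, in_set,
                                                   top_fraction = top_fraction,
                                                   seed = seed)),
      scse = per_sample(function(x) score_scse(x, in_set)),
      jasmine = {
        if (jasmine_variant == "combined") {
          mr <- .minmax(per_sample(function(x) score_jasmine(x, in_set, "mean_rank")))
          orr <- .minmax(per_sample(function(x) score_jasmine(x, in_set, "odds_ratio")))
          (mr + orr) / 2
        } else {
          .minmax(per_sample(function(x) score_jasmine(x, in_set, jasmine_variant)))
        }
      })
    cols <- stats::setNames(data.frame(col), paste0(s$name, "_", method))
  }

  st <- data.frame(sample_id = m$sample_ids, cols, row.names = NULL,
                   check.names = FALSE, stringsAsFactors = FALSE)
  class(st) <- c("score_table", "data.frame")
  attr(st, "meta") <- list(method = method, set = s$name, seed = seed,
                           params = list(K = K, alpha = alpha,
                                         top_fraction = top_fraction,
                                         jasmine_variant = jasmine_variant,
                                         min_genes = min_genes,
                                         rescale = rescale),
                           varexp = if (!is.null(model)) model$varexp else NULL,
                           match_report = sub$report)
  if (!is.null(model)) attr(st, "model") <- model
  st
}

#' Epithelial and mesenchymal scores per sample
#'
#' Fits the E set and the M set separately (the two axes are independent
#' summaries, not a forced trade-off). With the nnPCA backend the E column
#' is the leading axis of the E set and M1..MK are the leading `K_m` axes of
#' the M set, ordered by variance explained; other backends yield single
#' `E` and `M` columns.
#'
#' @param m An `expression_matrix` (normalized for nnpca/scse).
#' @param e_set,m_set `gene_set` objects.
#' @param method Scoring backend, as in [score_set()].
#' @param K_m Number of mesenchymal axes (nnpca only; default 2 exposes
#'   divergent M programs as M1 vs M2).
#' @param seed Seed passed to the backend.
#' @param ... Further backend parameters passed to [score_set()].
#' @return A `score_table` with columns `sample_id`, `E`, and `M1..MK` (or
#'   `M`), with attribute `models` holding the per-set `nnpca_model`s when
#'   applicable.
#' @export
em_scores <- function(m, e_set, m_set, method = "nnpca", K_m = 2L,
                      seed = 1L, ...) {
  e_tab <- score_set(m, e_set, method = method, K = 1L, seed = seed, ...)
  k_m <- if (method == "nnpca") as.integer(K_m) else 1L
  m_tab <- score_set(m, m_set, method = method, K = k_m, seed = seed, ...)
  out <- data.frame(sample_id = e_tab$sample_id,
                    E = e_tab[[2]], row.names = NULL,
                    stringsAsFactors = FALSE)
  if (method == "nnpca") {
    for (k in seq_len(k_m)) out[[paste0("M", k)]] <- m_tab[[k + 1L]]
  } else {
    out[["M"]] <- m_tab[[2]]
  }
  class(out) <- c("score_table", "data.frame")
  attr(out, "meta") <- list(method = method, seed = seed,
                            e_set = e_set$name, m_set = m_set$name,
                            K_m = k_m,
                            varexp_e = attr(e_tab, "meta")$varexp,
                            varexp_m = attr(m_tab, "meta")$varexp)
  attr(out, "models") <- list(E = attr(e_tab, "model"), M = attr(m_tab, "model"))
  out
}

#' Write a score table with a metadata sidecar
#'
#' The table goes to `path` as TSV; backend name, parameters, seed and
#' variance-explained fractions go to `<path>.json`.
#'
#' @param st A `score_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(st, path) {
  stopifnot(inherits(st, "score_table"))
  data.table::fwrite(as.data.frame(st), path, sep = "\t")
  meta <- attr(st, "meta")
  if (!is.null(meta)) {
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  }
  invisible(path)
}
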