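# Screening gene-set collections for EMT-correlated processes.
#
# Every set in a collection is scored (nnPCA PC1 by default — nonnegative
# loadings mean the score direction is "coordinated upregulation of the
# set", so the sign of the correlation is interpretable), then ranked by
# Pearson correlation with the EMT score (M1 by default). Sets sharing too
# many genes with the reference EMT set are filtered out first: their
# correlation is guaranteed by construction, not biology.

#' Pearson correlation with domain checks
#'
#' Standard product-moment correlation; errors on inputs for which it is
#' undefined (fewer than 3 points or a constant vector), which screening
#' turns into a skipped record rather than a crash.
#'
#' @param x,y Equal-length numeric vectors, length at least 3, both
#'   non-constant.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_cor <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    stop("`x` and `y` must be numeric vectors of equal length", call. = FALSE)
  }
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("NA values in correlation input", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Screen a gene-set collection against an EMT score
#'
#' For each set: compute its overlap with the reference EMT set (filtered
#' out above `overlap_threshold`); otherwise score the set per sample
#' (nnPCA PC1 or a per-sample backend) and record the Pearson correlation
#' of that score with `emt_scores`. Every input set appears in the record
#' table with a status — `scored`, `filtered_overlap`, or
#' `skipped_min_genes` (which also absorbs degenerate sets that cannot be
#' scored; the `note` column says why). Benjamini-Hochberg q-values are
#' reported for the scored correlations but play no part in the ranking,
#' which is by r alone.
#'
#' @param m An `expression_matrix` (normalized for the nnpca/scse methods).
#' @param emt_scores Numeric EMT score vector aligned to the samples of `m`
#'   (the M1 column of [em_scores()] by default in the pipeline).
#' @param collection A `gene_set_collection` to screen.
#' @param reference The `gene_set` the EMT score was built from (the M set
#'   by default); overlap is measured against it.
#' @param overlap_threshold Maximum allowed overlap fraction (default 0.30).
#' @param method Scoring backend for the screened sets.
#' @param min_genes Minimum matched genes per set.
#' @param top_n Length cap for the top-positive / top-negative lists.
#' @param overlap_denominator Passed to [overlap_fraction()].
#' @param seed Seed passed to the backend.
#' @return An object of class `screen_result`: `records` (one row per
#'   collection set), `top_positive`, `top_negative`, `params`.
#' @export
screen_collection <- function(m, emt_scores, collection, reference,
                              overlap_threshold = 0.30, method = "nnpca",
                              min_genes = 5L, top_n = 10L,
                              overlap_denominator = "candidate",
                              seed = 1L) {
  stopifnot(inherits(m, "expression_matrix"),
            inherits(collection, "gene_set_collection"),
            inherits(reference, "gene_set"))
  if (!is.numeric(emt_scores) || length(emt_scores) != ncol(m$values)) {
    stop("`emt_scores` must be numeric and aligned to the matrix samples",
         call. = FALSE)
  }
  assert_scalar_number(overlap_threshold, "overlap_threshold", lower = 0, upper = 1)
  assert_scalar_number(top_n, "top_n", lower = 0)

  sets <- collection$sets
  nsets <- length(sets)
  records <- data.frame(set = names(sets),
                        size = vapply(sets, function(s) length(s$genes), integer(1)),
                        n_matched = NA_integer_,
                        overlap = NA_real_,
                        r = NA_real_,
                        p = NA_real_,
                        status = NA_character_,
                        note = "",
                        row.names = NULL, stringsAsFactors = FALSE)
  upper_rows <- toupper(m$gene_ids)

  for (i in seq_len(nsets)) {
    s <- sets[[i]]
    records$n_matched[i] <- sum(upper_rows %in% s$genes)
    ov <- overlap_fraction(s, reference, denominator = overlap_denominator)
    records$overlap[i] <- ov
    if (ov > overlap_threshold) {
      records$status[i] <- "filtered_overlap"
      next
    }
    res <- tryCatch({
      # per-set solver warnings (e.g. slow convergence on structureless
      # background sets) would flood a large screen; errors still surface
      # as skipped records
      st <- suppressWarnings(
        score_set(m, s, method = method, K = 1L, min_genes = min_genes,
                  seed = seed))
      sc <- st[[2]]
      r <- pearson_cor(sc, emt_scores)
      pv <- suppressWarnings(stats::cor.test(sc, emt_scores))$p.value
      list(r = r, p = pv)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      records$status[i] <- "skipped_min_genes"
      records$note[i] <- conditionMessage(res)
    } else {
      records$status[i] <- "scored"
      records$r[i] <- res$r
      records$p[i] <- res$p
    }
  }

  scored <- records$status == "scored"
  records$q <- NA_real_
  if (any(scored)) {
    records$q[scored] <- stats::p.adjust(records$p[scored], method = "BH")
  } else {
    warning("no set could be scored; top lists are empty", call. = FALSE)
  }

  pool <- records[scored, , drop = FALSE]
  pool <- pool[order(-pool$r, pool$set), , drop = FALSE]
  top_n <- as.integer(top_n)
  top_positive <- utils::head(pool[pool$r > 0, , drop = FALSE], top_n)
  neg <- pool[pool$r < 0, , drop = FALSE]
  top_negative <- utils::head(neg[order(neg$r, neg$set), , drop = FALSE], top_n)
  rownames(top_positive) <- rownames(top_negative) <- NULL

  structure(list(records = records,
                 top_positive = top_positive,
                 top_negative = top_negative,
                 params = list(overlap_threshold = overlap_threshold,
                               method = method, min_genes = min_genes,
                               top_n = top_n, seed = seed,
                               overlap_denominator = overlap_denominator,
                               reference = reference$name)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %d sets: %s\n", nrow(x$records),
              paste(names(table(x$records$status)),
                    table(x$records$status), sep = "=", collapse = ", ")))
  if (nrow(x$top_positive) > 0) {
    cat("top positive:\n")
    print(utils::head(x$top_positive[, c("set", "r")], 5))
  }
  if (nrow(x$top_negative) > 0) {
    cat("top negative:\n")
    print(utils::head(x$top_negative[, c("set", "r")], 5))
  }
  invisible(x)
}

#' Write a screen result
#'
#' All records go to `path` as TSV; parameters and the top lists go to
#' `<path>.json`.
#'
#' @param x A `screen_result`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_screen <- function(x, path) {
  stopifnot(inherits(x, "screen_result"))
  data.table::fwrite(x$records, path, sep = "\t")
  jsonlite::write_json(list(params = x$params,
                            top_positive = x$top_positive,
                            top_negative = x$top_negative),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
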