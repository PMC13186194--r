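# EMT-state detection in E-M score space.
#
# Samples are clustered with a Gaussian mixture (full covariances — E-M
# clouds are elongated and tilted), the number of components is chosen by
# BIC, and components are labeled Epithelial / Hybrid-i / Mesenchymal by
# their mean mesenchymal-minus-epithelial position computed on z-scored
# columns, which makes "extreme E/M relative to the dataset" operational
# and invariant to affine rescaling of the score axes.

#' Fit a Gaussian-mixture state model in E-M score space
#'
#' For each candidate component count in `k_range`, an EM fit with full
#' per-component covariances is computed (via \pkg{mclust}, whose
#' model-based hierarchical initialization is deterministic); the K with the
#' best BIC wins. Components are then ordered by their mean `M - E` position
#' in z-scored coordinates: the lowest is Epithelial, the highest
#' Mesenchymal, and intermediates are Hybrid-1, Hybrid-2, ... ascending.
#' Hybrids exist only when the selected K is at least 3.
#'
#' @param scores A `score_table` (or data.frame) holding the columns named
#'   by `e_col` and `m_col`; at least 10 samples, and at least `5 * K`
#'   samples for the smallest candidate K.
#' @param k_range Candidate component counts (default `2:6`).
#' @param e_col,m_col Score columns spanning the state space.
#' @param n_init Retained for interface stability; the EM initialization
#'   used here is deterministic, so extra random restarts are not needed.
#' @param seed Seed (recorded; the fit itself is deterministic).
#' @return An object of class `gmm_state_fit`: selected `K`, component
#'   `means`, `covariances`, `weights`, per-sample `responsibilities` and
#'   hard `assignment`, per-sample `state`, per-component `state_label`,
#'   the `bic` table over `k_range`, and `seed`.
#' @export
fit_gmm_states <- function(scores, k_range = 2:6, e_col = "E", m_col = "M1",
                           n_init = 10L, seed = 1L) {
  df <- as.data.frame(scores)
  for (col in c(e_col, m_col)) {
    if (!col %in% names(df)) stop("score column '", col, "' not found", call. = FALSE)
    if (!all(is.finite(df[[col]]))) stop("non-finite values in column '", col, "'",
                                         call. = FALSE)
  }
  n <- nrow(df)
  if (n < 10L) stop("need at least 10 samples to fit states", call. = FALSE)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 1L)) stop("`k_range` must be positive", call. = FALSE)
  k_range <- k_range[n >= 5L * k_range]
  if (length(k_range) == 0L) {
    stop("fewer than 5*K samples for every candidate K", call. = FALSE)
  }
  em <- df[[e_col]]; mm <- df[[m_col]]
  if (stats::sd(em) == 0 || stats::sd(mm) == 0) {
    stop("degenerate (zero-variance) score column", call. = FALSE)
  }
  dat <- cbind(E = em, M = mm)

  # Mclust resolves mclustBIC in the caller's frame; bind it locally so the
  # package can call it without attaching mclust
  mclustBIC <- mclust::mclustBIC
  fits <- with_seed(seed, lapply(k_range, function(k) {
    tryCatch(mclust::Mclust(dat, G = k, modelNames = "VVV", verbose = FALSE),
             error = function(e) NULL)
  }))
  bic <- vapply(fits, function(f) if (is.null(f)) NA_real_ else as.numeric(f$bic),
                numeric(1))
  if (all(is.na(bic))) stop("all mixture fits failed", call. = FALSE)
  # mclust's BIC is 2*loglik - npar*log(n): larger is better
  best <- which.max(bic)
  fit <- fits[[best]]
  K <- k_range[best]

  z_e <- (em - mean(em)) / stats::sd(em)
  z_m <- (mm - mean(mm)) / stats::sd(mm)
  assignment <- fit$classification
  delta <- vapply(seq_len(K), function(k) {
    mean(z_m[assignment == k] - z_e[assignment == k])
  }, numeric(1))
  ord <- order(delta)                       # E end first, M end last
  state_label <- character(K)
  state_label[ord[1]] <- "Epithelial"
  state_label[ord[K]] <- "Mesenchymal"
  if (K > 2L) {
    state_label[ord[2:(K - 1)]] <- paste0("Hybrid-", seq_len(K - 2L))
  }

  means <- t(fit$parameters$mean)           # K x 2
  covs <- fit$parameters$variance$sigma     # 2 x 2 x K
  weights <- fit$parameters$pro
  resp <- fit$z
  colnames(resp) <- state_label

  structure(list(K = K, means = means, covariances = covs, weights = weights,
                 responsibilities = resp, assignment = assignment,
                 state = state_label[assignment],
                 state_label = state_label,
                 bic = data.frame(K = k_range, bic = bic),
                 sample_id = if ("sample_id" %in% names(df)) df$sample_id else
                   as.character(seq_len(n)),
                 e_col = e_col, m_col = m_col, seed = seed),
            class = "gmm_state_fit")
}

#' @export
print.gmm_state_fit <- function(x, ...) {
  cat(sprintf("<gmm_state_fit> K = %d (%s); n = %d\n", x$K,
              paste(.state_order(x$state_label), collapse = " -> "),
              length(x$assignment)))
  print(table(state = x$state))
  invisible(x)
}

# Canonical state ordering: Epithelial, Hybrid-1..., Mesenchymal
.state_order <- function(labels) {
  hybrids <- sort(grep("^Hybrid-", labels, value = TRUE))
  c("Epithelial", hybrids, "Mesenchymal")
}

#' Map user labels onto EMT states
#'
#' Cross-tabulates an annotation column (e.g. time point or cluster) against
#' the fitted EMT states and reports link records (label, state, count,
#' fraction of the label's samples), ready for a Sankey renderer. States are
#' ordered Epithelial, Hybrids, Mesenchymal.
#'
#' @param fit A `gmm_state_fit`.
#' @param ann Data.frame of sample annotations with a `sample_id` column
#'   covering every fitted sample.
#' @param label_column Name of the annotation column to map.
#' @return An object of class `label_state_map` with `contingency` (a
#'   table) and `links` (a data.frame of link records).
#' @export
map_labels <- function(fit, ann, label_column) {
  stopifnot(inherits(fit, "gmm_state_fit"))
  assert_string(label_column, "label_column")
  if (!label_column %in% names(ann)) {
    stop("label column '", label_column, "' not found in annotations", call. = FALSE)
  }
  idx <- match(fit$sample_id, ann$sample_id)
  if (anyNA(idx)) {
    miss <- fit$sample_id[is.na(idx)]
    stop("annotations missing for sample(s): ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  labels <- ann[[label_column]][idx]
  if (anyNA(labels)) {
    stop("missing '", label_column, "' label for sample(s): ",
         paste(utils::head(fit$sample_id[is.na(labels)], 5), collapse = ", "),
         call. = FALSE)
  }
  state <- factor(fit$state, levels = .state_order(fit$state_label))
  contingency <- table(label = labels, state = state)
  links <- as.data.frame(contingency, responseName = "count",
                         stringsAsFactors = FALSE)
  totals <- tapply(links$count, links$label, sum)
  links$fraction_of_label <- links$count / as.numeric(totals[links$label])
  links <- links[links$count > 0, , drop = FALSE]
  links <- links[order(links$label, match(links$state, levels(state))), ,
                 drop = FALSE]
  rownames(links) <- NULL
  structure(list(contingency = contingency, links = links,
                 label_column = label_column),
            class = "label_state_map")
}

#' @export
print.label_state_map <- function(x, ...) {
  cat(sprintf("<label_state_map> %s x EMT state\n", x$label_column))
  print(x$contingency)
  invisible(x)
}

#' Score trend along pseudotime (or any sample ordering)
#'
#' Sorts samples by the ordering, computes a centered rolling-mean curve
#' (window `max(5, ceiling(window_fraction * n))` samples) and the Spearman
#' rank correlation between score and ordering with its large-sample
#' p-value. Spearman is used because pseudotime is ordinal, not metric.
#'
#' @param scores A `score_table` or data.frame.
#' @param ordering Numeric vector aligned to the rows of `scores` (e.g.
#'   pseudotime), or the name of a column of `scores`.
#' @param score_column Name of the score column to trend.
#' @param window_fraction Rolling-window size as a fraction of n.
#' @return A list with `curve` (data.frame: ordering, score, trend),
#'   `rho`, `p_value` and `window`.
#' @export
score_trend <- function(scores, ordering, score_column,
                        window_fraction = 0.05) {
  df <- as.data.frame(scores)
  if (is.character(ordering) && length(ordering) == 1L) {
    if (!ordering %in% names(df)) stop("ordering column '", ordering, "' not found",
                                       call. = FALSE)
    ordering <- df[[ordering]]
  }
  if (!score_column %in% names(df)) {
    stop("score column '", score_column, "' not found", call. = FALSE)
  }
  y <- df[[score_column]]
  if (length(ordering) != length(y) || !all(is.finite(ordering))) {
    stop("`ordering` must be finite and aligned to the score table", call. = FALSE)
  }
  if (length(unique(ordering)) == 1L) {
    stop("constant ordering: no trend is defined", call. = FALSE)
  }
  n <- length(y)
  window <- max(5L, as.integer(ceiling(window_fraction * n)))
  if (n < window) stop("need at least ", window, " samples for the rolling window",
                       call. = FALSE)
  ord <- order(ordering)
  ys <- y[ord]
  xs <- ordering[ord]
  trend <- as.numeric(stats::filter(ys, rep(1 / window, window), sides = 2))
  ct <- suppressWarnings(stats::cor.test(y, ordering, method = "spearman",
                                         exact = FALSE))
  list(curve = data.frame(ordering = xs, score = ys, trend = trend),
       rho = unname(ct$estimate), p_value = ct$p.value, window = window)
}

#' Append state assignments to a score table
#'
#' @param st A `score_table`.
#' @param fit A `gmm_state_fit` fitted on the same samples.
#' @return The table with a `state` column added.
#' @export
add_states <- function(st, fit) {
  stopifnot(inherits(fit, "gmm_state_fit"))
  df <- as.data.frame(st)
  if (nrow(df) != length(fit$state)) {
    stop("score table and fit cover different sample counts", call. = FALSE)
  }
  df$state <- fit$state
  class(df) <- c("score_table", "data.frame")
  attr(df, "meta") <- attr(st, "meta")
  df
}
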