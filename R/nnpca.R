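# Nonnegative PCA by projected power iteration with data deflation.
#
# Each axis maximizes Var(X w) subject to w >= 0 entrywise and ||w|| = 1.
# Because loadings are nonnegative, an axis reads as "coordinated
# upregulation" of its genes — there is no sign ambiguity to resolve, which
# is what makes multiple mesenchymal programs (M1, M2, ...) interpretable.
# After each axis the data matrix is deflated (X <- X - t w'), so successive
# axes capture residual variance and variance-explained fractions are
# non-increasing.

#' Project a vector onto the nonnegative unit sphere
#'
#' Clips negative entries to zero and renormalizes. When no entry is
#' positive, falls back to the indicator of the largest entry (lowest index
#' on ties) so the result is always a valid nonnegative unit vector.
#'
#' @param v Non-empty numeric vector.
#' @return Unit-norm vector with nonnegative entries, same length as `v`.
#' @examples
#' project_nonneg_unit(c(3, 4, 0))   # (0.6, 0.8, 0)
#' project_nonneg_unit(c(-1, -2))    # (1, 0)
#' @export
project_nonneg_unit <- function(v) {
  if (!is.numeric(v) || length(v) == 0L || anyNA(v)) {
    stop("`v` must be a non-empty numeric vector without NA", call. = FALSE)
  }
  w <- pmax(v, 0)
  nrm <- sqrt(sum(w^2))
  if (nrm > 0) return(w / nrm)
  out <- numeric(length(v))
  out[which.max(v)] <- 1
  out
}

# One projected power iteration solve for the leading nonnegative axis of
# the (already deflated) matrix X (samples x genes). C = crossprod(X) is
# passed in to avoid recomputation across restarts.
.nnpca_power <- function(C, w0, tol, max_iter) {
  w <- w0
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    w_new <- project_nonneg_unit(as.numeric(C %*% w))
    if (sqrt(sum((w_new - w)^2)) < tol) {
      w <- w_new
      converged <- TRUE
      break
    }
    w <- w_new
  }
  list(w = w, n_iter = iter, converged = converged)
}

# Deterministic start portfolio for one deflation stage. The main start is
# the classical leading right-singular vector of the residual, sign chosen
# so the half with larger absolute mass is positive, then projected to the
# feasible set. Because the projected objective is non-convex, the
# complementary sign and the coordinate axes of the highest-variance genes
# are included as cheap extra starts; the best objective wins.
.nnpca_starts <- function(X, max_axes = 50L) {
  sv <- svd(X, nu = 0, nv = 1)
  v <- sv$v[, 1]
  if (sum(abs(v[v < 0])) > sum(abs(v[v > 0]))) v <- -v
  starts <- list(project_nonneg_unit(v), project_nonneg_unit(-v))
  p <- ncol(X)
  axes <- utils::head(order(-colSums(X^2)), max_axes)
  for (i in axes) {
    e <- numeric(p)
    e[i] <- 1
    starts <- c(starts, list(e))
  }
  starts
}

#' Fit nonnegative PCA on a centered matrix
#'
#' Extracts `K` successive variance-maximizing axes with nonnegative,
#' unit-norm loadings from a column-centered samples x genes matrix, using
#' projected power iteration over a deterministic start portfolio (the
#' projected classical leading singular vector of the current residual,
#' both signs, plus single-gene axes), with Hotelling-type data deflation
#' between axes. Variance explained is reported as a fraction of the total
#' centered variance of the ORIGINAL matrix, so fractions are comparable
#' across axes and sum to at most 1.
#'
#' @param X Numeric matrix, samples x genes, each column mean zero (use
#'   `scale(t(m$values), center = TRUE, scale = FALSE)` on a genes x samples
#'   matrix). An attribute `"center"` (per-gene means), if present, is
#'   carried into the model.
#' @param K Number of axes, `1 <= K <= min(dim(X))`.
#' @param tol Convergence threshold on the Euclidean change of the loading
#'   vector per iteration.
#' @param max_iter Iteration cap per axis; non-convergence is recorded and
#'   warned, never fatal.
#' @param restarts Additional seeded random nonnegative restarts per axis;
#'   the solution with the largest score variance wins. The deterministic
#'   singular-vector start is always included.
#' @param seed Seed for the random restarts (ignored when `restarts = 0`).
#' @return An object of class `nnpca_model` with fields `loadings`
#'   (genes x K, entrywise nonnegative, unit columns), `scores`
#'   (samples x K), `varexp` (non-increasing fractions), `center`, `n_iter`,
#'   `converged` and `seed`.
#' @export
fit_nnpca <- function(X, K, tol = 1e-8, max_iter = 500L, restarts = 0L,
                      seed = 1L) {
  if (!is.matrix(X) || !is.numeric(X)) {
    stop("`X` must be a numeric matrix (samples x genes)", call. = FALSE)
  }
  n <- nrow(X); p <- ncol(X)
  assert_scalar_number(K, "K", lower = 1, upper = min(n, p))
  K <- as.integer(K)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  scale_ref <- max(abs(X), 1e-12)
  col_means <- colMeans(X)
  if (any(abs(col_means) > 1e-6 * scale_ref)) {
    stop("`X` must be column-centered (gene means zero); center it first",
         call. = FALSE)
  }
  center <- attr(X, "center") %||% stats::setNames(numeric(p), colnames(X))
  gene_names <- colnames(X) %||% paste0("g", seq_len(p))

  total_var <- sum(X^2) / (n - 1)
  if (total_var <= 0) stop("matrix has zero total variance", call. = FALSE)

  loadings <- matrix(0, p, K, dimnames = list(gene_names, NULL))
  scores <- matrix(0, n, K, dimnames = list(rownames(X), NULL))
  varexp <- numeric(K)
  n_iter <- integer(K)
  converged <- logical(K)

  Xres <- X
  rst_seeds <- if (restarts > 0L) {
    with_seed(seed, sample.int(.Machine$integer.max, restarts))
  } else integer(0)

  for (k in seq_len(K)) {
    C <- crossprod(Xres)
    starts <- .nnpca_starts(Xres)
    for (s in rst_seeds) {
      starts <- c(starts, list(with_seed(s + k, project_nonneg_unit(stats::runif(p)))))
    }
    best <- NULL
    best_obj <- -Inf
    for (w0 in starts) {
      cand <- .nnpca_power(C, w0, tol = tol, max_iter = max_iter)
      obj <- as.numeric(crossprod(cand$w, C %*% cand$w))
      if (obj > best_obj) {
        best <- cand
        best_obj <- obj
      }
    }
    w <- best$w
    t_k <- as.numeric(Xres %*% w)
    loadings[, k] <- w
    scores[, k] <- t_k
    varexp[k] <- (sum(t_k^2) / (n - 1)) / total_var
    n_iter[k] <- best$n_iter
    converged[k] <- best$converged
    Xres <- Xres - tcrossprod(t_k, w)
  }
  if (!all(converged)) {
    warning("nnPCA axis(es) ", paste(which(!converged), collapse = ", "),
            " did not converge within ", max_iter, " iterations", call. = FALSE)
  }
  # Axes are extracted by successive deflation, but the product contract is
  # their ranking by variance explained; the non-convex solve can (rarely,
  # on unstructured data) leave a later axis ahead of an earlier one, so
  # report axes sorted by varexp.
  ord <- order(-varexp)
  loadings <- loadings[, ord, drop = FALSE]
  scores <- scores[, ord, drop = FALSE]
  varexp <- varexp[ord]
  n_iter <- n_iter[ord]
  converged <- converged[ord]
  colnames(loadings) <- colnames(scores) <- paste0("PC", seq_len(K))
  structure(list(loadings = loadings, scores = scores, varexp = varexp,
                 center = center, n_iter = n_iter, converged = converged,
                 seed = seed),
            class = "nnpca_model")
}

#' @export
print.nnpca_model <- function(x, ...) {
  cat(sprintf("<nnpca_model> %d genes, %d axes; variance explained: %s\n",
              nrow(x$loadings), ncol(x$loadings),
              paste(sprintf("%.3f", x$varexp), collapse = ", ")))
  invisible(x)
}

#' Variance explained by score columns
#'
#' Fraction of the total centered variance of `X_original` captured by each
#' score column: `Var(t_k) / sum of per-gene variances`.
#'
#' @param X_original Column-centered samples x genes matrix.
#' @param scores Samples x K score matrix (columns `t_k`).
#' @return Numeric vector of K fractions.
#' @export
variance_explained <- function(X_original, scores) {
  if (is.vector(scores)) scores <- matrix(scores, ncol = 1)
  stopifnot(is.matrix(X_original), nrow(X_original) == nrow(scores))
  n <- nrow(X_original)
  total_var <- sum(scale(X_original, center = TRUE, scale = FALSE)^2) / (n - 1)
  if (total_var <= 0) stop("zero total variance in `X_original`", call. = FALSE)
  apply(scores, 2, function(t_k) stats::var(t_k) / total_var)
}

#' Top-loading genes of an nnPCA axis
#'
#' Ranks the genes driving an axis by loading, descending, ties broken
#' alphabetically; genes with zero loading never appear (a zero loading
#' means the gene plays no part in the axis).
#'
#' @param model An `nnpca_model`.
#' @param pc Axis index, `1 <= pc <= K`.
#' @param n Maximum number of genes returned.
#' @return A data.frame with columns `gene` and `loading`.
#' @export
top_loading_genes <- function(model, pc = 1L, n = 10L) {
  stopifnot(inherits(model, "nnpca_model"))
  K <- ncol(model$loadings)
  if (!is.numeric(pc) || length(pc) != 1L || pc < 1 || pc > K) {
    stop("`pc` must be in 1..", K, call. = FALSE)
  }
  assert_scalar_number(n, "n", lower = 1)
  w <- model$loadings[, pc]
  keep <- w > 0
  genes <- names(w)[keep]
  vals <- unname(w[keep])
  ord <- order(-vals, genes)
  ord <- ord[seq_len(min(n, length(ord)))]
  data.frame(gene = genes[ord], loading = vals[ord], row.names = NULL,
             stringsAsFactors = FALSE)
}

# Center a genes x samples expression_matrix for nnPCA: returns samples x
# genes with per-gene means in attr "center".
.centered_samples_by_genes <- function(m) {
  X <- t(m$values)
  ctr <- colMeans(X)
  X <- sweep(X, 2, ctr)
  attr(X, "center") <- ctr
  X
}
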