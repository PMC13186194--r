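# Expression-matrix ingestion, normalization and gene-set subsetting.
#
# Internally everything is genes x samples. Delimited files with samples as
# rows are handled only via an explicit `transpose = TRUE` — orientation is
# never auto-detected, because silent auto-transpose corrupts square-ish
# matrices.

#' Construct an expression matrix
#'
#' @param values Numeric matrix, genes as rows and samples as columns.
#' @param gene_ids Unique gene symbols per row; defaults to `rownames(values)`.
#' @param sample_ids Unique sample identifiers per column; defaults to
#'   `colnames(values)`.
#' @param norm_tag One of `"raw"` (nonnegative counts), `"lognorm"`
#'   (log-normalized) or `"unknown"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              norm_tag = c("unknown", "raw", "lognorm")) {
  norm_tag <- match.arg(norm_tag)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene and sample identifiers are required", call. = FALSE)
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifiers; collapse duplicates first (read_matrix does this)",
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample identifiers", call. = FALSE)
  if (anyNA(values)) stop("expression values contain NA", call. = FALSE)
  if (norm_tag == "raw" && any(values < 0)) {
    stop("raw matrices must be nonnegative", call. = FALSE)
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
                 norm_tag = norm_tag),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$norm_tag))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

# Collapse duplicate gene rows by summation (count semantics) with a warning.
.collapse_duplicates <- function(values, gene_ids) {
  if (!anyDuplicated(gene_ids)) {
    rownames(values) <- gene_ids
    return(values)
  }
  dups <- unique(gene_ids[duplicated(gene_ids)])
  warning("collapsing ", length(dups), " duplicated gene id(s) by summation: ",
          paste(utils::head(dups, 5), collapse = ", "), call. = FALSE)
  out <- rowsum(values, group = gene_ids, reorder = FALSE)
  out
}

#' Read an expression matrix from disk
#'
#' Two on-disk layouts are supported. `"delimited"` is a TSV/CSV table
#' (gzip-transparent) with a header row of sample ids and gene ids in the
#' first column. `"triplet"` is the MatrixMarket-style sparse coordinate
#' format (banner, dimensions, 1-based `i j value` records) with sidecar
#' row-annotation and column-annotation text files, one id per line — the
#' layout 10x-style pipelines emit.
#'
#' Duplicate gene ids are collapsed by summation with a warning. The result
#' is tagged `raw` when every value is a nonnegative integer, else `unknown`.
#'
#' @param path Matrix file.
#' @param format `"delimited"` or `"triplet"`.
#' @param genes_path,samples_path Sidecar id files (triplet format only).
#' @param transpose If `TRUE`, the delimited file is samples x genes and is
#'   transposed after reading. Never auto-detected.
#' @param sep Field separator for delimited files; auto-set from the file
#'   extension (`.csv` vs anything else) when `NULL`.
#' @return An `expression_matrix`.
#' @export
read_matrix <- function(path, format = c("delimited", "triplet"),
                        genes_path = NULL, samples_path = NULL,
                        transpose = FALSE, sep = NULL) {
  format <- match.arg(format)
  assert_string(path, "path")
  if (!file.exists(path)) stop("matrix file not found: ", path, call. = FALSE)

  if (format == "delimited") {
    if (is.null(sep)) {
      sep <- if (grepl("\\.csv(\\.gz)?$", path, ignore.case = TRUE)) "," else "\t"
    }
    dt <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE,
                            check.names = FALSE)
    if (ncol(dt) < 2L) stop("delimited matrix needs an id column plus >= 1 sample column",
                            call. = FALSE)
    ids <- as.character(dt[[1]])
    vals <- dt[, -1, drop = FALSE]
    bad <- !vapply(vals, is.numeric, logical(1))
    if (any(bad)) {
      col <- colnames(vals)[which(bad)[1]]
      row <- which(is.na(suppressWarnings(as.numeric(vals[[which(bad)[1]]]))))[1]
      stop(sprintf("non-numeric value in column '%s' (data row %s) of %s",
                   col, row %||% "?", path), call. = FALSE)
    }
    values <- as.matrix(vals)
    rownames(values) <- NULL
    if (isTRUE(transpose)) {
      values <- t(values)
      gene_ids <- colnames(dt)[-1]
      sample_ids <- ids
      dimnames(values) <- list(gene_ids, sample_ids)
    } else {
      gene_ids <- ids
      sample_ids <- colnames(dt)[-1]
      dimnames(values) <- list(NULL, sample_ids)
    }
    values <- .collapse_duplicates(values, gene_ids)
  } else {
    if (is.null(genes_path) || is.null(samples_path)) {
      stop("triplet format requires `genes_path` and `samples_path`", call. = FALSE)
    }
    for (p in c(genes_path, samples_path)) {
      if (!file.exists(p)) stop("annotation file not found: ", p, call. = FALSE)
    }
    first <- readLines(path, n = 50L)
    body <- grep("^%", first, invert = TRUE, value = TRUE)
    recs <- lapply(strsplit(trimws(body), "\\s+"), as.numeric)
    recs <- Filter(function(r) length(r) >= 2, recs)
    if (length(recs) > 1L) {
      idx <- do.call(rbind, lapply(recs[-1], function(r) r[1:2]))
      if (any(idx == 0)) {
        stop("triplet indices must be 1-based; found index 0 in ", path, call. = FALSE)
      }
    }
    sm <- tryCatch(Matrix::readMM(path),
                   error = function(e) stop("cannot parse sparse triplet file ",
                                            path, ": ", conditionMessage(e),
                                            call. = FALSE))
    gene_ids <- trimws(readLines(genes_path, warn = FALSE))
    sample_ids <- trimws(readLines(samples_path, warn = FALSE))
    gene_ids <- gene_ids[nzchar(gene_ids)]
    sample_ids <- sample_ids[nzchar(sample_ids)]
    if (length(gene_ids) != nrow(sm) || length(sample_ids) != ncol(sm)) {
      stop(sprintf("triplet dimension mismatch: matrix is %d x %d but sidecars list %d genes and %d samples",
                   nrow(sm), ncol(sm), length(gene_ids), length(sample_ids)),
           call. = FALSE)
    }
    values <- as.matrix(sm)
    values <- .collapse_duplicates(values, gene_ids)
    sample_ids <- sample_ids
    colnames(values) <- sample_ids
  }

  tag <- if (all(values >= 0) && all(abs(values - round(values)) < 1e-9)) "raw" else "unknown"
  expression_matrix(values, gene_ids = rownames(values),
                    sample_ids = colnames(values), norm_tag = tag)
}

#' Write an expression matrix as delimited text
#'
#' Writes the genes x samples table with a `gene` id column; `read_matrix()`
#' on the result reproduces values and identifiers.
#'
#' @param m An `expression_matrix`.
#' @param path Output path (`.tsv` or `.csv`, optionally `.gz`).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "expression_matrix"))
  sep <- if (grepl("\\.csv(\\.gz)?$", path, ignore.case = TRUE)) "," else "\t"
  dt <- data.table::data.table(gene = m$gene_ids)
  dt <- cbind(dt, data.table::as.data.table(m$values))
  data.table::fwrite(dt, path, sep = sep)
  invisible(path)
}

#' Library-size normalize an expression matrix
#'
#' `cpm_log1p` scales each sample to a fixed total (10,000 by default, the
#' single-cell convention) and applies `log(1 + x)`; a monotone transform, so
#' within-sample gene ranks are preserved. All-zero samples stay all-zero
#' with a warning. `none` returns the input unchanged.
#'
#' @param m An `expression_matrix`; must not already be `lognorm` when
#'   `method = "cpm_log1p"`.
#' @param method `"cpm_log1p"` or `"none"`.
#' @param scale_factor Per-sample target total before `log1p`.
#' @return An `expression_matrix` (tagged `lognorm` for `cpm_log1p`).
#' @export
normalize_matrix <- function(m, method = c("cpm_log1p", "none"),
                             scale_factor = 1e4) {
  stopifnot(inherits(m, "expression_matrix"))
  method <- match.arg(method)
  if (method == "none") return(m)
  assert_scalar_number(scale_factor, "scale_factor", lower = 1)
  if (m$norm_tag == "lognorm") {
    stop("matrix is already log-normalized; refusing to renormalize", call. = FALSE)
  }
  totals <- colSums(m$values)
  zero <- totals == 0
  if (any(zero)) {
    warning(sum(zero), " sample(s) with zero total left all-zero: ",
            paste(utils::head(m$sample_ids[zero], 5), collapse = ", "),
            call. = FALSE)
    totals[zero] <- 1
  }
  vals <- log1p(sweep(m$values, 2, totals / scale_factor, "/"))
  expression_matrix(vals, m$gene_ids, m$sample_ids, norm_tag = "lognorm")
}

#' Subset an expression matrix to a gene set
#'
#' Matching is case-insensitive; output rows keep the matrix's own row order
#' (not the set order), so results are deterministic regardless of how the
#' set was written.
#'
#' @param m An `expression_matrix`.
#' @param s A `gene_set`.
#' @param min_genes Minimum matched genes (default 5; below this a PCA axis
#'   on the subset is dominated by single-gene noise).
#' @return A list with `matrix` (the submatrix `expression_matrix`) and
#'   `report` (matched symbols, missing symbols, match fraction).
#' @export
subset_to_set <- function(m, s, min_genes = 5L) {
  stopifnot(inherits(m, "expression_matrix"), inherits(s, "gene_set"))
  assert_scalar_number(min_genes, "min_genes", lower = 1)
  upper_rows <- toupper(m$gene_ids)
  keep <- upper_rows %in% s$genes
  matched <- s$genes[s$genes %in% upper_rows]
  missing <- setdiff(s$genes, upper_rows)
  if (sum(keep) < min_genes) {
    stop(sprintf("gene set '%s': only %d of %d genes found in the matrix (min_genes = %d)",
                 s$name, sum(keep), length(s$genes), min_genes), call. = FALSE)
  }
  sub <- expression_matrix(m$values[keep, , drop = FALSE],
                           gene_ids = m$gene_ids[keep],
                           sample_ids = m$sample_ids,
                           norm_tag = m$norm_tag)
  list(matrix = sub,
       report = list(set = s$name, matched = matched, missing = missing,
                     match_fraction = length(matched) / length(s$genes)))
}

#' Read sample annotations
#'
#' A delimited table whose first column (or a column named `sample_id`)
#' holds sample identifiers; remaining columns are labels (time point,
#' cluster) or numeric covariates such as pseudotime.
#'
#' @param path Delimited file.
#' @param m Optional `expression_matrix` to validate against: the annotation
#'   ids must be exactly the matrix's sample ids (any order).
#' @return A data.frame with a `sample_id` column, reordered to match `m`
#'   when given.
#' @export
read_annotations <- function(path, m = NULL) {
  assert_string(path, "path")
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  df <- data.table::fread(path, header = TRUE, data.table = FALSE)
  idcol <- if ("sample_id" %in% names(df)) "sample_id" else names(df)[1]
  df$sample_id <- as.character(df[[idcol]])
  df <- df[c("sample_id", setdiff(names(df), "sample_id"))]
  if (!is.null(m)) {
    stopifnot(inherits(m, "expression_matrix"))
    if (!setequal(df$sample_id, m$sample_ids) || nrow(df) != ncol(m$values)) {
      stop("annotation sample ids do not match the matrix's sample ids", call. = FALSE)
    }
    df <- df[match(m$sample_ids, df$sample_id), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}
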