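# Gene sets and GMT input/output.
#
# A gene set is the unit of scoring throughout the package: a named, ordered
# collection of unique, upper-cased gene symbols. Collections bundle many sets
# (e.g. an MSigDB-style GMT file supplied by the user for screening).

#' Construct a gene set
#'
#' Gene symbols are upper-cased and de-duplicated case-insensitively, keeping
#' the first occurrence, so mixed-case human/mouse symbols cannot create
#' spurious duplicates downstream.
#'
#' @param name Set name; non-empty, no tab characters.
#' @param genes Character vector of gene symbols; at least one after
#'   de-duplication.
#' @param description Free-text description (may be empty).
#' @return An object of class `gene_set` with fields `name`, `description`
#'   and `genes`.
#' @examples
#' gene_set("MES_MARKERS", c("VIM", "vim", "FN1"))
#' @export
gene_set <- function(name, genes, description = "") {
  assert_string(name, "name")
  if (grepl("\t", name, fixed = TRUE)) {
    stop("gene set name must not contain tab characters: ", name, call. = FALSE)
  }
  if (!is.character(genes) || length(genes) == 0L) {
    stop("`genes` must be a non-empty character vector", call. = FALSE)
  }
  if (!is.character(description) || length(description) != 1L || is.na(description)) {
    stop("`description` must be a single string", call. = FALSE)
  }
  genes <- toupper(trimws(genes))
  genes <- genes[nzchar(genes)]
  genes <- genes[!duplicated(genes)]
  if (length(genes) == 0L) {
    stop("gene set '", name, "' has no genes after cleaning", call. = FALSE)
  }
  structure(list(name = name, description = description, genes = genes),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$genes)))
  shown <- utils::head(x$genes, 8L)
  cat("  ", paste(shown, collapse = ", "),
      if (length(x$genes) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' Construct a gene-set collection
#'
#' @param sets List of `gene_set` objects; set names must be unique.
#' @param source_tag Free-text provenance tag carried through to outputs.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, source_tag = "") {
  if (!is.list(sets) || length(sets) == 0L ||
      !all(vapply(sets, inherits, logical(1), "gene_set"))) {
    stop("`sets` must be a non-empty list of gene_set objects", call. = FALSE)
  }
  nms <- vapply(sets, `[[`, character(1), "name")
  dup <- nms[duplicated(nms)]
  if (length(dup) > 0L) {
    stop("duplicate gene set name(s) in collection: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  names(sets) <- nms
  structure(list(sets = sets, source_tag = source_tag),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets%s\n", length(x$sets),
              if (nzchar(x$source_tag)) paste0(" [", x$source_tag, "]") else ""))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Parse a GMT gene-set file
#'
#' GMT is the tab-separated gene-set exchange format: one set per line with
#' fields name, description, then one or more gene symbols. Symbols are
#' upper-cased and de-duplicated per set (first occurrence kept).
#'
#' @param path Path to a GMT file.
#' @param source_tag Provenance tag for the collection; defaults to the file
#'   name.
#' @return A `gene_set_collection`.
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines("SETA\tdemo\tTP53\tVIM", f)
#' parse_gmt(f)
#' @export
parse_gmt <- function(path, source_tag = basename(path)) {
  assert_string(path, "path")
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("GMT file is empty (no gene sets): ", path, call. = FALSE)
  }
  seen <- character(0)
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("malformed GMT line %d in %s: expected >= 3 tab-separated fields, got %d",
                   i, path, length(fields)), call. = FALSE)
    }
    if (fields[[1]] %in% seen) {
      stop(sprintf("duplicate gene set name '%s' at line %d of %s",
                   fields[[1]], i, path), call. = FALSE)
    }
    seen <- c(seen, fields[[1]])
    sets[[i]] <- gene_set(fields[[1]], fields[-(1:2)], description = fields[[2]])
  }
  gene_set_collection(sets, source_tag = source_tag)
}

#' Write a gene-set collection to a GMT file
#'
#' Round-trip guarantee: `parse_gmt()` on the written file reproduces the set
#' names, descriptions and gene lists exactly.
#'
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  if (!inherits(collection, "gene_set_collection")) {
    stop("`collection` must be a gene_set_collection", call. = FALSE)
  }
  assert_string(path, "path")
  lines <- vapply(collection$sets, function(s) {
    paste(c(s$name, s$description, s$genes), collapse = "\t")
  }, character(1))
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e) stop("cannot write GMT file: ", path,
                                           " (", conditionMessage(e), ")",
                                           call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# Registry of E/M marker pairs shipped with the package. Each entry names a
# GMT file under inst/extdata holding exactly two sets: the epithelial set
# first, the mesenchymal set second.
.emt_registry <- function() {
  c(default = "emt_markers_default.gmt")
}

#' Bundled epithelial/mesenchymal marker sets
#'
#' Returns the E and M gene sets registered under `source`. The package ships
#' a compact default pair of widely recognized epithelial (junction/polarity)
#' and mesenchymal (motility/EMT transcription factor) markers; published EMT
#' signature files in GMT format drop in as replacements via [parse_gmt()].
#'
#' @param source Registry key; see the error message for valid keys.
#' @return A list with elements `E` and `M`, both `gene_set` objects. A
#'   warning is raised if the two sets overlap.
#' @examples
#' sets <- bundled_emt_sets()
#' sets$E
#' @export
bundled_emt_sets <- function(source = "default") {
  assert_string(source, "source")
  reg <- .emt_registry()
  if (!source %in% names(reg)) {
    stop("unknown EMT gene-set source '", source, "'; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  path <- system.file("extdata", reg[[source]], package = "emtscape",
                      mustWork = TRUE)
  coll <- parse_gmt(path, source_tag = source)
  if (length(coll$sets) != 2L) {
    stop("registry file for '", source, "' must hold exactly two sets (E, M)",
         call. = FALSE)
  }
  e_set <- coll$sets[[1]]
  m_set <- coll$sets[[2]]
  shared <- intersect(e_set$genes, m_set$genes)
  if (length(shared) > 0L) {
    warning("E and M sets for source '", source, "' share ", length(shared),
            " gene(s): ", paste(utils::head(shared, 5), collapse = ", "),
            call. = FALSE)
  }
  list(E = e_set, M = m_set)
}

#' Overlap fraction between two gene sets
#'
#' Used to filter screening candidates that share too many genes with the
#' reference EMT set (a candidate dominated by EMT genes trivially correlates
#' with the EMT score). The denominator is configurable: the candidate set's
#' size (default, so small EMT-heavy candidates are caught even against a
#' large reference), the reference's size, or the union (Jaccard).
#'
#' @param candidate,reference `gene_set` objects, both non-empty.
#' @param denominator One of `"candidate"`, `"reference"`, `"jaccard"`.
#' @return Fraction in `[0, 1]`.
#' @examples
#' a <- gene_set("A", c("A", "B", "C", "D"))
#' b <- gene_set("B", c("A", "B", "X"))
#' overlap_fraction(a, b) # 2/4
#' @export
overlap_fraction <- function(candidate, reference,
                             denominator = c("candidate", "reference", "jaccard")) {
  if (!inherits(candidate, "gene_set") || !inherits(reference, "gene_set")) {
    stop("`candidate` and `reference` must be gene_set objects", call. = FALSE)
  }
  denominator <- match.arg(denominator)
  n_shared <- length(intersect(candidate$genes, reference$genes))
  denom <- switch(denominator,
    candidate = length(candidate$genes),
    reference = length(reference$genes),
    jaccard   = length(union(candidate$genes, reference$genes)))
  n_shared / denom
}
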