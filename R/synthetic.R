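# Synthetic expression data with planted EMT structure.
#
# Two generators emulate the structures the analysis modules are built for:
# a single-cell EMT-induction time course (epithelial program down,
# mesenchymal program up along a latent progression) and a bulk cohort with
# two divergent mesenchymal programs active in different sample groups.
# Counts are Poisson draws on log-normal means — simple, and adequate for
# rank- and PCA-based scoring; scRNA-seq dropout and batch structure are
# deliberately not modeled.

#' Simulate an EMT-induction time course
#'
#' Each cell carries a latent progression value p in `[0, 1]` drawn from a
#' Beta distribution whose mean increases with the cell's time point, so
#' time points overlap (hybrid cells concentrate at transition times rather
#' than mapping hard onto states). Epithelial genes have log-mean
#' `baseline + effect * (1 - p)`, mesenchymal genes
#' `baseline + effect * p`, background genes `baseline`; Gaussian noise
#' (`noise_sd`) is added on the log scale, then counts are Poisson-sampled.
#'
#' Beyond the E and M programs, two planted "bystander process" blocks
#' track p and `1 - p` respectively while staying disjoint from the E/M
#' sets — they are what a gene-set screen should recover as the top
#' positively and negatively EMT-correlated processes.
#'
#' Planted states cut the progression at 1/3 and 2/3 (E / hybrid / M); the
#' reported pseudotime is p plus small jitter.
#'
#' @param n_cells,n_genes Matrix dimensions.
#' @param n_e,n_m Sizes of the planted epithelial and mesenchymal programs.
#' @param n_tracked,n_antitracked Sizes of the planted bystander blocks
#'   tracking p and `1 - p`.
#' @param timepoints Time-point labels; cells are spread evenly across them
#'   and the Beta mean rises linearly from 0.1 to 0.9 over their range.
#' @param effect Log-fold dynamic range of the planted programs; 0 gives a
#'   null dataset.
#' @param noise_sd Log-scale Gaussian noise standard deviation.
#' @param baseline Baseline natural-log mean expression.
#' @param concentration Beta concentration (a + b); larger = tighter
#'   progression within a time point.
#' @param seed Seed; everything is deterministic given it.
#' @return A list: `matrix` (raw-count `expression_matrix`), `annotations`
#'   (sample_id, time, pseudotime), `e_set` / `m_set` (`gene_set`s), and
#'   `truth` (planted gene blocks, per-cell progression, state, parameters).
#' @export
generate_timecourse <- function(n_cells = 2000L, n_genes = 1000L,
                                n_e = 50L, n_m = 50L,
                                n_tracked = 40L, n_antitracked = 40L,
                                timepoints = c(0, 1, 2, 4, 7),
                                effect = 2.0, noise_sd = 0.4,
                                baseline = 1.0, concentration = 12,
                                seed = 1L) {
  assert_scalar_number(n_cells, "n_cells", lower = 10)
  assert_scalar_number(n_genes, "n_genes", lower = 10)
  assert_scalar_number(effect, "effect", lower = 0)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  n_cells <- as.integer(n_cells); n_genes <- as.integer(n_genes)
  n_planted <- n_e + n_m + n_tracked + n_antitracked
  if (n_planted >= n_genes) {
    stop("planted programs (", n_planted, " genes) must be smaller than n_genes",
         call. = FALSE)
  }
  if (length(timepoints) < 2L) stop("need at least 2 time points", call. = FALSE)

  e_genes <- sprintf("EPI_G%03d", seq_len(n_e))
  m_genes <- sprintf("MES_G%03d", seq_len(n_m))
  tracked <- sprintf("PROCPOS_G%03d", seq_len(n_tracked))
  antitracked <- sprintf("PROCNEG_G%03d", seq_len(n_antitracked))
  bg <- sprintf("BG_G%04d", seq_len(n_genes - n_planted))
  gene_ids <- c(e_genes, m_genes, tracked, antitracked, bg)

  out <- with_seed(seed, {
    tp <- sort(timepoints)
    time <- sort(rep(tp, length.out = n_cells))
    rel <- (time - min(tp)) / (max(tp) - min(tp))
    mu <- 0.1 + 0.8 * rel
    p <- stats::rbeta(n_cells, mu * concentration, (1 - mu) * concentration)

    logmu <- matrix(baseline, n_genes, n_cells)
    down <- effect * (1 - p)  # epithelial-style trajectory
    up <- effect * p          # mesenchymal-style trajectory
    idx_e <- seq_len(n_e)
    idx_m <- n_e + seq_len(n_m)
    idx_tr <- n_e + n_m + seq_len(n_tracked)
    idx_at <- n_e + n_m + n_tracked + seq_len(n_antitracked)
    logmu[idx_e, ] <- baseline + matrix(down, n_e, n_cells, byrow = TRUE)
    logmu[idx_m, ] <- baseline + matrix(up, n_m, n_cells, byrow = TRUE)
    logmu[idx_tr, ] <- baseline + matrix(up, n_tracked, n_cells, byrow = TRUE)
    logmu[idx_at, ] <- baseline + matrix(down, n_antitracked, n_cells, byrow = TRUE)
    logmu <- logmu + matrix(stats::rnorm(n_genes * n_cells, 0, noise_sd),
                            n_genes, n_cells)
    counts <- matrix(stats::rpois(n_genes * n_cells, exp(logmu)),
                     n_genes, n_cells)
    pseudotime <- pmin(1, pmax(0, p + stats::rnorm(n_cells, 0, 0.01)))
    list(time = time, p = p, counts = counts, pseudotime = pseudotime)
  })

  sample_ids <- sprintf("cell%05d", seq_len(n_cells))
  em <- expression_matrix(out$counts, gene_ids = gene_ids,
                          sample_ids = sample_ids, norm_tag = "raw")
  state <- cut(out$p, breaks = c(-Inf, 1 / 3, 2 / 3, Inf),
               labels = c("E", "H", "M"))
  ann <- data.frame(sample_id = sample_ids, time = out$time,
                    pseudotime = out$pseudotime, stringsAsFactors = FALSE)
  truth <- list(e_genes = e_genes, m_genes = m_genes,
                tracked_genes = tracked, antitracked_genes = antitracked,
                background_genes = bg,
                progression = out$p, state = as.character(state),
                params = list(n_cells = n_cells, n_genes = n_genes,
                              n_e = n_e, n_m = n_m, effect = effect,
                              noise_sd = noise_sd, timepoints = timepoints),
                seed = seed)
  list(matrix = em, annotations = ann,
       e_set = gene_set("E_PLANTED", e_genes, "planted epithelial program"),
       m_set = gene_set("M_PLANTED", m_genes, "planted mesenchymal program"),
       truth = truth)
}

#' Simulate a cohort with two divergent mesenchymal programs
#'
#' Three sample groups: one upregulates mesenchymal program 1 only, one
#' program 2 only, and an epithelial-like group upregulates the E genes.
#' Program 2's effect is scaled down (default 0.8x) so the two programs
#' have distinct planted effect sizes and the variance ranking of the
#' nonnegative PCs (M1 = program 1, M2 = program 2) is determined. The M
#' gene set handed to scoring is the union of the two programs.
#'
#' @param n_samples Cohort size, split evenly across the three groups.
#' @param n_genes Total genes.
#' @param m1_genes,m2_genes,e_genes Program sizes.
#' @param effect Log-fold upregulation of a program in its group.
#' @param m2_effect_scale Multiplier on `effect` for program 2.
#' @param noise_sd,baseline As in [generate_timecourse()].
#' @param group_names Labels for the program-1, program-2 and E-like groups.
#' @param seed Seed.
#' @return A list: `matrix` (raw counts), `annotations` (sample_id, group),
#'   `e_set`, `m_set` (union of the two M programs), and `truth` (the
#'   planted programs and group memberships).
#' @export
generate_divergent_programs <- function(n_samples = 120L, n_genes = 500L,
                                        m1_genes = 30L, m2_genes = 30L,
                                        e_genes = 30L, effect = 2.0,
                                        m2_effect_scale = 0.8,
                                        noise_sd = 0.4, baseline = 1.5,
                                        group_names = c("Y", "AN", "Elike"),
                                        seed = 1L) {
  assert_scalar_number(n_samples, "n_samples", lower = 9)
  assert_scalar_number(effect, "effect", lower = 0)
  n_samples <- as.integer(n_samples); n_genes <- as.integer(n_genes)
  n_planted <- m1_genes + m2_genes + e_genes
  if (n_planted >= n_genes) stop("planted programs must be smaller than n_genes",
                                 call. = FALSE)
  if (length(group_names) != 3L) stop("exactly 3 group names expected", call. = FALSE)

  p1 <- sprintf("MPROG1_G%03d", seq_len(m1_genes))
  p2 <- sprintf("MPROG2_G%03d", seq_len(m2_genes))
  eg <- sprintf("EPI_G%03d", seq_len(e_genes))
  bg <- sprintf("BG_G%04d", seq_len(n_genes - n_planted))
  gene_ids <- c(p1, p2, eg, bg)
  group <- rep(group_names, length.out = n_samples)
  group <- sort(factor(group, levels = group_names))

  counts <- with_seed(seed, {
    logmu <- matrix(baseline, n_genes, n_samples)
    in1 <- group == group_names[1]
    in2 <- group == group_names[2]
    in3 <- group == group_names[3]
    logmu[seq_len(m1_genes), in1] <- baseline + effect
    logmu[m1_genes + seq_len(m2_genes), in2] <- baseline + effect * m2_effect_scale
    logmu[m1_genes + m2_genes + seq_len(e_genes), in3] <- baseline + effect
    logmu <- logmu + matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd),
                            n_genes, n_samples)
    matrix(stats::rpois(n_genes * n_samples, exp(logmu)), n_genes, n_samples)
  })

  sample_ids <- sprintf("sample%03d", seq_len(n_samples))
  em <- expression_matrix(counts, gene_ids = gene_ids,
                          sample_ids = sample_ids, norm_tag = "raw")
  ann <- data.frame(sample_id = sample_ids, group = as.character(group),
                    stringsAsFactors = FALSE)
  truth <- list(program1 = p1, program2 = p2, e_genes = eg,
                background_genes = bg, group = as.character(group),
                params = list(n_samples = n_samples, effect = effect,
                              m2_effect_scale = m2_effect_scale,
                              noise_sd = noise_sd),
                seed = seed)
  list(matrix = em, annotations = ann,
       e_set = gene_set("E_PLANTED", eg, "planted epithelial program"),
       m_set = gene_set("M_PLANTED", c(p1, p2),
                        "union of the two planted mesenchymal programs"),
       truth = truth)
}

#' Build a screening collection with planted hits
#'
#' Assembles a gene-set collection over the genes of a
#' [generate_timecourse()] dataset: `n_correlated` sets drawn from the
#' planted progression-tracking block (these should top the positive
#' ranking), `n_anticorrelated` sets from the anti-tracking block, and the
#' remainder sampled from background genes. All planted sets are disjoint
#' from the E/M reference programs by construction (overlap 0).
#'
#' @param truth The `truth` element of a [generate_timecourse()] result.
#' @param n_sets Total number of sets.
#' @param set_size Genes per set (capped at the relevant pool size for the
#'   planted sets).
#' @param n_correlated,n_anticorrelated Numbers of planted hit sets.
#' @param seed Seed.
#' @return A list with `collection` (a `gene_set_collection`) and
#'   `planted` (names of the planted positive/negative sets).
#' @export
generate_screen_collection <- function(truth, n_sets = 50L, set_size = 40L,
                                       n_correlated = 1L,
                                       n_anticorrelated = 1L, seed = 1L) {
  stopifnot(is.list(truth), !is.null(truth$tracked_genes))
  assert_scalar_number(n_sets, "n_sets", lower = 1)
  n_bgsets <- n_sets - n_correlated - n_anticorrelated
  if (n_bgsets < 0L) stop("n_sets smaller than the planted sets requested",
                          call. = FALSE)
  with_seed(seed, {
    sets <- list()
    for (i in seq_len(n_correlated)) {
      pool <- truth$tracked_genes
      g <- if (set_size >= length(pool)) pool else sample(pool, set_size)
      sets <- c(sets, list(gene_set(sprintf("PLANTED_POS_%d", i), g,
                                    "planted progression-tracking set")))
    }
    for (i in seq_len(n_anticorrelated)) {
      pool <- truth$antitracked_genes
      g <- if (set_size >= length(pool)) pool else sample(pool, set_size)
      sets <- c(sets, list(gene_set(sprintf("PLANTED_NEG_%d", i), g,
                                    "planted anti-tracking set")))
    }
    for (i in seq_len(n_bgsets)) {
      g <- sample(truth$background_genes,
                  min(set_size, length(truth$background_genes)))
      sets <- c(sets, list(gene_set(sprintf("RANDOM_SET_%02d", i), g,
                                    "background set")))
    }
    list(collection = gene_set_collection(sets, source_tag = "synthetic-screen"),
         planted = list(positive = sprintf("PLANTED_POS_%d", seq_len(n_correlated)),
                        negative = sprintf("PLANTED_NEG_%d", seq_len(n_anticorrelated))))
  })
}

#' Simulate well-separated EMT states in score space
#'
#' Draws samples from a Gaussian mixture along the epithelial-to-
#' mesenchymal diagonal of (E, M1) score space: an E component (high E, low
#' M), a hybrid component at the origin, and an M component (low E, high
#' M). Used to exercise the state-detection machinery against a known
#' assignment.
#'
#' @param n Number of samples.
#' @param means 3 x 2 matrix of component means in (E, M1); the default
#'   runs E = (2, -2), H = (0, 0), M = (-2, 2).
#' @param sd Within-component standard deviation (isotropic).
#' @param weights Mixing proportions.
#' @param seed Seed.
#' @return A list: `scores` (a `score_table` with E and M1 columns) and
#'   `truth` (planted component per sample, ordered E/H/M).
#' @export
generate_state_mixture <- function(n = 300L,
                                   means = rbind(E = c(2, -2),
                                                 H = c(0, 0),
                                                 M = c(-2, 2)),
                                   sd = 0.5,
                                   weights = c(1, 1, 1) / 3,
                                   seed = 1L) {
  assert_scalar_number(n, "n", lower = 10)
  stopifnot(is.matrix(means), ncol(means) == 2, nrow(means) == length(weights))
  out <- with_seed(seed, {
    comp <- sample.int(nrow(means), n, replace = TRUE, prob = weights)
    e <- stats::rnorm(n, means[comp, 1], sd)
    m <- stats::rnorm(n, means[comp, 2], sd)
    list(comp = comp, e = e, m = m)
  })
  st <- data.frame(sample_id = sprintf("s%04d", seq_len(n)),
                   E = out$e, M1 = out$m, stringsAsFactors = FALSE)
  class(st) <- c("score_table", "data.frame")
  list(scores = st,
       truth = list(component = out$comp,
                    label = rownames(means)[out$comp] %||%
                      as.character(out$comp),
                    seed = seed))
}

#' Write a synthetic bundle to disk in the public formats
#'
#' Writes the expression matrix (TSV), annotations (TSV) and the E/M gene
#' sets (GMT) of a generator result, so fixtures round-trip through the
#' same readers users run.
#'
#' @param bundle Result of [generate_timecourse()] or
#'   [generate_divergent_programs()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(is.list(bundle), inherits(bundle$matrix, "expression_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "matrix.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             genesets = file.path(dir, "genesets.gmt"))
  write_matrix(bundle$matrix, paths[["matrix"]])
  data.table::fwrite(bundle$annotations, paths[["annotations"]], sep = "\t")
  write_gmt(gene_set_collection(list(bundle$e_set, bundle$m_set),
                                source_tag = "synthetic"),
            paths[["genesets"]])
  invisible(paths)
}
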