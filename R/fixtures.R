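#' Specification for a synthetic single-cell reference
#'
#' Describes a negative-binomial scRNA-seq-like reference with planted
#' cell-type marker structure and, optionally, a two-condition design with
#' planted per-type condition DEGs.  Gene baselines are drawn log-normally so
#' genes differ in abundance; each cell type's markers have their mean
#' multiplied by `marker_fold_change` in cells of that type, and when
#' `n_conditions = 2` each type additionally gets `n_condition_degs`
#' non-marker genes whose mean is multiplied by `condition_fold_change` in
#' condition-2 cells of that type.
#'
#' @param n_cell_types number of cell types.
#' @param n_genes number of genes; must be at least
#'   `n_cell_types * n_markers_per_type` (marker sets are disjoint).
#' @param cells_per_type cells simulated per cell type.
#' @param n_markers_per_type planted markers per cell type.
#' @param marker_fold_change fold change applied to a type's markers in that
#'   type's cells (1 = no planted signal).
#' @param baseline_mean median expected count per gene per cell.
#' @param dispersion negative-binomial overdispersion; variance is
#'   `mu + dispersion * mu^2` (0 approaches Poisson).
#' @param n_conditions 1 or 2.
#' @param n_condition_degs per-type condition-responsive genes (only used
#'   when `n_conditions = 2`).
#' @param condition_fold_change fold change of condition DEGs in condition 2.
#' @param seed integer seed; identical seeds give bit-identical references.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cell_types = 6L,
                           n_genes = 1000L,
                           cells_per_type = 300L,
                           n_markers_per_type = 40L,
                           marker_fold_change = 8,
                           baseline_mean = 2,
                           dispersion = 0.5,
                           n_conditions = 1L,
                           n_condition_degs = 30L,
                           condition_fold_change = 4,
                           seed = 1L) {
  spec <- list(
    n_cell_types = as.integer(n_cell_types),
    n_genes = as.integer(n_genes),
    cells_per_type = as.integer(cells_per_type),
    n_markers_per_type = as.integer(n_markers_per_type),
    marker_fold_change = marker_fold_change,
    baseline_mean = baseline_mean,
    dispersion = dispersion,
    n_conditions = as.integer(n_conditions),
    n_condition_degs = as.integer(n_condition_degs),
    condition_fold_change = condition_fold_change,
    seed = as.integer(seed)
  )
  if (spec$n_cell_types < 1L || spec$n_genes < 1L || spec$cells_per_type < 1L) {
    abort("counts in a synthetic_spec must be positive.")
  }
  if (spec$marker_fold_change <= 0 || spec$baseline_mean <= 0 ||
      spec$dispersion <= 0 || spec$condition_fold_change <= 0) {
    abort("fold changes, baseline mean and dispersion must be positive.")
  }
  if (!spec$n_conditions %in% c(1L, 2L)) {
    abort("`n_conditions` must be 1 or 2.")
  }
  need <- spec$n_markers_per_type * spec$n_cell_types
  if (spec$n_conditions == 2L) {
    need <- need + spec$n_condition_degs * spec$n_cell_types
  }
  if (need > spec$n_genes) {
    abort(sprintf(
      "infeasible allocation: %d planted genes requested but only %d genes.",
      need, spec$n_genes
    ))
  }
  structure(spec, class = "synthetic_spec")
}

new_reference_dataset <- function(counts, cell_type, condition, split,
                                  gene_ids, markers = NULL,
                                  condition_degs = NULL, name = "ref") {
  stopifnot(nrow(counts) == length(cell_type), ncol(counts) == length(gene_ids))
  if (anyDuplicated(gene_ids)) abort("gene identifiers must be unique.")
  structure(
    list(
      counts = counts, cell_type = cell_type, condition = condition,
      split = split, gene_ids = gene_ids, markers = markers,
      condition_degs = condition_degs, name = name
    ),
    class = "reference_dataset"
  )
}

#' @export
print.reference_dataset <- function(x, ...) {
  cat(sprintf(
    "<reference_dataset '%s'> %d cells x %d genes; %d cell types",
    x$name, nrow(x$counts), ncol(x$counts), length(unique(x$cell_type))
  ), "\n")
  cat("  split:", paste(sprintf("%s=%d", names(table(x$split)), table(x$split)),
                        collapse = " "), "\n")
  if (!is.null(x$condition)) {
    cat("  conditions:", paste(unique(x$condition), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Generate a synthetic annotated single-cell reference
#'
#' Draws a cells-by-genes negative-binomial count matrix according to a
#' [synthetic_spec()], with disjoint planted marker sets per cell type and an
#' optional two-condition design.  Cells are initially all tagged `train`;
#' use [split_cells()] for an 8:1:1-style split.
#'
#' @param spec a [synthetic_spec()].
#' @param name reference name recorded in provenance.
#' @return a `reference_dataset`: `counts` (cells x genes), `cell_type`,
#'   `condition` (or NULL), `split`, `gene_ids`, plus `markers` and
#'   `condition_degs` lookup tables of the planted truth.
#' @export
generate_reference <- function(spec, name = "synthetic") {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  g <- spec$n_genes
  c_types <- paste0("type", seq_len(spec$n_cell_types))
  n_cells <- spec$cells_per_type * spec$n_cell_types
  gene_ids <- sprintf("gene%04d", seq_len(g))

  # log-normal gene baselines around baseline_mean (median)
  base_mu <- spec$baseline_mean * exp(rnorm(g, 0, 1))

  # disjoint planted gene sets
  pool <- sample.int(g)
  k <- spec$n_markers_per_type
  markers <- lapply(seq_len(spec$n_cell_types), function(i) {
    sort(pool[((i - 1) * k + 1):(i * k)])
  })
  names(markers) <- c_types
  used <- spec$n_cell_types * k
  condition_degs <- NULL
  if (spec$n_conditions == 2L) {
    kd <- spec$n_condition_degs
    condition_degs <- lapply(seq_len(spec$n_cell_types), function(i) {
      sort(pool[(used + (i - 1) * kd + 1):(used + i * kd)])
    })
    names(condition_degs) <- c_types
  }

  cell_type <- rep(c_types, each = spec$cells_per_type)
  condition <- NULL
  if (spec$n_conditions == 2L) {
    # alternate conditions within each type so both are balanced per type
    condition <- rep(rep(c("cond1", "cond2"), length.out = spec$cells_per_type),
                     times = spec$n_cell_types)
  }

  counts <- matrix(0L, nrow = n_cells, ncol = g)
  size <- 1 / spec$dispersion
  for (i in seq_len(spec$n_cell_types)) {
    mu <- base_mu
    mu[markers[[i]]] <- mu[markers[[i]]] * spec$marker_fold_change
    rows <- which(cell_type == c_types[i])
    if (spec$n_conditions == 2L) {
      mu2 <- mu
      mu2[condition_degs[[i]]] <- mu2[condition_degs[[i]]] * spec$condition_fold_change
      r1 <- rows[condition[rows] == "cond1"]
      r2 <- rows[condition[rows] == "cond2"]
      counts[r1, ] <- matrix(
        rnbinom(length(r1) * g, mu = rep(mu, each = length(r1)), size = size),
        nrow = length(r1)
      )
      counts[r2, ] <- matrix(
        rnbinom(length(r2) * g, mu = rep(mu2, each = length(r2)), size = size),
        nrow = length(r2)
      )
    } else {
      counts[rows, ] <- matrix(
        rnbinom(length(rows) * g, mu = rep(mu, each = length(rows)), size = size),
        nrow = length(rows)
      )
    }
  }
  storage.mode(counts) <- "integer"
  rownames(counts) <- sprintf("cell%05d", seq_len(n_cells))
  colnames(counts) <- gene_ids

  new_reference_dataset(
    counts, cell_type, condition,
    split = rep("train", n_cells), gene_ids = gene_ids,
    markers = markers, condition_degs = condition_degs, name = name
  )
}

#' Split reference cells into train/validation/test groups
#'
#' Random split stratified by cell type (and condition, when present) so that
#' every type appears in every non-empty split; per stratum the allocation
#' matches the requested fractions within one cell.
#'
#' @param ref a `reference_dataset`.
#' @param ratio three positive-or-zero fractions summing to 1
#'   (default `c(0.8, 0.1, 0.1)`).
#' @param seed integer seed.
#' @return the reference with its `split` tags overwritten.
#' @export
split_cells <- function(ref, ratio = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(inherits(ref, "reference_dataset"))
  if (length(ratio) != 3L || any(ratio < 0) || abs(sum(ratio) - 1) > 1e-8) {
    abort("`ratio` must be three non-negative fractions summing to 1.")
  }
  set.seed(as.integer(seed))
  split <- rep("train", nrow(ref$counts))
  strata <- if (is.null(ref$condition)) ref$cell_type else
    paste(ref$cell_type, ref$condition, sep = "|")
  n_splits <- sum(ratio > 0)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    n <- length(idx)
    if (n < n_splits) {
      warn(sprintf("stratum '%s' has %d cells (< %d splits); all go to train.",
                   s, n, n_splits))
      split[idx] <- "train"
      next
    }
    n_val <- round(ratio[2] * n)
    n_test <- round(ratio[3] * n)
    idx <- sample(idx)
    tags <- c(rep("val", n_val), rep("test", n_test),
              rep("train", n - n_val - n_test))
    split[idx] <- tags
  }
  ref$split <- split
  ref
}

#' Generate synthetic survival data with per-group hazards
#'
#' Exponential event times scaled by a per-group hazard multiplier, with
#' independent uniform censoring: a `censor_rate` fraction of patients is
#' censored at a uniformly chosen fraction of their event time.
#'
#' @param groups character/factor label per patient.
#' @param effect named hazard multiplier per label (hazard ratio relative to
#'   the baseline rate); all entries must be positive.
#' @param censor_rate fraction of patients censored (in `[0, 1)`).
#' @param base_hazard baseline exponential rate.
#' @param seed integer seed.
#' @param patient_id optional patient identifiers.
#' @return a tibble (`survival_table`) with `patient_id`, `time` (> 0),
#'   `event` (1 = observed, 0 = censored) and `group`.
#' @export
generate_survival <- function(groups, effect, censor_rate = 0.2,
                              base_hazard = 0.1, seed = 1L,
                              patient_id = NULL) {
  groups <- as.character(groups)
  if (is.null(names(effect)) || !all(unique(groups) %in% names(effect))) {
    abort("`effect` must be named and cover every group label.")
  }
  if (any(effect <= 0) || base_hazard <= 0) {
    abort("hazard multipliers and base hazard must be positive.")
  }
  if (censor_rate < 0 || censor_rate >= 1) {
    abort("`censor_rate` must be in [0, 1).")
  }
  set.seed(as.integer(seed))
  n <- length(groups)
  rate <- base_hazard * unname(effect[groups])
  time <- rexp(n, rate = rate)
  censored <- rbinom(n, 1L, censor_rate) == 1L
  u <- runif(n)
  time[censored] <- time[censored] * u[censored]
  time <- pmax(time, .Machine$double.eps)
  out <- tibble(
    patient_id = patient_id %||% sprintf("patient%04d", seq_len(n)),
    time = time,
    event = as.integer(!censored),
    group = groups
  )
  class(out) <- c("survival_table", class(out))
  out
}
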