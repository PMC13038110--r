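#' Library-size normalization into the model's input space
#'
#' Scales a non-negative count vector to counts-per-million and applies a
#' `log2(x + 1)` transform: `log2(1e6 * x / sum(x) + 1)`.  The map is
#' invariant to rescaling of the input (`normalize_log_cpm(k * x)` equals
#' `normalize_log_cpm(x)` for any `k > 0`) but is not idempotent.
#'
#' @param x non-negative numeric vector with a positive sum.
#' @return numeric vector of the same length.
#' @export
normalize_log_cpm <- function(x) {
  if (!is.numeric(x)) abort("`x` must be numeric.")
  if (any(x < 0)) abort("`x` must be non-negative.")
  s <- sum(x)
  if (s <= 0) abort("cannot normalize a vector with zero total counts.")
  log2(1e6 * x / s + 1)
}

#' Configuration for pseudobulk simulation
#'
#' Cell-type proportions are drawn from Dirichlet distributions: the `even`
#' mode uses a symmetric concentration `alpha_even` (default 25, near-even
#' proportions); the `dominant` mode picks one cell type uniformly at random
#' per draw and gives it concentration `alpha_dominant` (default 7) with 1
#' elsewhere, producing one dominant type.  The default mode `both` draws
#' half of the samples from each regime.  When several references are
#' supplied, a `mixed_reference_fraction` share of samples pools cells from
#' all references.
#'
#' @param n_samples number of pseudobulk samples.
#' @param cells_per_sample cells drawn (multinomially across types) per
#'   sample.
#' @param alpha_mode one of `"even"`, `"dominant"`, `"both"`.
#' @param alpha_even,alpha_dominant Dirichlet concentrations.
#' @param mixed_reference_fraction fraction of samples pooled across all
#'   references (ignored with a single reference).
#' @param seed integer seed.
#' @return a `simulation_config` object.
#' @export
simulation_config <- function(n_samples = 1000L,
                              cells_per_sample = 500L,
                              alpha_mode = c("both", "even", "dominant"),
                              alpha_even = 25,
                              alpha_dominant = 7,
                              mixed_reference_fraction = 0.25,
                              seed = 1L) {
  alpha_mode <- match.arg(alpha_mode)
  if (alpha_even <= 0 || alpha_dominant <= 0) {
    abort("Dirichlet concentrations must be positive.")
  }
  if (mixed_reference_fraction < 0 || mixed_reference_fraction > 1) {
    abort("`mixed_reference_fraction` must be in [0, 1].")
  }
  structure(
    list(
      n_samples = as.integer(n_samples),
      cells_per_sample = as.integer(cells_per_sample),
      alpha_mode = alpha_mode,
      alpha_even = alpha_even,
      alpha_dominant = alpha_dominant,
      mixed_reference_fraction = mixed_reference_fraction,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

rdirichlet <- function(n, alpha) {
  c <- length(alpha)
  x <- matrix(rgamma(n * c, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

#' Draw cell-type proportion vectors
#'
#' @param c_types number of cell types (>= 1).
#' @param config a [simulation_config()]; `alpha_mode`, `alpha_even`,
#'   `alpha_dominant` and `seed` are used.
#' @param n number of draws (defaults to `config$n_samples`).
#' @param set_seed whether to seed from the config (internal callers that
#'   already manage the RNG pass `FALSE`).
#' @return an `n` x `c_types` matrix of simplex rows.
#' @export
sample_proportions <- function(c_types, config = simulation_config(),
                               n = config$n_samples, set_seed = TRUE) {
  c_types <- as.integer(c_types)
  if (c_types < 1L) abort("`c_types` must be at least 1.")
  if (set_seed) set.seed(config$seed)
  if (c_types == 1L) return(matrix(1, nrow = n, ncol = 1))
  draw_even <- function(m) rdirichlet(m, rep(config$alpha_even, c_types))
  draw_dom <- function(m) {
    which_dom <- sample.int(c_types, m, replace = TRUE)
    t(vapply(which_dom, function(d) {
      a <- rep(1, c_types)
      a[d] <- config$alpha_dominant
      drop(rdirichlet(1, a))
    }, numeric(c_types)))
  }
  p <- switch(config$alpha_mode,
    even = draw_even(n),
    dominant = draw_dom(n),
    both = {
      n_even <- ceiling(n / 2)
      rbind(draw_even(n_even), draw_dom(n - n_even))
    }
  )
  p
}

#' Simulate pseudobulk samples with ground truth from a reference split
#'
#' For each drawn proportion vector, per-type cell counts are sampled
#' multinomially (`cells_per_sample` trials), cells are drawn uniformly with
#' replacement within type from the requested split, and the pseudobulk
#' count vector is the average raw count over all sampled cells.  The
#' per-type ground-truth GEP columns are the per-type raw-count means, so in
#' count space `b_counts == G_counts %*% p_target` exactly; `b_input` and the
#' `G_target` columns are those quantities passed through
#' [normalize_log_cpm()].  Types absent from a sample have zero `p_target`,
#' a zero `G_target` column and a `FALSE` entry in `type_mask`.
#'
#' When a reference carries condition labels, each sample is assigned one
#' condition (uniformly at random) and draws its cells from that condition
#' only, emulating cohorts profiled under distinct biological conditions.
#'
#' @param refs a `reference_dataset` or a list of them (shared gene space).
#' @param split which split tag to draw cells from (`"train"`, `"val"`,
#'   `"test"`).
#' @param config a [simulation_config()].
#' @return a `pseudobulk_set`: matrices `b_counts`, `b_input` (genes x
#'   samples), `p_drawn`, `p_target`, `type_mask` (types x samples), arrays
#'   `G_counts`, `G_target` (genes x types x samples), `source` and
#'   `condition` per sample, `cell_types`, `gene_ids`, `split`.
#' @export
simulate_pseudobulk <- function(refs, split = "train",
                                config = simulation_config()) {
  if (inherits(refs, "reference_dataset")) refs <- list(refs)
  stopifnot(length(refs) >= 1L,
            all(vapply(refs, inherits, logical(1), "reference_dataset")))
  gene_ids <- refs[[1]]$gene_ids
  for (r in refs) {
    if (!identical(r$gene_ids, gene_ids)) {
      abort("all references must share an identical ordered gene space.")
    }
  }
  cell_types <- sort(unique(unlist(lapply(refs, function(r) unique(r$cell_type)))))
  c_n <- length(cell_types)
  g <- length(gene_ids)
  n <- config$n_samples

  # per-source pools of cell row indices, restricted to the requested split
  pool_of <- function(ref) {
    keep <- ref$split == split
    lapply(setNames(cell_types, cell_types), function(ct) {
      which(keep & ref$cell_type == ct)
    })
  }
  pools <- lapply(refs, pool_of)
  for (ct in cell_types) {
    if (all(vapply(pools, function(p) length(p[[ct]]) == 0L, logical(1)))) {
      abort(sprintf("cell type '%s' absent from split '%s' in all references.",
                    ct, split))
    }
  }
  conditions <- unique(unlist(lapply(refs, function(r) unique(r$condition))))

  set.seed(config$seed)
  # deterministic source allocation: round(n * fraction) mixed samples
  n_mixed <- if (length(refs) > 1L) round(n * config$mixed_reference_fraction) else 0L
  src_names <- vapply(seq_along(refs), function(i) refs[[i]]$name %||% paste0("ref", i),
                      character(1))
  source <- c(rep("mixed", n_mixed),
              rep(src_names, length.out = n - n_mixed))
  cond_of_sample <- if (length(conditions) > 0) {
    sample(conditions, n, replace = TRUE)
  } else rep(NA_character_, n)

  p_drawn <- t(sample_proportions(c_n, config, n, set_seed = FALSE))  # c x n
  b_counts <- matrix(0, g, n, dimnames = list(gene_ids, NULL))
  p_target <- matrix(0, c_n, n, dimnames = list(cell_types, NULL))
  type_mask <- matrix(FALSE, c_n, n, dimnames = list(cell_types, NULL))
  G_counts <- array(0, c(g, c_n, n), dimnames = list(gene_ids, cell_types, NULL))
  G_target <- array(0, c(g, c_n, n), dimnames = list(gene_ids, cell_types, NULL))
  b_input <- matrix(0, g, n, dimnames = list(gene_ids, NULL))

  for (s in seq_len(n)) {
    m <- drop(rmultinom(1, config$cells_per_sample, p_drawn[, s]))
    use_refs <- if (source[s] == "mixed") seq_along(refs) else
      which(src_names == source[s])
    total <- numeric(g)
    for (k in seq_len(c_n)) {
      if (m[k] == 0L) next
      cand <- do.call(rbind, lapply(use_refs, function(i) {
        idx <- pools[[i]][[cell_types[k]]]
        if (!is.na(cond_of_sample[s]) && !is.null(refs[[i]]$condition)) {
          idx <- idx[refs[[i]]$condition[idx] == cond_of_sample[s]]
        }
        cbind(i, idx)
      }))
      if (nrow(cand) == 0L) {
        abort(sprintf(
          "no cells of type '%s' available in split '%s' for source '%s'.",
          cell_types[k], split, source[s]
        ))
      }
      pick <- cand[sample.int(nrow(cand), m[k], replace = TRUE), , drop = FALSE]
      sums <- numeric(g)
      for (i in unique(pick[, 1])) {
        rows <- pick[pick[, 1] == i, 2]
        sums <- sums + colSums(refs[[i]]$counts[rows, , drop = FALSE])
      }
      G_counts[, k, s] <- sums / m[k]
      total <- total + sums
      type_mask[k, s] <- TRUE
    }
    if (sum(total) <= 0) {
      abort(sprintf("sample %d has zero total counts.", s))
    }
    b_counts[, s] <- total / config$cells_per_sample
    p_target[, s] <- m / config$cells_per_sample
    b_input[, s] <- normalize_log_cpm(b_counts[, s])
    for (k in which(type_mask[, s])) {
      if (sum(G_counts[, k, s]) > 0) {
        G_target[, k, s] <- normalize_log_cpm(G_counts[, k, s])
      }
    }
  }

  structure(
    list(
      b_counts = b_counts, b_input = b_input,
      p_drawn = p_drawn, p_target = p_target, type_mask = type_mask,
      G_counts = G_counts, G_target = G_target,
      source = source, condition = cond_of_sample,
      cell_types = cell_types, gene_ids = gene_ids,
      split = split, config = config
    ),
    class = "pseudobulk_set"
  )
}

#' @export
print.pseudobulk_set <- function(x, ...) {
  cat(sprintf(
    "<pseudobulk_set> %d samples x %d genes; %d cell types; split '%s'\n",
    ncol(x$b_input), nrow(x$b_input), length(x$cell_types), x$split
  ))
  invisible(x)
}

#' Restrict a pseudobulk set to an ordered gene list
#'
#' Subsets (and reorders) the gene dimension of every gene-indexed component;
#' used to align simulated samples with the model's training gene list.
#' Normalization is not recomputed: the library-size factors of the full
#' transcriptome are retained, matching how a real bulk sample would be
#' normalized before gene selection.
#'
#' @param pb a `pseudobulk_set`.
#' @param genes character vector of gene identifiers (subset of
#'   `pb$gene_ids`).
#' @return the restricted `pseudobulk_set`.
#' @export
subset_genes <- function(pb, genes) {
  stopifnot(inherits(pb, "pseudobulk_set"))
  idx <- match(genes, pb$gene_ids)
  if (anyNA(idx)) {
    abort(sprintf("%d requested genes are absent from the pseudobulk set.",
                  sum(is.na(idx))))
  }
  pb$b_counts <- pb$b_counts[idx, , drop = FALSE]
  pb$b_input <- pb$b_input[idx, , drop = FALSE]
  pb$G_counts <- pb$G_counts[idx, , , drop = FALSE]
  pb$G_target <- pb$G_target[idx, , , drop = FALSE]
  pb$gene_ids <- pb$gene_ids[idx]
  pb
}
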