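#' One-vs-rest Wilcoxon rank-sum statistics for every gene
#'
#' Tie-corrected normal approximation of the two-sided rank-sum test,
#' vectorised over genes.  Internal engine for [select_degs()].
#'
#' @param expr cells x genes numeric matrix (normalized log values).
#' @param in_group logical vector flagging the cells of the tested type.
#' @return list with vectors `p` and `logfc` (mean in-group minus mean
#'   out-group, in the log space of `expr`).
#' @keywords internal
rank_sum_one_vs_rest <- function(expr, in_group, ranks = NULL,
                                 tie_term = NULL) {
  n <- nrow(expr)
  n1 <- sum(in_group)
  n2 <- n - n1
  stopifnot(n1 >= 1L, n2 >= 1L)
  if (is.null(ranks)) ranks <- apply(expr, 2, rank)
  w <- colSums(ranks[in_group, , drop = FALSE])
  u <- w - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  # tie correction: sum over tied groups of (t^3 - t) per gene
  if (is.null(tie_term)) {
    tie_term <- apply(expr, 2, function(col) {
      t_j <- tabulate(match(col, unique(col)))
      sum(t_j^3 - t_j)
    })
  }
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
  z <- ifelse(sigma2 > 0, (u - mu) / sqrt(sigma2), 0)
  p <- ifelse(sigma2 > 0, 2 * pnorm(-abs(z)), 1)
  logfc <- colMeans(expr[in_group, , drop = FALSE]) -
    colMeans(expr[!in_group, , drop = FALSE])
  list(p = p, logfc = logfc)
}

#' Select cell-type marker genes by one-vs-rest differential expression
#'
#' For every cell type in each reference, genes are tested one cell type
#' versus all others with a Wilcoxon rank-sum test on per-cell
#' log2-CPM expression; p-values are Benjamini-Hochberg adjusted within each
#' cell type's family of tests; genes with adjusted p below `p_cutoff` and a
#' positive log fold change are ranked by log fold change (descending, ties
#' broken by gene identifier) and the top `top_n` kept.  The returned gene
#' list is the union over cell types (and references) with per-gene
#' provenance.
#'
#' @param refs a `reference_dataset` or a list of them.
#' @param top_n genes kept per cell type after ranking (default `Inf` =
#'   all passing genes).
#' @param p_cutoff adjusted p-value threshold (default 0.1).
#' @param split optional split tag; when given, only cells with that tag are
#'   used (e.g. `"train"` to keep selection blind to held-out cells).
#' @return a `gene_list`: ordered unique `genes` plus a `table` tibble of
#'   per-(reference, cell type) selections with `logfc`, `p`, `p_adj`.
#' @export
select_degs <- function(refs, top_n = Inf, p_cutoff = 0.1, split = NULL) {
  if (inherits(refs, "reference_dataset")) refs <- list(refs)
  rows <- list()
  for (ref in refs) {
    keep <- if (is.null(split)) rep(TRUE, nrow(ref$counts)) else ref$split == split
    counts <- ref$counts[keep, , drop = FALSE]
    types <- ref$cell_type[keep]
    if (length(unique(types)) < 2L) {
      abort("need at least two cell types for one-vs-rest selection.")
    }
    lib <- rowSums(counts)
    if (any(lib == 0)) abort("reference contains cells with zero counts.")
    expr <- log2(1e6 * counts / lib + 1)
    ranks <- apply(expr, 2, rank)
    tie_term <- apply(expr, 2, function(col) {
      t_j <- tabulate(match(col, unique(col)))
      sum(t_j^3 - t_j)
    })
    for (ct in sort(unique(types))) {
      in_group <- types == ct
      if (sum(in_group) < 2L) {
        warn(sprintf("cell type '%s' has fewer than 2 cells; skipped.", ct))
        next
      }
      rs <- rank_sum_one_vs_rest(expr, in_group, ranks, tie_term)
      p_adj <- p.adjust(rs$p, method = "BH")
      pass <- which(p_adj < p_cutoff & rs$logfc > 0)
      if (length(pass) == 0L) next
      ord <- pass[order(-rs$logfc[pass], ref$gene_ids[pass])]
      ord <- head(ord, top_n)
      rows[[length(rows) + 1L]] <- tibble(
        gene = ref$gene_ids[ord],
        reference = ref$name,
        cell_type = ct,
        logfc = rs$logfc[ord],
        p = rs$p[ord],
        p_adj = p_adj[ord],
        rank = seq_along(ord)
      )
    }
  }
  table <- dplyr::bind_rows(rows)
  if (nrow(table) == 0L) abort("no genes passed the selection thresholds.")
  structure(
    list(genes = unique(table$gene), table = table),
    class = "gene_list"
  )
}

#' @export
print.gene_list <- function(x, ...) {
  cat(sprintf("<gene_list> %d unique genes from %d (reference, cell type) lists\n",
              length(x$genes), nrow(dplyr::distinct(x$table,
                .data$reference, .data$cell_type))))
  invisible(x)
}

#' Intersect a gene list with the genes available in a bulk matrix
#'
#' Keeps the gene-list order; errors on an empty intersection.  The
#' resulting order is what fixes the model's input/output columns.
#'
#' @param gene_list a `gene_list` (or character vector).
#' @param bulk_genes character vector of available identifiers.
#' @return the restricted `gene_list`.
#' @export
intersect_with_bulk <- function(gene_list, bulk_genes) {
  genes <- if (inherits(gene_list, "gene_list")) gene_list$genes else
    as.character(gene_list)
  keep <- genes[genes %in% bulk_genes]
  if (length(keep) == 0L) {
    abort("no genes shared between the gene list and the bulk matrix.")
  }
  if (inherits(gene_list, "gene_list")) {
    gene_list$genes <- keep
    gene_list$table <- dplyr::filter(gene_list$table, .data$gene %in% keep)
    gene_list
  } else {
    structure(list(genes = keep, table = tibble(gene = keep)),
              class = "gene_list")
  }
}
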