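# Readers and writers for the interchange formats: MTX + delimited
# metadata for single-cell references, delimited genes x samples tables for
# bulk expression, delimited survival tables, and the deconvolution output
# directory layout.

#' Write / read a single-cell reference as MTX plus metadata
#'
#' The on-disk layout follows the CellRanger-style triplet: `matrix.mtx`
#' (genes x cells, sparse), `genes.tsv` (one identifier per line) and
#' `cells.tsv` (tab-separated: `cell_id`, `cell_type`, optional `condition`,
#' `split`).
#'
#' @param ref a `reference_dataset`.
#' @param dir output directory (created if missing).
#' @return `write_reference` returns `dir` invisibly; `read_reference`
#'   returns a validated `reference_dataset`.
#' @export
write_reference <- function(ref, dir) {
  stopifnot(inherits(ref, "reference_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(t(ref$counts), sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(ref$gene_ids, file.path(dir, "genes.tsv"))
  meta <- data.frame(
    cell_id = rownames(ref$counts) %||% sprintf("cell%05d", nrow(ref$counts)),
    cell_type = ref$cell_type,
    split = ref$split,
    stringsAsFactors = FALSE
  )
  if (!is.null(ref$condition)) meta$condition <- ref$condition
  utils::write.table(meta, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_reference
#' @param name reference name recorded in provenance.
#' @param cell_type_col name of the cell-type column in `cells.tsv`.
#' @export
read_reference <- function(dir, name = basename(dir),
                           cell_type_col = "cell_type") {
  mtx_path <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx_path)) abort(sprintf("no matrix.mtx under '%s'.", dir))
  M <- Matrix::readMM(mtx_path)
  gene_ids <- readLines(file.path(dir, "genes.tsv"))
  meta <- utils::read.delim(file.path(dir, "cells.tsv"),
                            stringsAsFactors = FALSE)
  if (anyDuplicated(gene_ids)) {
    dup <- gene_ids[duplicated(gene_ids)][1]
    abort(sprintf("duplicate gene identifier '%s' in genes.tsv.", dup))
  }
  if (!cell_type_col %in% names(meta)) {
    abort(sprintf("cells.tsv lacks the cell-type column '%s'.", cell_type_col))
  }
  if (nrow(meta) != ncol(M) || length(gene_ids) != nrow(M)) {
    abort(sprintf(
      "dimension mismatch: matrix is %d genes x %d cells, metadata has %d genes / %d cells.",
      nrow(M), ncol(M), length(gene_ids), nrow(meta)
    ))
  }
  counts <- as.matrix(Matrix::t(M))
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("reference counts must be non-negative integers.")
  }
  storage.mode(counts) <- "integer"
  rownames(counts) <- meta$cell_id
  colnames(counts) <- gene_ids
  new_reference_dataset(
    counts,
    cell_type = meta[[cell_type_col]],
    condition = meta$condition,
    split = meta$split %||% rep("train", nrow(meta)),
    gene_ids = gene_ids,
    name = name
  )
}

#' Write / read a bulk expression matrix as delimited text
#'
#' Genes in rows (first column `gene`), one column per sample.
#'
#' @param bulk genes x samples numeric matrix with rownames and colnames.
#' @param path file path.
#' @param normalize apply [normalize_log_cpm()] per sample after reading
#'   (for raw-count inputs).
#' @return `write_bulk` returns `path` invisibly; `read_bulk` the matrix.
#' @export
write_bulk <- function(bulk, path) {
  df <- data.frame(gene = rownames(bulk), bulk, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bulk
#' @export
read_bulk <- function(path, normalize = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene") abort("first column of a bulk table must be 'gene'.")
  samples <- names(df)[-1]
  if (anyDuplicated(samples)) {
    abort(sprintf("duplicate sample id '%s' in bulk table.",
                  samples[duplicated(samples)][1]))
  }
  if (anyDuplicated(df$gene)) {
    abort(sprintf("duplicate gene id '%s' in bulk table.",
                  df$gene[duplicated(df$gene)][1]))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  if (normalize) m <- apply(m, 2, normalize_log_cpm)
  m
}

#' Write / read a survival table as delimited text
#'
#' Columns `patient_id`, `time`, `event` (and any extras).
#'
#' @param survival_table a tibble/data.frame.
#' @param path file path.
#' @return the path (writer, invisibly) or a tibble (reader).
#' @export
write_survival <- function(survival_table, path) {
  utils::write.table(survival_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_survival
#' @export
read_survival <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "time", "event")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(sprintf("survival table lacks column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(df$patient_id)) abort("duplicate patient ids.")
  if (any(df$time < 0)) abort("negative survival times.")
  if (!all(df$event %in% c(0L, 1L))) abort("event must be 0/1.")
  as_tibble(df)
}

#' Write deconvolution results to a directory
#'
#' `proportions.tsv` holds the samples x cell-types proportion table;
#' `gep_<sample>.tsv` holds one genes x cell-types expression table per
#' sample.  Column order is the checkpoint's cell-type order; file naming
#' is stable across runs.
#'
#' @param result a `deconv_result`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_deconvolution <- function(result, dir) {
  stopifnot(inherits(result, "deconv_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pm <- data.frame(sample = rownames(result$proportions_matrix),
                   result$proportions_matrix, check.names = FALSE)
  utils::write.table(pm, file.path(dir, "proportions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (s in seq_len(dim(result$G_hat)[3])) {
    sample_id <- dimnames(result$G_hat)[[3]][s]
    gep <- data.frame(gene = result$gene_ids,
                      result$G_hat[, , s], check.names = FALSE)
    names(gep)[-1] <- result$cell_types
    utils::write.table(
      gep, file.path(dir, sprintf("gep_%s.tsv", sample_id)),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(dir)
}

#' Read back a deconvolution output directory
#'
#' @param dir directory written by [write_deconvolution()].
#' @return a `deconv_result` (without a model reference).
#' @export
read_deconvolution <- function(dir) {
  pm_df <- utils::read.delim(file.path(dir, "proportions.tsv"),
                             check.names = FALSE)
  samples <- pm_df$sample
  pm <- as.matrix(pm_df[, -1, drop = FALSE])
  rownames(pm) <- samples
  types <- colnames(pm)
  geps <- lapply(samples, function(s) {
    df <- utils::read.delim(file.path(dir, sprintf("gep_%s.tsv", s)),
                            check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$gene
    m
  })
  genes <- rownames(geps[[1]])
  G <- array(unlist(geps), c(length(genes), length(types), length(samples)),
             dimnames = list(genes, types, samples))
  structure(
    list(
      proportions = tidyr::pivot_longer(
        dplyr::mutate(as_tibble(pm), sample = samples, .before = 1),
        -"sample", names_to = "cell_type", values_to = "proportion"
      ),
      proportions_matrix = pm, G_hat = G,
      gene_ids = genes, cell_types = types
    ),
    class = "deconv_result"
  )
}
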