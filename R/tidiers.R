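# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @export
tidy.deconv_fit <- function(x, ...) {
  tidyr::pivot_longer(x$history, c("train_loss", "val_loss"),
                      names_to = "set", values_to = "loss") |>
    dplyr::mutate(set = sub("_loss$", "", .data$set))
}

#' @export
glance.deconv_fit <- function(x, ...) {
  tibble(
    n_epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss,
    n_parameters = count_params(x$model),
    lambda_p = x$config$lambda_p,
    lambda_G = x$config$lambda_G,
    learning_rate = x$config$learning_rate
  )
}

#' @export
tidy.deconv_result <- function(x, ...) x$proportions

#' @export
tidy.gene_list <- function(x, ...) x$table

#' @export
tidy.patient_grouping <- function(x, ...) {
  tibble(patient = seq_along(x$group), group = x$group)
}

#' Plot training history
#'
#' @param object a `deconv_fit`.
#' @param ... unused.
#' @return a ggplot of train/validation loss per epoch.
#' @export
autoplot.deconv_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$epoch, y = .data$loss,
                               colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "loss (log scale)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot predicted cell-type proportions
#'
#' @param object a `deconv_result`.
#' @param ... unused.
#' @return a stacked-bar ggplot, one bar per sample.
#' @export
autoplot.deconv_result <- function(object, ...) {
  ggplot2::ggplot(object$proportions,
                  ggplot2::aes(x = .data$sample, y = .data$proportion,
                               fill = .data$cell_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "predicted proportion", fill = "cell type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Scatter plot of predicted vs true proportions
#'
#' @param result a `deconv_result`.
#' @param truth a `pseudobulk_set` with `p_target`.
#' @return a ggplot faceted by cell type, annotated with CCC and L1.
#' @export
plot_proportion_fit <- function(result, truth) {
  p_true <- t(truth$p_target)
  df <- dplyr::bind_rows(lapply(seq_along(result$cell_types), function(k) {
    tibble(cell_type = result$cell_types[k],
           truth = p_true[, k],
           predicted = result$proportions_matrix[, k])
  }))
  lab <- df |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::summarise(
      label = sprintf("CCC %.3f\nL1 %.3f", ccc(.data$truth, .data$predicted),
                      l1_error(.data$truth, .data$predicted)),
      .groups = "drop"
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$truth, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$label),
                       x = -Inf, y = Inf, hjust = -0.1, vjust = 1.2,
                       size = 3, inherit.aes = FALSE) +
    ggplot2::facet_wrap(~cell_type) +
    ggplot2::labs(x = "true proportion", y = "predicted proportion") +
    ggplot2::theme_minimal()
}

#' Write / read a gene list as a delimited file
#'
#' Two columns: `gene` and `provenance` (semicolon-joined
#' `reference:cell_type` tags).
#'
#' @param gene_list a `gene_list`.
#' @param path file path.
#' @return the path (writer, invisibly) or a `gene_list` (reader).
#' @export
write_gene_list <- function(gene_list, path) {
  prov <- gene_list$table |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      provenance = paste(unique(paste0(.data$reference, ":", .data$cell_type)),
                         collapse = ";"),
      .groups = "drop"
    )
  out <- tibble(gene = gene_list$genes) |> dplyr::left_join(prov, by = "gene")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_list
#' @export
read_gene_list <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(list(genes = df$gene, table = as_tibble(df)), class = "gene_list")
}
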