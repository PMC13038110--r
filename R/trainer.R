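#' Training configuration
#'
#' The loss is `lambda_p * MSE(p_hat, p) + lambda_G * MSE(G_hat, G)` where
#' the expression term averages only over cell types present in each sample
#' (the type mask).  The proportion term is up-weighted by default because
#' proportion squared errors (on the simplex) are orders of magnitude
#' smaller than squared errors in log2 expression space.
#'
#' @param lambda_p,lambda_G non-negative loss weights (defaults 100 and 1);
#'   their sum must be positive.
#' @param learning_rate Adam learning rate.
#' @param lr_decay multiplicative decay applied to the learning rate at
#'   `lr_decay_epoch` (1 = constant rate); a late decay lets the expression
#'   head settle fine per-gene structure below the constant-rate noise
#'   floor.
#' @param lr_decay_epoch epoch at which the decay is applied.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping.
#' @param seed integer seed controlling shuffling.
#' @return a `train_config` object.
#' @export
train_config <- function(lambda_p = 100, lambda_G = 1,
                         learning_rate = 1e-3, lr_decay = 0.1,
                         lr_decay_epoch = 30L, batch_size = 64L,
                         max_epochs = 40L, early_stop_patience = 8L,
                         seed = 1L) {
  if (lambda_p < 0 || lambda_G < 0 || lambda_p + lambda_G <= 0) {
    abort("loss weights must be non-negative with a positive sum.")
  }
  if (learning_rate < 0) abort("`learning_rate` must be non-negative.")
  structure(
    list(lambda_p = lambda_p, lambda_G = lambda_G,
         learning_rate = learning_rate, lr_decay = lr_decay,
         lr_decay_epoch = as.integer(lr_decay_epoch),
         batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs),
         early_stop_patience = as.integer(early_stop_patience),
         seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Weighted two-term MSE loss
#'
#' `lambda_p * mean((p_hat - p)^2) + lambda_G * mean((G_hat - G)^2)` where
#' the second mean runs over the entries of cell-type columns flagged
#' present by `mask`; with an all-`FALSE` mask the expression term is 0.
#'
#' @param p_hat,p samples x types proportion matrices.
#' @param G_hat,G genes x types x samples expression arrays.
#' @param mask types x samples logical matrix of present types.
#' @param lambda_p,lambda_G loss weights.
#' @return scalar loss (and gradient components as attributes via
#'   [deconv_loss_grad()]).
#' @export
deconv_loss <- function(p_hat, p, G_hat, G, mask,
                        lambda_p = 100, lambda_G = 1) {
  stopifnot(all(dim(p_hat) == dim(p)), all(dim(G_hat) == dim(G)))
  lp <- mean((p_hat - p)^2)
  g <- dim(G)[1]
  mask_exp <- array(rep(mask, each = g), dim(G))
  n_mask <- sum(mask) * g
  lg <- if (n_mask > 0) sum(((G_hat - G)^2)[mask_exp]) / n_mask else 0
  lambda_p * lp + lambda_G * lg
}

deconv_loss_grad <- function(p_hat, p, G_hat, G, mask,
                             lambda_p = 100, lambda_G = 1) {
  g <- dim(G)[1]
  dP <- 2 * lambda_p * (p_hat - p) / length(p)
  n_mask <- sum(mask) * g
  mask_exp <- array(rep(mask, each = g), dim(G))
  dG <- if (n_mask > 0) 2 * lambda_G * (G_hat - G) * mask_exp / n_mask else
    array(0, dim(G))
  list(dP = dP, dG = dG)
}

pb_tensors <- function(pb) {
  list(
    X = t(pb$b_input),              # n x g
    P = t(pb$p_target),             # n x c
    G = pb$G_target,                # g x c x n
    mask = pb$type_mask             # c x n
  )
}

#' Train the dual-branch model on pseudobulk sets
#'
#' Joint end-to-end Adam optimisation of both branches with the weighted
#' two-term MSE loss; per-epoch train/validation losses are logged, the
#' best-validation parameters are retained, and training stops early when
#' validation loss has not improved for `early_stop_patience` epochs.
#'
#' @param model a `deconv_model` (see [build_model()]).
#' @param train_pb,val_pb `pseudobulk_set`s built from disjoint cell splits
#'   and restricted to the model's gene list ([subset_genes()]).
#' @param config a [train_config()].
#' @param verbose print per-epoch losses.
#' @return a `deconv_fit`: the trained model (best-validation parameters)
#'   and a `history` tibble (epoch, train_loss, val_loss, best flag).
#' @export
train_deconvolution <- function(model, train_pb, val_pb,
                                config = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "deconv_model"),
            inherits(train_pb, "pseudobulk_set"),
            inherits(val_pb, "pseudobulk_set"))
  if (!identical(train_pb$gene_ids, val_pb$gene_ids)) {
    abort("train and validation sets must share the gene space.")
  }
  if (length(train_pb$gene_ids) != model$config$n_genes) {
    abort(sprintf("model expects %d genes but pseudobulk has %d.",
                  model$config$n_genes, length(train_pb$gene_ids)))
  }
  tr <- pb_tensors(train_pb)
  va <- pb_tensors(val_pb)
  n <- nrow(tr$X)
  model <- fit_scaler(model, tr$X)
  if (all(model$params$proj.b == 0)) {
    # start the expression head at the per-type mean target profile so
    # optimisation spends its budget on per-sample deviations, not offsets
    for (k in seq_len(dim(tr$G)[2])) {
      present <- which(tr$mask[k, ])
      if (length(present) > 0) {
        model$params$proj.b[, k] <-
          rowMeans(tr$G[, k, present, drop = FALSE], dims = 1L)
      }
    }
  }
  set.seed(config$seed)
  opt <- adam_init(model$params)
  best <- list(loss = Inf, params = model$params, state = model$state,
               epoch = 0L)
  history <- vector("list", config$max_epochs)
  stall <- 0L

  eval_loss <- function(m, te) {
    bs <- 256L
    tot <- 0
    for (start in seq(1L, nrow(te$X), by = bs)) {
      idx <- start:min(start + bs - 1L, nrow(te$X))
      out <- model_forward(m, te$X[idx, , drop = FALSE], training = FALSE)
      tot <- tot + length(idx) * deconv_loss(
        out$p_hat, te$P[idx, , drop = FALSE], out$G_hat,
        te$G[, , idx, drop = FALSE], te$mask[, idx, drop = FALSE],
        config$lambda_p, config$lambda_G
      )
    }
    tot / nrow(te$X)
  }

  for (epoch in seq_len(config$max_epochs)) {
    lr <- config$learning_rate *
      if (epoch >= config$lr_decay_epoch) config$lr_decay else 1
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      Xb <- tr$X[idx, , drop = FALSE]
      Pb <- tr$P[idx, , drop = FALSE]
      Gb <- tr$G[, , idx, drop = FALSE]
      mb <- tr$mask[, idx, drop = FALSE]
      out <- model_forward(model, Xb, training = TRUE)
      model$state <- out$state
      l <- deconv_loss(out$p_hat, Pb, out$G_hat, Gb, mb,
                       config$lambda_p, config$lambda_G)
      if (!is.finite(l)) {
        abort(sprintf(
          "training diverged: non-finite loss at epoch %d (batch starting %d). Try a lower learning rate.",
          epoch, start
        ))
      }
      ep_loss <- ep_loss + l * length(idx)
      gr <- deconv_loss_grad(out$p_hat, Pb, out$G_hat, Gb, mb,
                             config$lambda_p, config$lambda_G)
      grads <- model_backward(model, out$cache, gr$dP, gr$dG)
      upd <- adam_step(model$params, grads, opt, lr)
      model$params <- upd$params
      opt <- upd$st
    }
    ep_loss <- ep_loss / n
    val_loss <- eval_loss(model, va)
    is_best <- val_loss < best$loss
    if (is_best) {
      best <- list(loss = val_loss, params = model$params,
                   state = model$state, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    history[[epoch]] <- tibble(epoch = epoch, train_loss = ep_loss,
                               val_loss = val_loss, best = is_best)
    if (verbose) {
      inform(sprintf("epoch %3d  train %.5f  val %.5f%s",
                     epoch, ep_loss, val_loss, if (is_best) " *" else ""))
    }
    if (stall >= config$early_stop_patience) break
  }
  model$params <- best$params
  model$state <- best$state
  structure(
    list(model = model, history = dplyr::bind_rows(history),
         best_epoch = best$epoch, best_val_loss = best$loss,
         config = config),
    class = "deconv_fit"
  )
}

#' @export
print.deconv_fit <- function(x, ...) {
  cat(sprintf("<deconv_fit> %d epochs; best validation loss %.5f at epoch %d\n",
              nrow(x$history), x$best_val_loss, x$best_epoch))
  invisible(x)
}
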