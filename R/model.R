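#' Configuration of the dual-branch deconvolution network
#'
#' The network consumes a length-`n_genes` bulk expression vector and shares
#' one linear feature-extraction layer of width `feature_dim` between two
#' heads: a multilayer perceptron (widths `mlp_dims` then `n_types`, SiLU
#' between linear layers, terminal softmax) predicting cell-type
#' proportions, and a 1D U-Net predicting the genes-by-types expression
#' matrix.  The U-Net views the shared features as a one-channel sequence,
#' lifts it to `base_channels` with a stem convolution, applies `unet_depth`
#' down blocks (max pool, then twice conv + batch norm + ReLU; each block
#' doubles the channels and halves the length) and `unet_depth` up blocks
#' (transposed convolution halving channels and doubling length, skip
#' concatenation from the matching down stage, then the same two conv
#' rounds), maps to `n_types` channels with a 1x1 head convolution, and
#' projects each channel from length `feature_dim` to `n_genes` with a
#' shared linear map followed by ReLU.
#'
#' @param n_genes number of input/output genes.
#' @param n_types number of cell types.
#' @param feature_dim width of the shared linear layer; must be divisible by
#'   `2^unet_depth`.
#' @param mlp_dims hidden widths of the proportion head (the terminal
#'   `n_types` layer is appended automatically).
#' @param unet_depth number of down/up sampling blocks.
#' @param base_channels channels after the stem convolution.
#' @param kernel_size odd convolution kernel size.
#' @param proportion_activation `"softmax"` (simplex output) or `"identity"`.
#' @param gep_activation `"relu"` (non-negative output) or `"identity"`.
#' @param seed integer seed for parameter initialisation.
#' @return a `model_config` object.
#' @export
model_config <- function(n_genes, n_types,
                         feature_dim = 4096L,
                         mlp_dims = c(4096L, 1024L, 256L, 64L),
                         unet_depth = 4L,
                         base_channels = 8L,
                         kernel_size = 3L,
                         proportion_activation = c("softmax", "identity"),
                         gep_activation = c("relu", "identity"),
                         seed = 1L) {
  proportion_activation <- match.arg(proportion_activation)
  gep_activation <- match.arg(gep_activation)
  cfg <- list(
    n_genes = as.integer(n_genes), n_types = as.integer(n_types),
    feature_dim = as.integer(feature_dim),
    mlp_dims = as.integer(mlp_dims),
    unet_depth = as.integer(unet_depth),
    base_channels = as.integer(base_channels),
    kernel_size = as.integer(kernel_size),
    proportion_activation = proportion_activation,
    gep_activation = gep_activation,
    seed = as.integer(seed)
  )
  if (cfg$n_genes < 1L || cfg$n_types < 1L) abort("invalid dimensions.")
  if (cfg$kernel_size %% 2L != 1L) abort("`kernel_size` must be odd.")
  if (cfg$feature_dim %% 2L^cfg$unet_depth != 0L) {
    abort(sprintf("`feature_dim` (%d) must be divisible by 2^unet_depth (%d).",
                  cfg$feature_dim, 2L^cfg$unet_depth))
  }
  structure(cfg, class = "model_config")
}

#' Build the dual-branch deconvolution model
#'
#' Initialises all parameters reproducibly from `config$seed` (He-scaled
#' normal weights, zero biases, unit batch-norm scales).
#'
#' @param config a [model_config()].
#' @param gene_ids,cell_types optional identifier vectors recorded in the
#'   model; `cell_types` fixes the column semantics of the predicted
#'   expression matrix.
#' @return a `deconv_model`: flat parameter list, batch-norm running state,
#'   the config, and the recorded identifiers.
#' @export
build_model <- function(config, gene_ids = NULL, cell_types = NULL) {
  stopifnot(inherits(config, "model_config"))
  if (!is.null(gene_ids) && length(gene_ids) != config$n_genes) {
    abort("`gene_ids` length must equal `n_genes`.")
  }
  if (!is.null(cell_types) && length(cell_types) != config$n_types) {
    abort("`cell_types` length must equal `n_types`.")
  }
  set.seed(config$seed)
  g <- config$n_genes; cc <- config$n_types
  Fd <- config$feature_dim; k <- config$kernel_size
  base <- config$base_channels; depth <- config$unet_depth

  params <- list()
  state <- list()
  add_lin <- function(nm, n_in, n_out) {
    l <- init_linear(n_in, n_out)
    params[[paste0(nm, ".W")]] <<- l$W
    params[[paste0(nm, ".b")]] <<- l$b
  }
  add_conv <- function(nm, c_out, c_in, kk) {
    l <- init_conv(c_out, c_in, kk)
    params[[paste0(nm, ".W")]] <<- l$W
    params[[paste0(nm, ".b")]] <<- l$b
  }
  add_bn <- function(nm, ch) {
    l <- init_bn(ch)
    params[[paste0(nm, ".gamma")]] <<- l$gamma
    params[[paste0(nm, ".beta")]] <<- l$beta
    state[[paste0(nm, ".mean")]] <<- numeric(ch)
    state[[paste0(nm, ".var")]] <<- rep(1, ch)
  }

  add_lin("shared", g, Fd)
  dims <- c(Fd, config$mlp_dims, cc)
  for (i in seq_len(length(dims) - 1L)) {
    add_lin(paste0("mlp", i), dims[i], dims[i + 1L])
  }
  # start the proportion head near the uniform simplex: tiny terminal
  # weights keep the softmax out of its saturated (zero-gradient) regime
  last <- sprintf("mlp%d.W", length(dims) - 1L)
  params[[last]] <- params[[last]] * 0.01
  add_conv("stem", base, 1L, k)
  ch <- base
  for (i in seq_len(depth)) {
    add_conv(sprintf("down%d.conv1", i), 2L * ch, ch, k)
    add_bn(sprintf("down%d.bn1", i), 2L * ch)
    add_conv(sprintf("down%d.conv2", i), 2L * ch, 2L * ch, k)
    add_bn(sprintf("down%d.bn2", i), 2L * ch)
    ch <- 2L * ch
  }
  for (i in seq_len(depth)) {
    add_conv(sprintf("up%d.tconv", i), ch %/% 2L, ch, 2L)
    add_conv(sprintf("up%d.conv1", i), ch %/% 2L, ch, k)
    add_bn(sprintf("up%d.bn1", i), ch %/% 2L)
    add_conv(sprintf("up%d.conv2", i), ch %/% 2L, ch %/% 2L, k)
    add_bn(sprintf("up%d.bn2", i), ch %/% 2L)
    ch <- ch %/% 2L
  }
  add_conv("head", cc, base, 1L)
  # per-channel projection: each cell type's channel gets its own linear
  # map from sequence space to gene space
  params$proj.W <- array(rnorm(Fd * g * cc, sd = sqrt(2 / Fd)), c(Fd, g, cc))
  params$proj.b <- matrix(0, g, cc)

  structure(
    list(params = params, state = state, config = config,
         gene_ids = gene_ids, cell_types = cell_types,
         scaler = list(mu = numeric(g), sd = rep(1, g))),
    class = "deconv_model"
  )
}

#' Fit the model's per-gene input standardization
#'
#' Stores per-gene mean and standard deviation (computed on the training
#' inputs) in the model; [model_forward()] standardizes every input with
#' them, which keeps the network's activations in a trainable range.
#' Called automatically by [train_deconvolution()].
#'
#' @param model a `deconv_model`.
#' @param X training samples x genes matrix.
#' @return the model with its `scaler` set.
#' @export
fit_scaler <- function(model, X) {
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  s[s < 1e-8] <- 1
  model$scaler <- list(mu = mu, sd = s)
  model
}

#' @export
print.deconv_model <- function(x, ...) {
  cat(sprintf(
    "<deconv_model> %d genes -> %d cell types; feature_dim %d, depth %d; %s parameters\n",
    x$config$n_genes, x$config$n_types, x$config$feature_dim,
    x$config$unet_depth, format(count_params(x), big.mark = ",")
  ))
  invisible(x)
}

#' Number of trainable parameters of a model
#' @param model a `deconv_model`.
#' @return integer count.
#' @export
count_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

bn_pack <- function(p, s, nm) {
  list(gamma = p[[paste0(nm, ".gamma")]], beta = p[[paste0(nm, ".beta")]],
       mean = s[[paste0(nm, ".mean")]], var = s[[paste0(nm, ".var")]])
}

#' Forward pass of the dual-branch network
#'
#' @param model a `deconv_model`.
#' @param X batch matrix, samples x genes, in normalized log2 space.
#' @param training logical; training mode uses batch statistics in the
#'   normalization layers (and updates their running state in the returned
#'   cache), inference mode uses running statistics so each sample's output
#'   is independent of the rest of the batch.
#' @return list with `p_hat` (samples x types), `G_hat` (genes x types x
#'   samples) and, when `training`, a `cache` for [model_backward()] plus
#'   updated running `state`.
#' @export
model_forward <- function(model, X, training = FALSE) {
  cfg <- model$config
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != cfg$n_genes) {
    abort(sprintf("gene-dimension mismatch: model expects %d genes, received %d.",
                  cfg$n_genes, ncol(X)))
  }
  p <- model$params
  s <- model$state
  B <- nrow(X)
  cache <- list()

  X <- t((t(X) - model$scaler$mu) / model$scaler$sd)
  sh <- nn_linear_fwd(X, p$shared.W, p$shared.b)
  cache$shared <- sh
  feats <- sh$Y                                    # B x Fd

  # proportion head -----------------------------------------------------
  n_mlp <- length(cfg$mlp_dims) + 1L
  H <- feats
  cache$mlp <- vector("list", n_mlp)
  for (i in seq_len(n_mlp)) {
    li <- nn_linear_fwd(H, p[[sprintf("mlp%d.W", i)]], p[[sprintf("mlp%d.b", i)]])
    if (i < n_mlp) {
      si <- nn_silu_fwd(li$Y)
      H <- si$Y
      cache$mlp[[i]] <- list(lin = li, act = si)
    } else {
      H <- li$Y
      cache$mlp[[i]] <- list(lin = li)
    }
  }
  p_hat <- if (cfg$proportion_activation == "softmax") nn_softmax_fwd(H) else H

  # GEP head -------------------------------------------------------------
  Xseq <- array(t(feats), c(1L, cfg$feature_dim, B))
  st <- nn_conv1d_fwd(Xseq, p$stem.W, p$stem.b)
  cache$stem <- st
  skips <- list(st$Y)
  H3 <- st$Y
  bn_updates <- list()
  run_block <- function(H3, conv_nm, bn_nm) {
    cv <- nn_conv1d_fwd(H3, p[[paste0(conv_nm, ".W")]], p[[paste0(conv_nm, ".b")]])
    bnp <- bn_pack(p, s, bn_nm)
    bn <- nn_bn_fwd(cv$Y, bnp$gamma, bnp$beta, bnp$mean, bnp$var, training)
    if (training) {
      bn_updates[[paste0(bn_nm, ".mean")]] <<- bn$run_mean
      bn_updates[[paste0(bn_nm, ".var")]] <<- bn$run_var
    }
    rl <- nn_relu_fwd(bn$Y)
    list(Y = rl$Y, conv = cv, bn = bn, relu = rl)
  }
  cache$down <- vector("list", cfg$unet_depth)
  for (i in seq_len(cfg$unet_depth)) {
    pl <- nn_maxpool2_fwd(H3)
    b1 <- run_block(pl$Y, sprintf("down%d.conv1", i), sprintf("down%d.bn1", i))
    b2 <- run_block(b1$Y, sprintf("down%d.conv2", i), sprintf("down%d.bn2", i))
    cache$down[[i]] <- list(pool = pl, b1 = b1, b2 = b2)
    H3 <- b2$Y
    if (i < cfg$unet_depth) skips[[i + 1L]] <- H3
  }
  cache$up <- vector("list", cfg$unet_depth)
  for (i in seq_len(cfg$unet_depth)) {
    tc <- nn_tconv2_fwd(H3, p[[sprintf("up%d.tconv.W", i)]],
                        p[[sprintf("up%d.tconv.b", i)]])
    skip <- skips[[cfg$unet_depth - i + 1L]]
    cat_in <- array(0, dim(tc$Y) + c(dim(skip)[1], 0L, 0L))
    n1 <- dim(tc$Y)[1]
    cat_in[seq_len(n1), , ] <- tc$Y
    cat_in[n1 + seq_len(dim(skip)[1]), , ] <- skip
    b1 <- run_block(cat_in, sprintf("up%d.conv1", i), sprintf("up%d.bn1", i))
    b2 <- run_block(b1$Y, sprintf("up%d.conv2", i), sprintf("up%d.bn2", i))
    cache$up[[i]] <- list(tconv = tc, n_tc = n1, b1 = b1, b2 = b2)
    H3 <- b2$Y
  }
  hd <- nn_conv1d_fwd(H3, p$head.W, p$head.b)
  cache$head <- hd
  Hc <- hd$Y                                       # (c, Fd, B)
  G_pre <- array(0, c(cfg$n_genes, cfg$n_types, B))
  Hks <- vector("list", cfg$n_types)
  for (k in seq_len(cfg$n_types)) {
    Hk <- matrix(Hc[k, , ], cfg$feature_dim, B)    # Fd x B
    Hks[[k]] <- Hk
    G_pre[, k, ] <- crossprod(p$proj.W[, , k], Hk) + p$proj.b[, k]
  }
  cache$proj <- list(Hks = Hks)
  if (cfg$gep_activation == "relu") {
    grl <- nn_relu_fwd(G_pre)
    cache$gep_act <- grl
    G_hat <- grl$Y
  } else {
    G_hat <- G_pre
  }
  cache$p_hat <- p_hat
  cache$B <- B

  out <- list(p_hat = p_hat, G_hat = G_hat)
  if (training) {
    out$cache <- cache
    out$state <- modifyList(s, bn_updates)
  }
  out
}

#' Backward pass: gradients of the loss w.r.t. every parameter
#'
#' @param model a `deconv_model`.
#' @param cache the cache returned by [model_forward()] with
#'   `training = TRUE`.
#' @param dP gradient w.r.t. `p_hat` (samples x types).
#' @param dG gradient w.r.t. `G_hat` (genes x types x samples).
#' @return flat named list of gradients matching `model$params`.
#' @export
model_backward <- function(model, cache, dP, dG) {
  cfg <- model$config
  p <- model$params
  B <- cache$B
  grads <- list()

  # GEP head backward ----------------------------------------------------
  if (cfg$gep_activation == "relu") dG <- nn_relu_bwd(dG, cache$gep_act)
  grads$proj.W <- array(0, dim(p$proj.W))
  grads$proj.b <- matrix(0, cfg$n_genes, cfg$n_types)
  dH3 <- array(0, c(cfg$n_types, cfg$feature_dim, B))
  for (k in seq_len(cfg$n_types)) {
    dGk <- matrix(dG[, k, ], cfg$n_genes, B)
    grads$proj.W[, , k] <- tcrossprod(cache$proj$Hks[[k]], dGk)
    grads$proj.b[, k] <- rowSums(dGk)
    dH3[k, , ] <- p$proj.W[, , k] %*% dGk
  }

  hb <- nn_conv1d_bwd(dH3, cache$head$X, p$head.W)
  grads$head.W <- hb$dW; grads$head.b <- hb$db
  dH3 <- hb$dX

  bwd_block <- function(dY, blk, conv_nm, bn_nm) {
    dY <- nn_relu_bwd(dY, blk$relu)
    bb <- nn_bn_bwd(dY, blk$bn)
    grads[[paste0(bn_nm, ".gamma")]] <<- bb$dgamma
    grads[[paste0(bn_nm, ".beta")]] <<- bb$dbeta
    cb <- nn_conv1d_bwd(bb$dX, blk$conv$X, p[[paste0(conv_nm, ".W")]])
    grads[[paste0(conv_nm, ".W")]] <<- cb$dW
    grads[[paste0(conv_nm, ".b")]] <<- cb$db
    cb$dX
  }

  dskips <- vector("list", cfg$unet_depth)
  for (i in rev(seq_len(cfg$unet_depth))) {
    u <- cache$up[[i]]
    dH3 <- bwd_block(dH3, u$b2, sprintf("up%d.conv2", i), sprintf("up%d.bn2", i))
    dH3 <- bwd_block(dH3, u$b1, sprintf("up%d.conv1", i), sprintf("up%d.bn1", i))
    n1 <- u$n_tc
    d_tc <- dH3[seq_len(n1), , , drop = FALSE]
    dskips[[cfg$unet_depth - i + 1L]] <-
      dH3[(n1 + 1L):dim(dH3)[1], , , drop = FALSE]
    tb <- nn_tconv2_bwd(d_tc, u$tconv$X, p[[sprintf("up%d.tconv.W", i)]])
    grads[[sprintf("up%d.tconv.W", i)]] <- tb$dW
    grads[[sprintf("up%d.tconv.b", i)]] <- tb$db
    dH3 <- tb$dX
  }
  for (i in rev(seq_len(cfg$unet_depth))) {
    d <- cache$down[[i]]
    if (i < cfg$unet_depth) {
      # this stage's output also fed a skip connection
      dH3 <- dH3 + dskips[[i + 1L]]
    }
    dH3 <- bwd_block(dH3, d$b2, sprintf("down%d.conv2", i), sprintf("down%d.bn2", i))
    dH3 <- bwd_block(dH3, d$b1, sprintf("down%d.conv1", i), sprintf("down%d.bn1", i))
    dH3 <- nn_maxpool2_bwd(dH3, d$pool)
  }
  dH3 <- dH3 + dskips[[1L]]                        # stem output fed skip 1
  sb <- nn_conv1d_bwd(dH3, cache$stem$X, p$stem.W)
  grads$stem.W <- sb$dW; grads$stem.b <- sb$db
  dXseq <- sb$dX                                    # (1, Fd, B)
  dfeats_unet <- t(matrix(dXseq, cfg$feature_dim, B))

  # proportion head backward --------------------------------------------
  if (cfg$proportion_activation == "softmax") {
    dP <- nn_softmax_bwd(dP, cache$p_hat)
  }
  n_mlp <- length(cfg$mlp_dims) + 1L
  dH <- dP
  for (i in rev(seq_len(n_mlp))) {
    blk <- cache$mlp[[i]]
    if (i < n_mlp) dH <- nn_silu_bwd(dH, blk$act)
    lb <- nn_linear_bwd(dH, blk$lin$X, p[[sprintf("mlp%d.W", i)]])
    grads[[sprintf("mlp%d.W", i)]] <- lb$dW
    grads[[sprintf("mlp%d.b", i)]] <- lb$db
    dH <- lb$dX
  }
  dfeats <- dH + dfeats_unet

  shb <- nn_linear_bwd(dfeats, cache$shared$X, p$shared.W)
  grads$shared.W <- shb$dW
  grads$shared.b <- shb$db
  grads[names(model$params)]
}

#' Deconvolve bulk samples with a trained model
#'
#' Matches the bulk matrix's gene identifiers against the model's training
#' gene list (order-corrected), runs the network in inference mode, and
#' returns per-sample proportions and expression profiles.
#'
#' @param model a trained `deconv_model` with recorded `gene_ids`.
#' @param bulk genes x samples numeric matrix in normalized log2 space
#'   (rownames = gene identifiers), or a matrix already ordered like the
#'   model's gene list when it has no rownames.
#' @param min_gene_overlap minimum fraction of training genes that must be
#'   present in `bulk` (default 0.9); below it matching aborts.
#' @return a `deconv_result`: `proportions` tibble (sample, cell type,
#'   proportion), `proportions_matrix` (samples x types), `G_hat` (genes x
#'   types x samples, missing genes zero-filled), `gene_ids`, `cell_types`.
#' @export
deconvolve <- function(model, bulk, min_gene_overlap = 0.9) {
  stopifnot(inherits(model, "deconv_model"))
  cfg <- model$config
  genes <- model$gene_ids
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(cfg$n_genes))
  if (is.null(rownames(bulk))) {
    if (nrow(bulk) != cfg$n_genes) {
      abort(sprintf("bulk has %d rows but the model expects %d genes (no rownames to match by).",
                    nrow(bulk), cfg$n_genes))
    }
    X <- t(bulk)
  } else {
    idx <- match(genes, rownames(bulk))
    frac <- mean(!is.na(idx))
    if (frac < min_gene_overlap) {
      abort(sprintf("only %.1f%% of the model's %d training genes found in bulk (need >= %.0f%%).",
                    100 * frac, length(genes), 100 * min_gene_overlap))
    }
    X <- matrix(0, ncol(bulk), cfg$n_genes)
    ok <- !is.na(idx)
    X[, ok] <- t(bulk[idx[ok], , drop = FALSE])
  }
  out <- model_forward(model, X, training = FALSE)
  samples <- colnames(bulk) %||% sprintf("sample%d", seq_len(nrow(X)))
  types <- model$cell_types %||% sprintf("type%d", seq_len(cfg$n_types))
  pm <- out$p_hat
  dimnames(pm) <- list(samples, types)
  dimnames(out$G_hat) <- list(genes, types, samples)
  structure(
    list(
      proportions = tidyr::pivot_longer(
        dplyr::mutate(as_tibble(pm), sample = samples, .before = 1),
        -"sample", names_to = "cell_type", values_to = "proportion"
      ),
      proportions_matrix = pm,
      G_hat = out$G_hat,
      gene_ids = genes,
      cell_types = types
    ),
    class = "deconv_result"
  )
}

#' @export
print.deconv_result <- function(x, ...) {
  cat(sprintf("<deconv_result> %d samples; %d cell types; %d genes\n",
              nrow(x$proportions_matrix), length(x$cell_types),
              length(x$gene_ids)))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single file holding the config, all parameters and
#' running statistics, and the gene/cell-type identifier order that defines
#' the output's column semantics.
#'
#' @param model a `deconv_model`.
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "deconv_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "deconv_model")) abort("not a deconv_model checkpoint.")
  model
}
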