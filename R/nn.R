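# Layer primitives for the dual-branch network.
#
# Written directly against BLAS matrix products: sequence tensors are
# arrays of dim (channels, length, batch) so that reshaping to a
# (channels, length*batch) matrix is free, and every convolution becomes a
# small number of dense matrix products (one per kernel offset).  Each
# *_fwd returns the output plus whatever the matching *_bwd needs.

nn_linear_fwd <- function(X, W, b) {
  # X: B x in, W: in x out, b: out
  Y <- X %*% W
  Y <- Y + matrix(b, nrow(Y), length(b), byrow = TRUE)
  list(Y = Y, X = X)
}

nn_linear_bwd <- function(dY, X, W) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

nn_silu_fwd <- function(X) {
  s <- 1 / (1 + exp(-X))
  list(Y = X * s, s = s, X = X)
}

nn_silu_bwd <- function(dY, cache) {
  dY * (cache$s * (1 + cache$X * (1 - cache$s)))
}

nn_relu_fwd <- function(X) {
  list(Y = pmax(X, 0), mask = X > 0)
}

nn_relu_bwd <- function(dY, cache) dY * cache$mask

nn_softmax_fwd <- function(Z) {
  # rows of Z are samples
  Zs <- Z - apply(Z, 1, max)
  E <- exp(Zs)
  E / rowSums(E)
}

nn_softmax_bwd <- function(dP, P) {
  # Jacobian-vector product of row-wise softmax
  P * (dP - rowSums(dP * P))
}

nn_conv1d_fwd <- function(X, W, b) {
  list(Y = cpp_conv1d_fwd(X, W, b), X = X)
}

nn_conv1d_bwd <- function(dY, X, W) {
  out <- cpp_conv1d_bwd(dY, X, W)
  out$db <- drop(out$db)
  out
}

# pure-R reference implementations, kept as an independent check of the
# compiled kernels
r_conv1d_fwd <- function(X, W, b) {
  # X: (Cin, L, B); W: (Cout, Cin, k) with odd k, 'same' padding
  d <- dim(X); Cin <- d[1]; L <- d[2]; B <- d[3]
  Cout <- dim(W)[1]; k <- dim(W)[3]; pad <- (k - 1L) %/% 2L
  Xp <- array(0, c(Cin, L + 2L * pad, B))
  Xp[, pad + seq_len(L), ] <- X
  Ymat <- matrix(0, Cout, L * B)
  for (t in seq_len(k)) {
    Xs <- Xp[, t:(t + L - 1L), , drop = FALSE]
    dim(Xs) <- c(Cin, L * B)
    Ymat <- Ymat + matrix(W[, , t], Cout, Cin) %*% Xs
  }
  Y <- Ymat + b
  dim(Y) <- c(Cout, L, B)
  list(Y = Y, X = X)
}

r_conv1d_bwd <- function(dY, X, W) {
  d <- dim(X); Cin <- d[1]; L <- d[2]; B <- d[3]
  Cout <- dim(W)[1]; k <- dim(W)[3]; pad <- (k - 1L) %/% 2L
  Xp <- array(0, c(Cin, L + 2L * pad, B))
  Xp[, pad + seq_len(L), ] <- X
  dYmat <- dY; dim(dYmat) <- c(Cout, L * B)
  dW <- array(0, dim(W))
  db <- rowSums(dYmat)
  dXp <- array(0, c(Cin, L + 2L * pad, B))
  for (t in seq_len(k)) {
    Xs <- Xp[, t:(t + L - 1L), , drop = FALSE]
    dim(Xs) <- c(Cin, L * B)
    dW[, , t] <- tcrossprod(dYmat, Xs)
    dXs <- crossprod(matrix(W[, , t], Cout, Cin), dYmat)
    dim(dXs) <- c(Cin, L, B)
    dXp[, t:(t + L - 1L), ] <- dXp[, t:(t + L - 1L), , drop = FALSE] + dXs
  }
  dX <- dXp[, pad + seq_len(L), , drop = FALSE]
  dim(dX) <- c(Cin, L, B)
  list(dX = dX, dW = dW, db = db)
}

nn_bn_fwd <- function(X, gamma, beta, run_mean, run_var, training,
                      momentum = 0.1, eps = 1e-5) {
  d <- dim(X)
  Xm <- X; dim(Xm) <- c(d[1], d[2] * d[3])
  if (training) {
    mu <- rowMeans(Xm)
    v <- rowMeans(Xm * Xm) - mu * mu
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean
    v <- run_var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (Xm - mu) * inv
  Y <- gamma * xhat + beta
  dim(Y) <- d
  list(Y = Y, xhat = xhat, inv = inv, gamma = gamma, dims = d,
       run_mean = run_mean, run_var = run_var, training = training)
}

nn_bn_bwd <- function(dY, cache) {
  d <- cache$dims
  N <- d[2] * d[3]
  dYm <- dY; dim(dYm) <- c(d[1], N)
  dgamma <- rowSums(dYm * cache$xhat)
  dbeta <- rowSums(dYm)
  if (cache$training) {
    dX <- (cache$gamma * cache$inv / N) *
      (N * dYm - dbeta - cache$xhat * dgamma)
  } else {
    dX <- cache$gamma * cache$inv * dYm
  }
  dim(dX) <- d
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

nn_maxpool2_fwd <- function(X) {
  d <- dim(X); L <- d[2]
  stopifnot(L %% 2L == 0L)
  X1 <- X[, seq(1L, L, 2L), , drop = FALSE]
  X2 <- X[, seq(2L, L, 2L), , drop = FALSE]
  mask <- X1 >= X2
  list(Y = pmax(X1, X2), mask = mask)
}

nn_maxpool2_bwd <- function(dY, cache) {
  d <- dim(dY)
  dX <- array(0, c(d[1], d[2] * 2L, d[3]))
  dX[, seq(1L, d[2] * 2L, 2L), ] <- dY * cache$mask
  dX[, seq(2L, d[2] * 2L, 2L), ] <- dY * (!cache$mask)
  dX
}

nn_tconv2_fwd <- function(X, W, b) {
  # transposed conv, kernel 2 stride 2: X (Cin, L, B) -> Y (Cout, 2L, B)
  d <- dim(X); Cin <- d[1]; L <- d[2]; B <- d[3]
  Cout <- dim(W)[1]
  Xm <- X; dim(Xm) <- c(Cin, L * B)
  Y1 <- matrix(W[, , 1], Cout, Cin) %*% Xm
  Y2 <- matrix(W[, , 2], Cout, Cin) %*% Xm
  dim(Y1) <- c(Cout, L, B); dim(Y2) <- c(Cout, L, B)
  Y <- array(0, c(Cout, 2L * L, B))
  Y[, seq(1L, 2L * L, 2L), ] <- Y1
  Y[, seq(2L, 2L * L, 2L), ] <- Y2
  Y <- Y + b
  list(Y = Y, X = X)
}

nn_tconv2_bwd <- function(dY, X, W) {
  d <- dim(X); Cin <- d[1]; L <- d[2]; B <- d[3]
  Cout <- dim(W)[1]
  dY1 <- dY[, seq(1L, 2L * L, 2L), , drop = FALSE]
  dY2 <- dY[, seq(2L, 2L * L, 2L), , drop = FALSE]
  dim(dY1) <- c(Cout, L * B); dim(dY2) <- c(Cout, L * B)
  Xm <- X; dim(Xm) <- c(Cin, L * B)
  dW <- array(0, dim(W))
  dW[, , 1] <- tcrossprod(dY1, Xm)
  dW[, , 2] <- tcrossprod(dY2, Xm)
  db <- rowSums(dY1) + rowSums(dY2)
  dX <- crossprod(matrix(W[, , 1], Cout, Cin), dY1) +
    crossprod(matrix(W[, , 2], Cout, Cin), dY2)
  dim(dX) <- c(Cin, L, B)
  list(dX = dX, dW = dW, db = db)
}

# parameter initialisers -----------------------------------------------------

init_linear <- function(n_in, n_out) {
  list(W = matrix(rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = numeric(n_out))
}

init_conv <- function(c_out, c_in, k) {
  list(W = array(rnorm(c_out * c_in * k, sd = sqrt(2 / (c_in * k))),
                 c(c_out, c_in, k)),
       b = numeric(c_out))
}

init_bn <- function(ch) list(gamma = rep(1, ch), beta = numeric(ch))

# Adam ------------------------------------------------------------------------

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * gr
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * gr * gr
    new <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
    attributes(new) <- attributes(params[[nm]])   # no stray dimnames
    params[[nm]] <- new
  }
  list(params = params, st = st)
}
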