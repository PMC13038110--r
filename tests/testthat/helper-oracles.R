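# Independent brute-force oracles used to check the package's
# implementations.  These are deliberately naive (loops, exhaustive
# enumeration) and share no code with the implementations they check.

brute_l1 <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) s <- s + abs(y[i] - x[i])
  s / length(x)
}

brute_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my)) / n
  num / (sqrt(sum((x - mx)^2) / n) * sqrt(sum((y - my)^2) / n))
}

brute_ccc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  vx <- sum((x - mx)^2) / n; vy <- sum((y - my)^2) / n
  rho <- brute_pearson(x, y)
  2 * rho * sqrt(vx) * sqrt(vy) / (vx + vy + (mx - my)^2)
}

brute_r2 <- function(x, y) {
  1 - sum((y - x)^2) / sum((x - mean(x))^2)
}

# exhaustive enumeration of distinct two-group partitions induced by
# conjunctions of cell states, for a patients x types 0/1 matrix
brute_partition_count <- function(S) {
  n <- nrow(S); cc <- ncol(S)
  keys <- character(0)
  for (k in seq_len(cc)) {
    for (types in utils::combn(cc, k, simplify = FALSE)) {
      n_codes <- 2^k
      for (code in seq_len(n_codes) - 1) {
        req <- as.integer(intToBits(code))[seq_len(k)]
        v <- rep(1L, n)
        for (j in seq_len(k)) v <- v * as.integer(S[, types[j]] == req[j])
        if (v[1] == 1L) v <- 1L - v
        keys <- c(keys, paste(v, collapse = ""))
      }
    }
  }
  length(unique(keys))
}

# exhaustive minimum-Hamming pairing check for group correspondence
brute_best_pairing <- function(vC, vD) {
  h <- function(a, b) sum(a != b)
  if (h(vC, vD) <= h(vC, 1L - vD)) vD else 1L - vD
}

# small well-separated reference shared across tests
tiny_reference <- function(n_types = 3L, n_genes = 200L, cells = 120L,
                           fold = 8, seed = 42L, conditions = 1L) {
  generate_reference(synthetic_spec(
    n_cell_types = n_types, n_genes = n_genes, cells_per_type = cells,
    n_markers_per_type = 10L, marker_fold_change = fold,
    n_conditions = conditions, n_condition_degs = 8L,
    condition_fold_change = 4, seed = seed
  ))
}

# a compact model configuration used wherever architecture details are not
# under test
tiny_model_config <- function(g, cc, seed = 1L) {
  model_config(g, cc, feature_dim = 32L, mlp_dims = c(32L, 16L),
               unet_depth = 2L, base_channels = 4L, seed = seed)
}
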