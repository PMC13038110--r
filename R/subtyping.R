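# Combinatorial cell-state patient subtyping on deconvolution output:
# proportion-based clustering with KNN transfer, per-type binary cell
# states, enumeration of conjunctive group definitions, log-rank screening
# with BH control, IoU merging, consensus assignment, and external-cohort
# transfer of the final grouping.

# Leiden clustering on a k-nearest-neighbour graph, with the resolution
# searched so the partition reaches a requested number of clusters.
knn_graph <- function(X, k = 15L) {
  n <- nrow(X)
  k <- min(k, n - 1L)
  D <- as.matrix(dist(X))
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- order(D[i, ])[2:(k + 1L)]
    cbind(i, nb)
  }))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}

leiden_n_clusters <- function(graph, n_clusters, resolution_range = c(1e-4, 50),
                              max_iter = 40L, seed = 1L) {
  run <- function(res) {
    set.seed(seed)
    igraph::membership(igraph::cluster_leiden(
      graph, objective_function = "modularity", resolution = res,
      n_iterations = 5L
    ))
  }
  lo <- resolution_range[1]; hi <- resolution_range[2]
  m_lo <- run(lo); m_hi <- run(hi)
  if (max(m_lo) > n_clusters || max(m_hi) < n_clusters) {
    return(list(membership = NULL, resolution = NA_real_))
  }
  for (i in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    m <- run(mid)
    kk <- max(m)
    if (kk == n_clusters) {
      return(list(membership = as.integer(m), resolution = mid))
    }
    if (kk < n_clusters) lo <- mid else hi <- mid
  }
  list(membership = NULL, resolution = NA_real_)
}

#' Cluster patients by predicted cell-type proportions
#'
#' PCA on the proportion matrix followed by Leiden clustering of a
#' k-nearest-neighbour graph in PCA space, with the Leiden resolution
#' auto-tuned to reach `n_clusters`.  The fitted PCA rotation is retained so
#' an external cohort can be transferred into the same space with
#' [knn_transfer()].
#'
#' @param P patients x cell-types proportion matrix.
#' @param n_clusters target cluster count (e.g. 4).
#' @param n_pcs principal components kept (default all).
#' @param knn_k neighbours in the graph (default 15).
#' @param seed integer seed.
#' @return a `proportion_subtypes` object: `labels` (integer per patient),
#'   `pca` (the `prcomp` fit), `scores`, `resolution`.
#' @export
proportion_subtypes <- function(P, n_clusters = 4L, n_pcs = NULL,
                                knn_k = 15L, seed = 1L) {
  P <- as.matrix(P)
  if (nrow(P) < n_clusters) abort("fewer patients than requested clusters.")
  if (all(apply(P, 2, var) == 0)) abort("degenerate proportion matrix (rank 0).")
  pca <- prcomp(P, center = TRUE, scale. = FALSE)
  n_pcs <- n_pcs %||% ncol(pca$x)
  scores <- pca$x[, seq_len(min(n_pcs, ncol(pca$x))), drop = FALSE]
  g <- knn_graph(scores, knn_k)
  fit <- leiden_n_clusters(g, n_clusters, seed = seed)
  if (is.null(fit$membership)) {
    abort(sprintf("could not reach %d clusters in the resolution search.",
                  n_clusters))
  }
  structure(
    list(labels = fit$membership, pca = pca, scores = scores,
         n_pcs = ncol(scores), resolution = fit$resolution,
         knn_k = knn_k),
    class = "proportion_subtypes"
  )
}

#' Transfer cluster labels to a new cohort by KNN in the fitted PCA space
#'
#' Each new patient receives the majority label of its `k` nearest training
#' patients in the PCA space fitted by [proportion_subtypes()]; ties are
#' broken deterministically by the smallest label.
#'
#' @param fit a `proportion_subtypes` object.
#' @param P_new new patients x cell-types proportion matrix (same columns).
#' @param k neighbours (default 5).
#' @return integer labels for the new patients.
#' @export
knn_transfer <- function(fit, P_new, k = 5L) {
  stopifnot(inherits(fit, "proportion_subtypes"))
  P_new <- as.matrix(P_new)
  if (ncol(P_new) != nrow(fit$pca$rotation)) {
    abort("new proportion matrix has the wrong number of cell types.")
  }
  new_scores <- predict(fit$pca, P_new)[, seq_len(fit$n_pcs), drop = FALSE]
  train <- fit$scores
  k <- min(k, nrow(train))
  vapply(seq_len(nrow(new_scores)), function(i) {
    d2 <- colSums((t(train) - new_scores[i, ])^2)
    nb <- order(d2)[seq_len(k)]
    tab <- table(fit$labels[nb])
    winners <- as.integer(names(tab)[tab == max(tab)])
    min(winners)
  }, integer(1))
}

#' Binary cell states from predicted cell-type-specific GEPs
#'
#' For every cell type, patients are clustered on that type's predicted
#' expression profile (Leiden on a KNN graph, resolution binary-searched to
#' exactly two clusters); the two clusters are the type's two cell states.
#' State 0 is always the larger cluster (ties broken by the lower patient
#' index), making repeated runs identical.  When two clusters are
#' unreachable by the resolution search the partition falls back to a
#' two-way cut of a hierarchical clustering (Ward), and this is recorded.
#'
#' @param G_hat genes x types x patients array of predicted GEPs (as in a
#'   `deconv_result`), or a patients x genes x types array.
#' @param cell_types optional type names.
#' @param knn_k,seed KNN graph size and seed.
#' @return a `cell_state_table`: `states` (patients x types 0/1 matrix) and
#'   `fallback` (logical per type: hierarchical fallback used).
#' @export
binarize_cell_states <- function(G_hat, cell_types = NULL, knn_k = 15L,
                                 seed = 1L) {
  stopifnot(length(dim(G_hat)) == 3L)
  cc <- dim(G_hat)[2]
  n <- dim(G_hat)[3]
  if (n < 4L) abort("need at least 4 patients to define cell states.")
  cell_types <- cell_types %||% dimnames(G_hat)[[2]] %||%
    sprintf("type%d", seq_len(cc))
  states <- matrix(0L, n, cc, dimnames = list(dimnames(G_hat)[[3]], cell_types))
  fallback <- logical(cc)
  for (k in seq_len(cc)) {
    X <- t(G_hat[, k, ])                       # patients x genes
    if (all(apply(X, 2, var) == 0)) {
      fallback[k] <- TRUE
      warn(sprintf("cell type '%s': identical profiles; no data-driven 2-way cut; patient 1 isolated.",
                   cell_types[k]))
      states[, k] <- 0L
      states[1, k] <- 1L
      next
    }
    g <- knn_graph(X, knn_k)
    fit <- leiden_n_clusters(g, 2L, seed = seed)
    memb <- fit$membership
    if (is.null(memb)) {
      fallback[k] <- TRUE
      warn(sprintf("cell type '%s': 2 clusters unreachable by Leiden; hierarchical fallback.",
                   cell_types[k]))
      memb <- cutree(hclust(dist(X), method = "ward.D2"), 2L)
    }
    # orient: state 0 = larger cluster; tie -> cluster of patient 1
    n1 <- sum(memb == 1L)
    big <- if (n1 > n - n1) 1L else if (n1 < n - n1) 2L else memb[1L]
    states[, k] <- as.integer(memb != big)
  }
  structure(list(states = states, fallback = fallback, cell_types = cell_types),
            class = "cell_state_table")
}

#' @export
print.cell_state_table <- function(x, ...) {
  cat(sprintf("<cell_state_table> %d patients x %d cell types\n",
              nrow(x$states), ncol(x$states)))
  invisible(x)
}

canonical_partition_key <- function(v) {
  # unordered two-group partition: flip so the first element is 0
  if (v[1] == 1L) v <- 1L - v
  paste(v, collapse = "")
}

#' Enumerate all conjunctive two-group patient definitions
#'
#' A definition picks `k` cell types (`k = 1..c`) and one required state per
#' chosen type; patients satisfying every constraint form group 1 and the
#' rest form group 2.  Definitions inducing the same unordered two-group
#' partition are counted once (for `k = 1` the two states of a type give
#' complementary, hence identical, partitions).  With all `2^c` state
#' combinations populated the distinct count is `3^c - 1 - c`; for six
#' binary cell types that is 722.
#'
#' @param states a `cell_state_table` or a patients x types 0/1 matrix.
#' @return a tibble, one row per distinct partition: list-columns `types`
#'   and `req_states` (the lexicographically first constraint realising the
#'   partition), `v1` (group-1 indicator), `n1`, `n2`, `degenerate` (one
#'   side empty; such definitions are excluded from survival screening),
#'   and `definition` (stable identifier).
#' @export
enumerate_definitions <- function(states) {
  S <- if (inherits(states, "cell_state_table")) states$states else
    as.matrix(states)
  if (!all(S %in% c(0L, 1L))) abort("states must be 0/1.")
  cc <- ncol(S)
  n <- nrow(S)
  type_names <- colnames(S) %||% sprintf("type%d", seq_len(cc))
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (k in seq_len(cc)) {
    combos <- utils::combn(cc, k, simplify = FALSE)
    for (types in combos) {
      for (code in 0:(2L^k - 1L)) {
        req <- as.integer(intToBits(code))[seq_len(k)]
        v1 <- as.integer(rowSums(S[, types, drop = FALSE] ==
                                   matrix(req, n, k, byrow = TRUE)) == k)
        key <- canonical_partition_key(v1)
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        n1 <- sum(v1)
        out[[length(out) + 1L]] <- tibble(
          definition = sprintf("def%04d", length(out) + 1L),
          types = list(type_names[types]),
          req_states = list(req),
          v1 = list(v1),
          n1 = n1, n2 = n - n1,
          degenerate = n1 == 0L || n1 == n
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Screen group definitions for survival differences
#'
#' Two-sample log-rank test per definition, Benjamini-Hochberg adjustment
#' across all tested definitions, keep adjusted p below `alpha`.
#' Degenerate definitions, groups smaller than `min_group`, and definitions
#' whose two groups hold no events are skipped (and reported with NA p).
#'
#' @param defs tibble from [enumerate_definitions()].
#' @param survival_table tibble with `patient_id`, `time`, `event`, ordered
#'   like the state table's patients.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param min_group minimum size of either group (default 5).
#' @return the definitions tibble with `p`, `p_adj` and `kept` columns,
#'   filtered rows retained for audit (use `dplyr::filter(kept)` for the
#'   surviving set).
#' @export
screen_survival <- function(defs, survival_table, alpha = 0.05,
                            min_group = 5L) {
  stopifnot(all(c("time", "event") %in% names(survival_table)))
  n <- length(defs$v1[[1]])
  if (nrow(survival_table) != n) {
    abort("survival table and definitions cover different patient counts.")
  }
  p <- rep(NA_real_, nrow(defs))
  for (i in seq_len(nrow(defs))) {
    if (defs$degenerate[i]) next
    if (min(defs$n1[i], defs$n2[i]) < min_group) next
    grp <- defs$v1[[i]]
    if (sum(survival_table$event[grp == 1L]) == 0L &&
        sum(survival_table$event[grp == 0L]) == 0L) next
    sd_ <- survival::survdiff(
      survival::Surv(survival_table$time, survival_table$event) ~ grp
    )
    p[i] <- pchisq(sd_$chisq, df = 1L, lower.tail = FALSE)
  }
  p_adj <- rep(NA_real_, length(p))
  tested <- !is.na(p)
  p_adj[tested] <- p.adjust(p[tested], method = "BH")
  defs$p <- p
  defs$p_adj <- p_adj
  defs$kept <- !is.na(p_adj) & p_adj < alpha
  defs
}

iou <- function(a, b) {
  u <- sum(a | b)
  if (u == 0L) return(0)
  sum(a & b) / u
}

#' Pairwise-similarity graph over screened definitions
#'
#' The similarity of two definitions is `max(IoU(A1, B1), IoU(A1, B2))`
#' where `A1`, `B1` are each definition's smaller patient group (ties take
#' the encoded group 1, recorded in `size_tie`); the symmetric matrix is
#' binarized at `threshold` to an adjacency matrix whose connected
#' components group near-identical definitions.
#'
#' @param defs screened definitions (rows with `kept == TRUE` of
#'   [screen_survival()] output, or any definitions tibble with `v1`).
#' @param threshold IoU edge threshold (default 0.8).
#' @return a `definition_graph`: `S` (similarity matrix), `adjacency`,
#'   `component` (integer per definition), `defs` (the input rows),
#'   `size_tie` flags.
#' @export
build_definition_graph <- function(defs, threshold = 0.8) {
  if (nrow(defs) < 1L) abort("need at least one definition.")
  m <- nrow(defs)
  small <- vector("list", m)
  size_tie <- logical(m)
  for (i in seq_len(m)) {
    v <- defs$v1[[i]]
    n1 <- sum(v)
    n2 <- length(v) - n1
    if (n1 == n2) {
      size_tie[i] <- TRUE
      small[[i]] <- v == 1L
    } else if (n1 < n2) {
      small[[i]] <- v == 1L
    } else {
      small[[i]] <- v == 0L
    }
  }
  if (any(size_tie)) {
    inform(sprintf(
      "%d definition(s) have equal group sizes; their encoded group 1 was used as the smaller group.",
      sum(size_tie)
    ))
  }
  S <- diag(1, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (j <= i) next
      s <- max(iou(small[[i]], small[[j]]), iou(small[[i]], !small[[j]]))
      S[i, j] <- S[j, i] <- s
    }
  }
  adjacency <- (S >= threshold) * 1L
  g <- igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  structure(
    list(S = S, adjacency = adjacency, component = as.integer(comp),
         defs = defs, threshold = threshold, size_tie = size_tie),
    class = "definition_graph"
  )
}

#' Align group orientations within one component (group correspondence)
#'
#' Takes the definitions of one connected component, anchors on the
#' definition with the smallest survival p-value, and pairs each other
#' definition's two indicator encodings with the anchor's two encodings by
#' minimal Hamming distance.  An exact distance tie pairs with the
#' definition's first encoding (recorded in `ties`).
#'
#' @param defs definitions tibble (with `v1` and `p`) of one component.
#' @return list with `family1`, `family2` (lists of aligned indicator
#'   vectors, anchor first), `anchor` (row index of the anchor), `ties`.
#' @export
match_groups <- function(defs) {
  if (nrow(defs) < 1L) abort("empty component.")
  anchor <- which.min(replace(defs$p, is.na(defs$p), Inf))
  v1C <- defs$v1[[anchor]]
  v2C <- 1L - v1C
  family1 <- list(v1C)
  family2 <- list(v2C)
  ties <- logical(nrow(defs))
  hamming <- function(a, b) sum((a + b) %% 2L)
  for (i in seq_len(nrow(defs))) {
    if (i == anchor) next
    v1D <- defs$v1[[i]]
    v2D <- 1L - v1D
    d11 <- hamming(v1C, v1D)
    d12 <- hamming(v1C, v2D)
    if (d11 == d12) ties[i] <- TRUE
    family1[[length(family1) + 1L]] <- if (d11 <= d12) v1D else v2D
    d21 <- hamming(v2C, v1D)
    d22 <- hamming(v2C, v2D)
    family2[[length(family2) + 1L]] <- if (d21 <= d22) v1D else v2D
  }
  if (any(ties)) {
    inform(sprintf("%d definition(s) had tied Hamming distances; paired with their first encoding.",
                   sum(ties)))
  }
  list(family1 = family1, family2 = family2, anchor = anchor, ties = ties)
}

consensus_of_family <- function(family) {
  n_def <- length(family) - 1L            # n other definitions beside anchor
  thresh <- (n_def + 1L) / 2L
  M <- do.call(cbind, family)             # patients x (n+1)
  in0 <- rowSums(M == 0L)
  in1 <- rowSums(M == 1L)
  out <- rep(2L, nrow(M))
  out[in0 > thresh] <- 0L
  out[in1 > thresh] <- 1L
  out
}

#' Consensus patient assignment over aligned definitions
#'
#' Applies the strict-majority rule to each of the two aligned families
#' from [match_groups()]: a patient joins group 0 (or 1) when more than
#' `(n + 1) / 2` of the `n + 1` aligned definitions place it there, and is
#' otherwise unresolved (group 2).  Of the two candidate orientations the
#' one assigning fewer patients to group 2 wins (ties keep the first).
#'
#' @param aligned output of [match_groups()].
#' @return list with `assignment` (0/1/2 per patient) and `orientation`
#'   (1 or 2: which family won).
#' @export
consensus_patients <- function(aligned) {
  a1 <- consensus_of_family(aligned$family1)
  a2 <- consensus_of_family(aligned$family2)
  if (sum(a2 == 2L) < sum(a1 == 2L)) {
    list(assignment = a2, orientation = 2L)
  } else {
    list(assignment = a1, orientation = 1L)
  }
}

rmst <- function(time, event, tau = max(time)) {
  # restricted mean survival time: area under the Kaplan-Meier curve to tau
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  t_ <- c(0, pmin(fit$time, tau))
  s_ <- c(1, fit$surv)
  keep <- t_ <= tau
  t_ <- c(t_[keep], tau)
  s_ <- c(s_[keep], s_[sum(keep)])
  sum(diff(t_) * s_[-length(s_)])
}

#' Merge component consensuses into a final three-way patient grouping
#'
#' Each component's consensus defines a candidate patient group (its
#' smaller resolved group).  A candidate is labelled favorable or
#' unfavorable by comparing the restricted-mean survival of its group
#' against the remaining patients.  Candidates sharing a direction are
#' merged by the same strict-majority vote as [consensus_patients()];
#' patients claimed by both final groups are moved to the remainder (and
#' counted in `n_conflict`).
#'
#' @param consensuses list of 0/1/2 assignment vectors (one per component).
#' @param survival_table per-patient `time` and `event`, same order.
#' @return a `patient_grouping`: `group` per patient
#'   (`"favorable"`, `"unfavorable"`, `"rest"`), `direction` per input
#'   consensus, `n_conflict`.
#' @export
merge_patterns <- function(consensuses, survival_table) {
  if (length(consensuses) == 0L) {
    inform("no screened definitions; returning an empty grouping.")
    return(structure(
      list(group = rep("rest", nrow(survival_table)),
           direction = character(0), n_conflict = 0L),
      class = "patient_grouping"
    ))
  }
  n <- nrow(survival_table)
  direction <- character(length(consensuses))
  indicator <- vector("list", length(consensuses))
  for (i in seq_along(consensuses)) {
    a <- consensuses[[i]]
    n0 <- sum(a == 0L); n1 <- sum(a == 1L)
    small_code <- if (n0 <= n1) 0L else 1L
    ind <- as.integer(a == small_code)
    in_g <- ind == 1L
    if (sum(in_g) == 0L || sum(!in_g) == 0L) {
      direction[i] <- "undetermined"
      indicator[[i]] <- ind
      next
    }
    r_in <- rmst(survival_table$time[in_g], survival_table$event[in_g],
                 tau = max(survival_table$time))
    r_out <- rmst(survival_table$time[!in_g], survival_table$event[!in_g],
                  tau = max(survival_table$time))
    direction[i] <- if (r_in > r_out) "favorable" else "unfavorable"
    indicator[[i]] <- ind
  }
  vote <- function(dir) {
    idx <- which(direction == dir)
    if (length(idx) == 0L) return(rep(FALSE, n))
    M <- do.call(cbind, indicator[idx])
    rowSums(M == 1L) > length(idx) / 2
  }
  fav <- vote("favorable")
  unf <- vote("unfavorable")
  conflict <- fav & unf
  if (any(conflict)) {
    inform(sprintf("%d patient(s) claimed by both final groups; moved to the remainder.",
                   sum(conflict)))
  }
  group <- rep("rest", n)
  group[fav & !conflict] <- "favorable"
  group[unf & !conflict] <- "unfavorable"
  structure(
    list(group = group, direction = direction, n_conflict = sum(conflict)),
    class = "patient_grouping"
  )
}

#' Run the full cell-state subtyping pipeline
#'
#' Chains [binarize_cell_states()], [enumerate_definitions()],
#' [screen_survival()], [build_definition_graph()], per-component
#' [match_groups()] + [consensus_patients()], and [merge_patterns()].
#'
#' @param G_hat genes x types x patients predicted GEP array.
#' @param survival_table per-patient `time`/`event` tibble, same order.
#' @param alpha,min_group,iou_threshold screening and merging parameters.
#' @param knn_k,seed clustering parameters.
#' @return list with `states`, `definitions` (screened tibble), `graph`,
#'   `consensuses`, `grouping`.
#' @export
subtype_patients <- function(G_hat, survival_table, alpha = 0.05,
                             min_group = 5L, iou_threshold = 0.8,
                             knn_k = 15L, seed = 1L) {
  states <- binarize_cell_states(G_hat, knn_k = knn_k, seed = seed)
  defs <- enumerate_definitions(states)
  defs <- screen_survival(defs, survival_table, alpha = alpha,
                          min_group = min_group)
  kept <- defs[defs$kept, ]
  if (nrow(kept) == 0L) {
    return(list(states = states, definitions = defs, graph = NULL,
                consensuses = list(),
                grouping = merge_patterns(list(), survival_table)))
  }
  graph <- build_definition_graph(kept, threshold = iou_threshold)
  consensuses <- lapply(sort(unique(graph$component)), function(cmp) {
    sub <- kept[graph$component == cmp, ]
    consensus_patients(match_groups(sub))$assignment
  })
  grouping <- merge_patterns(consensuses, survival_table)
  list(states = states, definitions = defs, graph = graph,
       consensuses = consensuses, grouping = grouping)
}

#' Transfer a patient grouping to an external cohort by expression signature
#'
#' For each direction (favorable, unfavorable): genes differentially
#' expressed between that group and the rest of the training cohort are
#' selected by rank-sum test (BH-adjusted); a one-component PCA is fitted
#' to the selected genes separately per cohort, the test component's sign
#' aligned to the training component by correlating gene loadings; a
#' logistic regression on the training component is applied to the test
#' component.  Test patients claimed by both directions go to the
#' remainder.
#'
#' @param bulk_train,bulk_test genes x patients expression matrices
#'   (normalized log scale) sharing gene identifiers in rownames.
#' @param grouping a `patient_grouping` for the training cohort.
#' @param p_cutoff adjusted-p threshold for signature genes (default 0.05).
#' @param max_genes cap on signature size per direction (default 200,
#'   ranked by |logFC|).
#' @return a `patient_grouping` for the test cohort.
#' @export
external_validation <- function(bulk_train, bulk_test, grouping,
                                p_cutoff = 0.05, max_genes = 200L) {
  stopifnot(inherits(grouping, "patient_grouping"))
  shared <- intersect(rownames(bulk_train), rownames(bulk_test))
  if (length(shared) == 0L) abort("no shared genes between cohorts.")
  btr <- bulk_train[shared, , drop = FALSE]
  bte <- bulk_test[shared, , drop = FALSE]
  n_te <- ncol(bte)
  claim <- matrix(FALSE, n_te, 2L,
                  dimnames = list(NULL, c("favorable", "unfavorable")))
  for (dir in c("favorable", "unfavorable")) {
    in_g <- grouping$group == dir
    if (sum(in_g) < 2L || sum(!in_g) < 2L) next
    rs <- rank_sum_one_vs_rest(t(btr), in_g)
    p_adj <- p.adjust(rs$p, method = "BH")
    sig <- which(p_adj < p_cutoff)
    if (length(sig) == 0L) {
      abort(sprintf("no signature genes found for the %s group.", dir))
    }
    sig <- sig[order(-abs(rs$logfc[sig]))]
    sig <- head(sig, max_genes)
    Xtr <- t(btr[sig, , drop = FALSE])
    Xte <- t(bte[sig, , drop = FALSE])
    pc_tr <- prcomp(Xtr, center = TRUE, scale. = FALSE, rank. = 1L)
    pc_te <- prcomp(Xte, center = TRUE, scale. = FALSE, rank. = 1L)
    if (stats::cor(pc_tr$rotation[, 1L], pc_te$rotation[, 1L]) < 0) {
      pc_te$x[, 1L] <- -pc_te$x[, 1L]
    }
    df_tr <- data.frame(y = as.integer(in_g), pc = pc_tr$x[, 1L])
    # perfect separation on a clean signature is expected and harmless:
    # only the decision boundary is used
    lr <- suppressWarnings(glm(y ~ pc, data = df_tr, family = binomial()))
    prob <- suppressWarnings(
      predict(lr, data.frame(pc = pc_te$x[, 1L]), type = "response")
    )
    claim[, dir] <- prob > 0.5
  }
  conflict <- claim[, 1L] & claim[, 2L]
  if (any(conflict)) {
    inform(sprintf("%d test patient(s) claimed by both directions; moved to the remainder.",
                   sum(conflict)))
  }
  group <- rep("rest", n_te)
  group[claim[, "favorable"] & !conflict] <- "favorable"
  group[claim[, "unfavorable"] & !conflict] <- "unfavorable"
  structure(
    list(group = group, direction = grouping$direction,
         n_conflict = sum(conflict)),
    class = "patient_grouping"
  )
}
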