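full_state_table <- function(cc) {
  # one patient per state combination: every combination populated
  S <- as.matrix(expand.grid(rep(list(0:1), cc)))
  colnames(S) <- paste0("ct", seq_len(cc))
  S
}

test_that("definition enumeration counts distinct partitions", {
  # c = 1: the two single-type definitions are complements of each other
  expect_equal(nrow(enumerate_definitions(full_state_table(1))), 1)
  # c = 2: 8 raw definitions collapse to 6 distinct partitions
  expect_equal(nrow(enumerate_definitions(full_state_table(2))), 6)
  for (cc in 1:4) {
    S <- full_state_table(cc)
    expect_equal(nrow(enumerate_definitions(S)), 3^cc - 1 - cc)
    expect_equal(nrow(enumerate_definitions(S)), brute_partition_count(S))
  }
})

test_that("enumeration de-duplicates against the brute-force partition oracle on sparse tables", {
  set.seed(13)
  for (rep_ in 1:5) {
    S <- matrix(rbinom(10 * 3, 1, 0.5), 10, 3)
    expect_equal(nrow(enumerate_definitions(S)), brute_partition_count(S))
  }
})

test_that("planted proportion archetypes are recovered as clusters", {
  set.seed(41)
  arch <- rbind(
    c(0.7, 0.1, 0.1, 0.05, 0.03, 0.02),
    c(0.1, 0.7, 0.1, 0.05, 0.03, 0.02),
    c(0.05, 0.05, 0.6, 0.2, 0.05, 0.05),
    c(0.05, 0.05, 0.05, 0.05, 0.4, 0.4)
  )
  P <- arch[rep(1:4, each = 60), ] + matrix(rnorm(240 * 6, sd = 0.02), 240, 6)
  P <- abs(P); P <- P / rowSums(P)
  truth <- rep(1:4, each = 60)
  fit <- proportion_subtypes(P, n_clusters = 4, seed = 1)
  expect_equal(length(unique(fit$labels)), 4)
  purity <- mean(vapply(1:4, function(k) {
    max(table(fit$labels[truth == k])) / 60
  }, numeric(1)))
  expect_gte(purity, 0.95)

  # permutation invariance up to relabelling: co-membership must agree
  perm <- sample(240)
  fit_p <- proportion_subtypes(P[perm, ], n_clusters = 4, seed = 1)
  co1 <- outer(fit$labels[order(seq_len(240))], fit$labels, "==")
  co_perm <- outer(fit_p$labels, fit_p$labels, "==")
  co2 <- co_perm[order(perm), order(perm)]
  expect_gte(mean(co1 == co2), 0.99)
})

test_that("degenerate proportion matrices are rejected", {
  P <- matrix(0.25, 30, 4)
  expect_error(proportion_subtypes(P, n_clusters = 4), "degenerate|clusters")
})

test_that("KNN transfer reproduces training labels and breaks ties low", {
  set.seed(42)
  arch <- rbind(c(0.8, 0.1, 0.1), c(0.1, 0.8, 0.1), c(0.1, 0.1, 0.8))
  P <- arch[rep(1:3, each = 40), ] + matrix(rnorm(120 * 3, sd = 0.02), 120, 3)
  P <- abs(P); P <- P / rowSums(P)
  fit <- proportion_subtypes(P, n_clusters = 3, seed = 2)
  # training points transferred onto themselves keep their own label
  self <- knn_transfer(fit, P, k = 1)
  expect_equal(self, fit$labels)
  # new draws from the same archetypes land in the right cluster
  P_new <- arch[rep(1:3, each = 20), ] + matrix(rnorm(60 * 3, sd = 0.02), 60, 3)
  P_new <- abs(P_new); P_new <- P_new / rowSums(P_new)
  lab_new <- knn_transfer(fit, P_new, k = 5)
  arch_label <- vapply(1:3, function(k) {
    as.integer(names(which.max(table(fit$labels[rep(1:3, each = 40) == k]))))
  }, integer(1))
  expect_gte(mean(lab_new == arch_label[rep(1:3, each = 20)]), 0.9)
})

test_that("binary cell states recover planted expression modes", {
  set.seed(43)
  n <- 40L; g <- 30L; cc <- 2L
  planted <- matrix(rbinom(n * cc, 1, 0.5), n, cc)
  G <- array(rnorm(g * cc * n, sd = 0.3), c(g, cc, n))
  shift <- matrix(rnorm(g * cc, sd = 2), g, cc)
  for (k in seq_len(cc)) {
    for (i in seq_len(n)) {
      if (planted[i, k] == 1) G[, k, i] <- G[, k, i] + shift[, k]
    }
  }
  cs <- binarize_cell_states(G, seed = 7)
  for (k in seq_len(cc)) {
    agree <- mean(cs$states[, k] == planted[, k])
    expect_gte(max(agree, 1 - agree), 0.95)
  }
  # determinism of the orientation rule
  cs2 <- binarize_cell_states(G, seed = 7)
  expect_identical(cs$states, cs2$states)
})

test_that("identical profiles trigger the logged fallback path", {
  G <- array(1, c(10, 1, 8))
  expect_warning(cs <- binarize_cell_states(G, seed = 1), "identical")
  expect_true(cs$fallback[1])
})

test_that("survival screening keeps a strong planted split and respects alpha", {
  set.seed(44)
  n <- 200L
  v <- rep(c(1L, 0L), each = 100)
  st <- generate_survival(ifelse(v == 1, "hi", "lo"), c(hi = 4, lo = 1),
                          censor_rate = 0.2, seed = 9)
  S <- cbind(v, matrix(rbinom(n * 2, 1, 0.5), n, 2))
  colnames(S) <- paste0("ct", 1:3)
  defs <- enumerate_definitions(S)
  screened <- screen_survival(defs, st, alpha = 0.05)
  planted_key <- paste(if (v[1] == 1) 1 - v else v, collapse = "")
  keys <- vapply(screened$v1, function(x)
    paste(if (x[1] == 1) 1 - x else x, collapse = ""), character(1))
  expect_true(screened$kept[keys == planted_key])
  # alpha = 0 screens everything out
  s0 <- screen_survival(defs, st, alpha = 0)
  expect_false(any(s0$kept))
  # degenerate and tiny groups are never tested
  expect_true(all(is.na(screened$p[screened$degenerate])))
  expect_true(all(is.na(screened$p[pmin(screened$n1, screened$n2) < 5])))
})

test_that("definition similarity follows the smaller-group IoU rule", {
  mk_def <- function(v) tibble::tibble(v1 = list(as.integer(v)), p = 0.01)
  n <- 10L
  a <- c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0)     # A1 = {1,2}
  b <- c(0, 1, 1, 0, 0, 0, 0, 0, 0, 0)     # B1 = {2,3}
  defs <- dplyr::bind_rows(mk_def(a), mk_def(b))
  gr <- build_definition_graph(defs, threshold = 0.8)
  expect_equal(diag(gr$S), c(1, 1))
  expect_equal(gr$S[1, 2], max(1 / 3, 0 / 10), tolerance = 1e-12)
  expect_true(isSymmetric(gr$S))

  # identical partitions with swapped labels match through the complement
  defs2 <- dplyr::bind_rows(mk_def(a), mk_def(1 - a))
  gr2 <- build_definition_graph(defs2, threshold = 0.8)
  expect_equal(gr2$S[1, 2], 1)
  expect_equal(length(unique(gr2$component)), 1)

  # a definition alone is its own component with self-similarity 1
  gr3 <- build_definition_graph(mk_def(a))
  expect_equal(gr3$S, matrix(1, 1, 1))
  expect_equal(gr3$component, 1L)
})

test_that("group correspondence pairs encodings by minimal Hamming distance", {
  mk_defs <- function(vs, ps) {
    tibble::tibble(v1 = lapply(vs, as.integer), p = ps)
  }
  vC <- c(1, 1, 0, 0, 0)
  # identical definition pairs with itself at distance zero
  al <- match_groups(mk_defs(list(vC, vC), c(0.001, 0.01)))
  expect_equal(al$family1[[2]], as.integer(vC))
  # label-swapped definition pairs with the complement encoding
  al2 <- match_groups(mk_defs(list(vC, 1 - vC), c(0.001, 0.01)))
  expect_equal(al2$family1[[2]], as.integer(vC))
  expect_equal(al2$family2[[2]], as.integer(1 - vC))

  # random instances against the exhaustive oracle
  set.seed(45)
  for (rep_ in 1:25) {
    n <- sample(4:12, 1)
    m <- sample(2:5, 1)
    vs <- lapply(seq_len(m), function(i) rbinom(n, 1, 0.5))
    ps <- runif(m)
    al3 <- match_groups(mk_defs(vs, ps))
    anchor <- which.min(ps)
    vCr <- vs[[anchor]]
    kk <- 2L
    for (i in seq_len(m)) {
      if (i == anchor) next
      expect_equal(al3$family1[[kk]], brute_best_pairing(vCr, vs[[i]]))
      kk <- kk + 1L
    }
  }
})

test_that("consensus applies the strict printed majority threshold", {
  # three assignments; one patient in group 0 twice and group 1 once:
  # 2 > (2+1)/2 = 1.5 is TRUE -> group 0 under n = 2 other definitions
  fam <- list(c(0L, 0L, 1L), c(0L, 1L, 1L), c(1L, 0L, 1L))
  a <- consensus_of_family(fam)
  # patient 1: in group 0 twice -> 2 > 1.5 -> group 0
  expect_equal(a[1], 0L)
  # patient 3: unanimous group 1
  expect_equal(a[3], 1L)
  # patient 2: 0 twice -> group 0
  expect_equal(a[2], 0L)

  # exact 50/50 splits stay unresolved: with n + 1 = 2 assignments a
  # patient in each group once satisfies neither strict majority
  fam2 <- list(c(0L, 1L), c(1L, 1L))
  a2 <- consensus_of_family(fam2)
  expect_equal(a2, c(2L, 1L))

  # a single definition is its own consensus
  single <- match_groups(tibble::tibble(v1 = list(c(1L, 0L, 0L)), p = 0.01))
  cons <- consensus_patients(single)
  expect_true(all(cons$assignment %in% c(0L, 1L)))
  expect_equal(sum(cons$assignment == 2L), 0)

  # order invariance over the non-anchor definitions
  vs <- list(c(1L, 1L, 0L, 0L), c(1L, 0L, 0L, 0L), c(1L, 1L, 1L, 0L))
  d1 <- tibble::tibble(v1 = vs, p = c(0.001, 0.2, 0.3))
  d2 <- tibble::tibble(v1 = vs[c(1, 3, 2)], p = c(0.001, 0.3, 0.2))
  expect_equal(consensus_patients(match_groups(d1))$assignment,
               consensus_patients(match_groups(d2))$assignment)
})

test_that("unanimous definitions yield themselves as consensus", {
  v <- c(1L, 1L, 0L, 0L, 0L, 1L)
  defs <- tibble::tibble(v1 = list(v, v, v), p = c(0.001, 0.01, 0.02))
  cons <- consensus_patients(match_groups(defs))
  expect_true(all(cons$assignment != 2L))
  expect_true(all(cons$assignment == v) || all(cons$assignment == 1L - v))
})

test_that("pattern merging labels directions by survival and unions groups", {
  set.seed(46)
  n <- 120L
  fav <- c(rep(1L, 30), rep(0L, 90))
  unf <- c(rep(0L, 90), rep(1L, 30))
  grp <- ifelse(fav == 1, "fav", ifelse(unf == 1, "unf", "rest"))
  st <- generate_survival(grp, c(fav = 0.25, unf = 4, rest = 1),
                          censor_rate = 0.1, seed = 12)
  cons <- list(fav, fav, unf)       # two favorable patterns, one unfavorable
  out <- merge_patterns(cons, st)
  expect_equal(out$direction, c("favorable", "favorable", "unfavorable"))
  expect_equal(which(out$group == "favorable"), which(fav == 1))
  expect_equal(which(out$group == "unfavorable"), which(unf == 1))

  # no screened definitions: explicit empty grouping
  expect_message(empty <- merge_patterns(list(), st), "no screened")
  expect_true(all(empty$group == "rest"))
})

test_that("expression-signature transfer recovers groups across cohorts", {
  set.seed(47)
  g <- 150L; n <- 120L
  grp <- rep(c("favorable", "rest", "unfavorable"), c(30, 60, 30))
  sig_fav <- 1:20; sig_unf <- 21:40
  mk_bulk <- function(n, grp) {
    B <- matrix(rnorm(g * n, mean = 5), g, n,
                dimnames = list(sprintf("g%03d", 1:g),
                                sprintf("p%03d", 1:n)))
    B[sig_fav, grp == "favorable"] <- B[sig_fav, grp == "favorable"] + 3
    B[sig_unf, grp == "unfavorable"] <- B[sig_unf, grp == "unfavorable"] + 3
    B
  }
  btr <- mk_bulk(n, grp)
  grouping <- structure(list(group = grp, direction = character(0),
                             n_conflict = 0L),
                        class = "patient_grouping")
  # self-transfer: test cohort = training cohort
  self <- external_validation(btr, btr, grouping)
  expect_gte(mean(self$group == grp), 0.9)
  # independent cohort with the same signature
  grp2 <- rep(c("favorable", "rest", "unfavorable"), c(20, 40, 20))
  bte <- mk_bulk(80L, grp2)
  tf <- external_validation(btr, bte, grouping)
  expect_gte(mean(tf$group == grp2), 0.75)
  # negative control: no expression signal at all
  b_null_tr <- matrix(rnorm(g * n, mean = 5), g, n,
                      dimnames = dimnames(btr))
  expect_error(external_validation(b_null_tr, bte, grouping),
               "no signature genes")
})

test_that("the full subtyping pipeline recovers a planted grouping", {
  set.seed(48)
  n <- 90L; g <- 40L; cc <- 3L
  planted <- matrix(rbinom(n * cc, 1, 0.5), n, cc)
  G <- array(rnorm(g * cc * n, sd = 0.3), c(g, cc, n))
  shift <- matrix(rnorm(g * cc, sd = 2), g, cc)
  for (k in seq_len(cc)) {
    G[, k, planted[, k] == 1] <- G[, k, planted[, k] == 1] + shift[, k]
  }
  # survival driven by the state of cell type 1
  st <- generate_survival(ifelse(planted[, 1] == 1, "good", "bad"),
                          c(good = 0.25, bad = 1.5), censor_rate = 0.1,
                          seed = 20)
  out <- subtype_patients(G, st, seed = 3)
  expect_s3_class(out$definitions, "tbl_df")
  expect_gt(sum(out$definitions$kept), 0)
  # the favorable/unfavorable split must align with the planted driver state
  drv <- planted[, 1] == 1
  fav <- out$grouping$group == "favorable"
  unf <- out$grouping$group == "unfavorable"
  if (any(fav)) expect_gte(sum(fav & drv) / sum(fav), 0.8)
  if (any(unf)) expect_gte(sum(unf & !drv) / sum(unf), 0.8)
  expect_gt(sum(fav) + sum(unf), 0)
})
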