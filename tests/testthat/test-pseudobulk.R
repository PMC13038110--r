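test_that("log-CPM normalization matches direct arithmetic and is scale invariant", {
  expect_equal(normalize_log_cpm(c(1, 1)), rep(log2(5e5 + 1), 2))
  x <- c(0, 0, 1e6, 0)
  expect_equal(normalize_log_cpm(x), c(0, 0, log2(1e6 + 1), 0))
  set.seed(1)
  y <- rgamma(20, 2)
  expect_equal(normalize_log_cpm(3.7 * y), normalize_log_cpm(y))
  expect_error(normalize_log_cpm(rep(0, 5)), "zero total")
  expect_error(normalize_log_cpm(c(-1, 2)), "non-negative")
})

test_that("Dirichlet proportion draws have the expected moments", {
  expect_equal(sample_proportions(1, simulation_config(seed = 1), n = 10),
               matrix(1, 10, 1))
  cfg_even <- simulation_config(alpha_mode = "even", seed = 2)
  p <- sample_proportions(6, cfg_even, n = 5000)
  expect_equal(dim(p), c(5000, 6))
  expect_equal(rowSums(p), rep(1, 5000), tolerance = 1e-12)
  expect_true(all(abs(colMeans(p) - 1 / 6) < 0.01))

  # dominant mode: the boosted type has Dirichlet mean 7/12
  cfg_dom <- simulation_config(alpha_mode = "dominant", seed = 3)
  pd <- sample_proportions(6, cfg_dom, n = 5000)
  dom_vals <- apply(pd, 1, max)
  expect_true(abs(mean(dom_vals) - 7 / 12) < 0.02)
  expect_error(sample_proportions(0, cfg_even), "at least 1")
})

test_that("pseudobulk counts satisfy the linear reconstruction identity", {
  ref <- split_cells(tiny_reference(), seed = 1)
  pb <- simulate_pseudobulk(ref, "train",
                            simulation_config(n_samples = 40,
                                              cells_per_sample = 200,
                                              seed = 7))
  for (s in seq_len(40)) {
    recon <- pb$G_counts[, , s] %*% pb$p_target[, s]
    expect_lt(max(abs(recon - pb$b_counts[, s])), 1e-9)
  }
  # p_target zeros exactly where the mask is FALSE
  expect_identical(unname(pb$p_target == 0), unname(!pb$type_mask))
  # input space is the normalized log transform of the counts
  expect_equal(pb$b_input[, 1], normalize_log_cpm(pb$b_counts[, 1]))
})

test_that("single-type references give the pseudobulk the type's own profile", {
  ref <- generate_reference(synthetic_spec(
    n_cell_types = 1, n_genes = 80, cells_per_type = 50,
    n_markers_per_type = 5, seed = 6
  ))
  pb <- simulate_pseudobulk(ref, "train",
                            simulation_config(n_samples = 5,
                                              cells_per_sample = 30, seed = 2))
  expect_true(all(pb$p_target == 1))
  for (s in 1:5) {
    expect_equal(pb$b_counts[, s], pb$G_counts[, 1, s])
  }
})

test_that("the mixed-reference share is allocated deterministically", {
  refs <- lapply(1:3, function(i) {
    r <- tiny_reference(seed = 10L + i)
    r$name <- paste0("ref", i)
    split_cells(r, seed = i)
  })
  cfg <- simulation_config(n_samples = 400, cells_per_sample = 60,
                           mixed_reference_fraction = 0.25, seed = 5)
  pb <- simulate_pseudobulk(refs, "train", cfg)
  expect_equal(sum(pb$source == "mixed"), 100)
  expect_setequal(unique(pb$source), c("mixed", "ref1", "ref2", "ref3"))
})

test_that("realized proportions converge to the drawn proportions", {
  ref <- split_cells(tiny_reference(n_types = 6L, n_genes = 60L, cells = 60L),
                     seed = 2)
  pb <- simulate_pseudobulk(ref, "train",
                            simulation_config(n_samples = 50,
                                              cells_per_sample = 2000,
                                              seed = 8))
  l1 <- mean(colSums(abs(pb$p_target - pb$p_drawn)))
  expect_lt(l1, 0.05)
})

test_that("pseudobulk sampling never reaches outside the requested split", {
  # white box: a reference whose held-out cells carry a sentinel gene that
  # train cells never express
  ref <- tiny_reference(n_types = 2L, n_genes = 50L, cells = 40L, seed = 3)
  ref <- split_cells(ref, c(0.5, 0.25, 0.25), seed = 3)
  sentinel <- 1L
  ref$counts[, sentinel] <- 0L
  ref$counts[ref$split != "train", sentinel] <- 1000L
  pb <- simulate_pseudobulk(ref, "train",
                            simulation_config(n_samples = 20,
                                              cells_per_sample = 50, seed = 4))
  expect_true(all(pb$b_counts[sentinel, ] == 0))
  pb_val <- simulate_pseudobulk(ref, "val",
                                simulation_config(n_samples = 10,
                                                  cells_per_sample = 50,
                                                  seed = 4))
  expect_true(all(pb_val$b_counts[sentinel, ] > 0))
})

test_that("pseudobulk simulation is reproducible and validates inputs", {
  ref <- split_cells(tiny_reference(), seed = 1)
  cfg <- simulation_config(n_samples = 10, cells_per_sample = 50, seed = 11)
  pb1 <- simulate_pseudobulk(ref, "train", cfg)
  pb2 <- simulate_pseudobulk(ref, "train", cfg)
  expect_identical(pb1$b_counts, pb2$b_counts)
  expect_identical(pb1$p_target, pb2$p_target)

  ref_missing <- ref
  ref_missing$split[ref_missing$cell_type == "type1"] <- "train"
  ref_missing$split[ref_missing$cell_type == "type1"][1:5] <- "val"
  ref_missing$split[ref_missing$cell_type == "type2"] <- "train"
  ref_missing$split[ref_missing$cell_type == "type3"] <- "train"
  # drop type3 from the val split entirely
  expect_error(
    simulate_pseudobulk(ref_missing, "val",
                        simulation_config(n_samples = 5, seed = 1)),
    "absent from split"
  )
})

test_that("gene subsetting reorders every gene-indexed component", {
  ref <- split_cells(tiny_reference(), seed = 1)
  pb <- simulate_pseudobulk(ref, "train",
                            simulation_config(n_samples = 6,
                                              cells_per_sample = 40, seed = 2))
  genes <- rev(pb$gene_ids[11:30])
  sub <- subset_genes(pb, genes)
  expect_identical(sub$gene_ids, genes)
  expect_equal(sub$b_input[1, ], pb$b_input[match(genes[1], pb$gene_ids), ])
  expect_equal(sub$G_target[5, , 2], pb$G_target[match(genes[5], pb$gene_ids), , 2])
  expect_error(subset_genes(pb, c("absent_gene")), "absent")
})
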