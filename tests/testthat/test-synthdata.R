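test_that("degenerate noise settings give exactly the planted profiles", {
  # penetrance 1, no background, no high-level events: every sample carries
  # exactly its class blocks at +/-1
  cfg <- simulation_config(n_classes = 2, samples_per_class = 6, n_genes = 80,
                           blocks_per_class = 2, block_size = 5,
                           penetrance = 1, high_level_fraction = 0,
                           background_rate = 0, seed = 3)
  sim <- simulate_cohort(cfg)
  m <- unclass(sim$cohort$matrix)
  for (cl in sim$cohort$class_names) {
    gt <- sim$ground_truth[[cl]]
    rows <- m[sim$cohort$labels == cl, , drop = FALSE]
    expect_true(all(rows[, gt$gene] == rep(gt$sign, each = nrow(rows))))
    off <- setdiff(colnames(m), gt$gene)
    expect_true(all(rows[, off] == 0))
  }

  # penetrance 0 and background 0: all-zero matrix
  sim0 <- simulate_cohort(simulation_config(n_classes = 2,
                                            samples_per_class = 4,
                                            n_genes = 60, penetrance = 0,
                                            background_rate = 0, seed = 1))
  expect_true(all(unclass(sim0$cohort$matrix) == 0))
})

test_that("all values are five-level calls and seeds reproduce cohorts", {
  cfg <- simulation_config(seed = 17)
  sim1 <- simulate_cohort(cfg)
  expect_true(all(unclass(sim1$cohort$matrix) %in% -2:2))
  sim2 <- simulate_cohort(cfg)
  expect_identical(sim1$cohort$matrix, sim2$cohort$matrix)
  sim3 <- simulate_cohort(simulation_config(seed = 18))
  expect_false(identical(sim1$cohort$matrix, sim3$cohort$matrix))
})

test_that("off-block nonzero rate matches the background rate (binomial)", {
  cfg <- simulation_config(n_classes = 3, samples_per_class = 40,
                           n_genes = 500, blocks_per_class = 2,
                           block_size = 10, penetrance = 0.9,
                           background_rate = 0.02, seed = 7)
  sim <- simulate_cohort(cfg)
  planted <- unlist(lapply(sim$ground_truth, function(d) d$gene))
  off <- unclass(sim$cohort$matrix)[, setdiff(colnames(sim$cohort$matrix),
                                              planted)]
  rate <- mean(off != 0)
  se <- sqrt(0.02 * 0.98 / length(off))
  expect_lt(abs(rate - 0.02), 3 * se)
})

test_that("planted signal dominates background in carriers", {
  sim <- simulate_cohort(simulation_config(seed = 21)) # pen .9 > bg .02
  m <- unclass(sim$cohort$matrix)
  planted <- unlist(lapply(sim$ground_truth, function(d) d$gene))
  for (cl in sim$cohort$class_names) {
    rows <- m[sim$cohort$labels == cl, , drop = FALSE]
    on_mean <- mean(abs(rows[, sim$ground_truth[[cl]]$gene]))
    off_mean <- mean(abs(rows[, setdiff(colnames(m), planted)]))
    expect_gt(on_mean, off_mean)
  }
})

test_that("subtype structure is assigned and planted as specified", {
  spec <- list(class1 = list(
    list(name = "st_a", fraction = 0.5,
         blocks = list(list(start = 1, size = 5, sign = 1))),
    list(name = "st_b", fraction = 0.5,
         # a co-deletion pair: two loss blocks planted together
         blocks = list(list(start = 21, size = 5, sign = -1),
                       list(start = 31, size = 5, sign = -1)))))
  cfg <- simulation_config(n_classes = 2, samples_per_class = 40,
                           n_genes = 200, blocks_per_class = 1,
                           block_size = 5, penetrance = 0.8,
                           background_rate = 0, high_level_fraction = 0,
                           subtype_spec = spec, seed = 13)
  sim <- simulate_cohort(cfg)
  st <- subtype_labels(sim)
  expect_identical(as.integer(table(st)[c("st_a", "st_b")]), c(20L, 20L))

  # each co-deletion block is carried independently at the penetrance rate
  m <- unclass(sim$cohort$matrix)
  b_ids <- names(st)[st == "st_b"]
  carried1 <- m[b_ids, "g0021"] != 0
  carried2 <- m[b_ids, "g0031"] != 0
  se <- sqrt(0.8 * 0.2 / length(b_ids))
  expect_lt(abs(mean(carried1) - 0.8), 3 * se)
  expect_lt(abs(mean(carried2) - 0.8), 3 * se)
  expect_lt(abs(mean(carried1 & carried2) - 0.64),
            3 * sqrt(0.64 * 0.36 / length(b_ids)))

  # no subtype_spec: asking for subtype labels is an error
  plain <- simulate_cohort(simulation_config(n_genes = 60, seed = 1))
  expect_error(subtype_labels(plain), "without a subtype_spec")
})

test_that("overlapping planted blocks are rejected", {
  spec <- list(class1 = list(
    list(name = "bad", fraction = 1,
         blocks = list(list(start = 84, size = 20, sign = 1)))))
  cfg <- simulation_config(n_classes = 2, samples_per_class = 4,
                           n_genes = 200, blocks_per_class = 1,
                           block_size = 10, subtype_spec = spec, seed = 1)
  # class2's auto block starts at gene 101; the subtype block reaches it
  expect_error(simulate_cohort(cfg), "overlap")
})

test_that("simulated cohorts round-trip through the on-disk artifact set", {
  sim <- simulate_cohort(simulation_config(n_classes = 2,
                                           samples_per_class = 5,
                                           n_genes = 60, seed = 2))
  dir <- withr::local_tempdir()
  paths <- write_simulated_cohort(sim, dir)
  expect_equal(read_cna_matrix(paths["matrix"]), sim$cohort$matrix)
  expect_identical(read_labels(paths["labels"]), sim$cohort$labels)
  gt <- jsonlite::read_json(paths["ground_truth"], simplifyVector = TRUE)
  expect_identical(gt$ground_truth$class1$genes,
                   sim$ground_truth$class1$gene)
})
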