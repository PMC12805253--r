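small_cohort <- function(seed = 2, n = 25, classes = 2, genes = 40) {
  sim <- simulate_cohort(simulation_config(n_classes = classes,
                                           samples_per_class = n,
                                           n_genes = genes, block_size = 5,
                                           seed = seed))
  sim$cohort
}

test_that("epoch partition chunks classes into bags with the remainder rule", {
  co <- small_cohort(n = 25, classes = 1)
  # a one-class cohort is not classifiable, but bag construction is generic
  bags <- make_bags(co, 10, seed = 1, mode = "epoch_partition")
  expect_identical(sort(vapply(bags, function(b) nrow(b$profiles), integer(1)),
                        decreasing = TRUE), c(10L, 10L, 5L))
  # remainder of 1 is dropped for the epoch
  co21 <- small_cohort(n = 21, classes = 1)
  bags21 <- make_bags(co21, 10, seed = 1, mode = "epoch_partition")
  expect_identical(vapply(bags21, function(b) nrow(b$profiles), integer(1)),
                   c(10L, 10L))
  # bags are homogeneous and cover each sample once
  co2 <- small_cohort(n = 12, classes = 3)
  bags2 <- make_bags(co2, 5, seed = 3, mode = "epoch_partition")
  for (b in bags2) {
    expect_length(unique(co2$labels[b$sample_ids]), 1)
    expect_identical(unique(co2$labels[b$sample_ids]),
                     co2$class_names[b$label])
  }
  ids <- unlist(lapply(bags2, function(b) b$sample_ids))
  expect_identical(sort(ids), sort(rownames(co2$matrix)))
})

test_that("resampled bags are deterministic and sized K without replacement", {
  co <- small_cohort(n = 15, classes = 2)
  b1 <- make_bags(co, 6, seed = 4, mode = "resample", bags_per_class = 5)
  b2 <- make_bags(co, 6, seed = 4, mode = "resample", bags_per_class = 5)
  expect_identical(lapply(b1, `[[`, "sample_ids"),
                   lapply(b2, `[[`, "sample_ids"))
  expect_length(b1, 10)
  for (b in b1) {
    expect_identical(nrow(b$profiles), 6L)
    expect_false(anyDuplicated(b$sample_ids) > 0)
  }
})

test_that("zero learning rate leaves parameters unchanged", {
  co <- small_cohort()
  fit <- train_mil(co, M = 8, L = 4,
                   config = train_config(learning_rate = 0, epochs = 2,
                                         seed = 5))
  fresh <- mil_params_init(colnames(co$matrix), co$class_names, M = 8, L = 4,
                           seed = derive_seed(5, "init"), init_sd = 0.01)
  expect_equal(fit$params$W1, fresh$W1, ignore_attr = TRUE)
  expect_equal(fit$params$Wc, fresh$Wc, ignore_attr = TRUE)
})

test_that("a freshly initialized model starts near the uniform-loss bound", {
  co <- small_cohort(classes = 2)
  fit <- train_mil(co, M = 8, L = 4,
                   config = train_config(learning_rate = 0, epochs = 1,
                                         seed = 6))
  expect_lt(fit$log$train_loss[1], log(2) + 0.05)
})

test_that("training is deterministic given the config seed", {
  co <- small_cohort()
  cfg <- train_config(epochs = 3, seed = 7)
  f1 <- train_mil(co, M = 8, L = 4, config = cfg)
  f2 <- train_mil(co, M = 8, L = 4, config = cfg)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$params$W1, f2$params$W1)
})

test_that("full-batch gradient descent at a small step never increases loss", {
  co <- small_cohort(n = 10, genes = 20)
  bags <- make_bags(co, 5, seed = 8, mode = "epoch_partition")
  p <- mil_params_init(colnames(co$matrix), co$class_names, M = 6, L = 3,
                       seed = 9, init_sd = 0.3)
  mean_loss <- function(p) {
    mean(vapply(bags, function(b) {
      cnamil:::mil_backward(p, b$profiles, b$label)$loss
    }, numeric(1)))
  }
  lr <- 1e-4
  losses <- numeric(6)
  losses[1] <- mean_loss(p)
  for (it in 1:5) {
    gsum <- NULL
    for (b in bags) {
      g <- cnamil:::mil_backward(p, b$profiles, b$label)$grads
      gsum <- if (is.null(gsum)) g else Map(`+`, gsum, g)
    }
    for (nm in cnamil:::param_names()) {
      p[[nm]] <- p[[nm]] - lr * gsum[[nm]] / length(bags)
    }
    losses[it + 1] <- mean_loss(p)
  }
  expect_true(all(diff(losses) <= 0))
})

test_that("attention concentrates on typical instances of a class", {
  # typical = carries all its class blocks; atypical = misses at least one
  sim <- simulate_cohort(simulation_config(penetrance = 0.75,
                                           background_rate = 0.01, seed = 31))
  co <- sim$cohort
  fit <- train_mil(co, M = 32, L = 16,
                   config = train_config(epochs = 20, seed = 31))
  m <- unclass(co$matrix)
  typical <- vapply(rownames(m), function(id) {
    gt <- sim$ground_truth[[co$labels[id]]]
    all(m[id, gt$gene] != 0)
  }, logical(1))
  att_typ <- c(); att_aty <- c()
  for (s in 1:10) {
    bags <- make_bags(co, 10, seed = s, mode = "resample", bags_per_class = 4)
    for (b in bags) {
      out <- classify_bag(fit$params, b)
      is_typ <- typical[b$sample_ids]
      att_typ <- c(att_typ, out$attention[is_typ])
      att_aty <- c(att_aty, out$attention[!is_typ])
    }
  }
  expect_gt(mean(att_typ), mean(att_aty))
})

test_that("evaluation reports the contractual accuracies and confusion", {
  sim <- simulate_cohort(simulation_config(penetrance = 1,
                                           background_rate = 0,
                                           high_level_fraction = 0,
                                           samples_per_class = 20,
                                           n_genes = 120, seed = 41))
  co <- sim$cohort
  fit <- train_mil(co, M = 16, L = 8, config = train_config(epochs = 25,
                                                            seed = 41))
  rep <- evaluate_mil(fit$params, co, K = 10, seed = 42)
  # noise-free planted cohort: a trained model is a perfect predictor
  expect_equal(rep$bag_accuracy, 1)
  expect_equal(rep$instance_accuracy, 1)
  expect_equal(unname(rep$confusion), diag(3))
  expect_equal(unname(rowSums(rep$confusion)), rep(1, 3), tolerance = 1e-6)

  # an untrained uniform predictor assigns instances at chance level
  p0 <- mil_params_init(colnames(co$matrix), co$class_names, M = 16, L = 8,
                        seed = 43, init_sd = 0)
  rep0 <- evaluate_mil(p0, co, K = 10, seed = 44)
  se <- sqrt((1 / 3) * (2 / 3) / nrow(co$matrix))
  expect_lt(abs(rep0$instance_accuracy - 1 / 3), 3 * se)
  expect_equal(unname(rowSums(rep0$confusion)), rep(1, 3), tolerance = 1e-6)
})
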