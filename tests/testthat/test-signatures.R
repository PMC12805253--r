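trained_fixture <- function(seed = 51) {
  sim <- simulate_cohort(simulation_config(penetrance = 0.95,
                                           background_rate = 0.01,
                                           samples_per_class = 20,
                                           n_genes = 120, seed = seed))
  fit <- train_mil(sim$cohort, M = 16, L = 8,
                   config = train_config(epochs = 20, seed = seed))
  list(sim = sim, fit = fit)
}

test_that("instance predictions obey the attention-normalization contract", {
  fx <- trained_fixture()
  bags <- make_bags(fx$sim$cohort, 8, seed = 1, mode = "epoch_partition")
  preds <- instance_predictions(fx$fit$params, bags)
  phat_cols <- grep("^phat_", names(preds))
  p_cols <- grep("^p_", names(preds)) # raw singleton probabilities
  # per bag, the normalized weighted scores sum to 1
  for (b in unique(preds$bag)) {
    expect_equal(sum(preds[preds$bag == b, phat_cols]), 1, tolerance = 1e-6)
  }
  # phat = attention * p, and argmax is preserved by the positive scaling
  expect_equal(as.matrix(preds[phat_cols]),
               as.matrix(preds[p_cols]) * preds$attention,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(preds$predicted_class,
                   max.col(as.matrix(preds[p_cols]), ties.method = "first"))

  # bag of identical instances: equal attention, equal phat rows
  one <- fx$sim$cohort$matrix[rep(1, 4), , drop = FALSE]
  rownames(one) <- paste0("dup", 1:4)
  pd <- instance_predictions(fx$fit$params, mil_bag(one, label = 1))
  expect_equal(pd$attention, rep(0.25, 4), tolerance = 1e-9)
  expect_equal(var(pd[[phat_cols[1]]]), 0, tolerance = 1e-18)

  # singleton bag: weight 1 and phat equals the raw probabilities
  single <- instance_predictions(fx$fit$params,
                                 mil_bag(one[1, , drop = FALSE], label = 1))
  expect_equal(single$attention, 1)
  expect_equal(unlist(single[phat_cols]), unlist(single[p_cols]),
               ignore_attr = TRUE)
})

test_that("instance accuracy counts correct argmax predictions", {
  preds <- data.frame(sample_id = c("a", "b", "c", "d"),
                      predicted_class = c(1L, 1L, 2L, 2L),
                      phat_x = c(0.9, 0.8, 0.1, 0.2),
                      phat_y = c(0.1, 0.2, 0.9, 0.8))
  labels <- c(a = "x", b = "x", c = "y", d = "y")
  expect_equal(instance_accuracy(preds, labels), 1)
  labels["d"] <- "x"
  expect_equal(instance_accuracy(preds, labels), 0.75)
  # invariant under reordering
  expect_equal(instance_accuracy(preds[c(3, 1, 4, 2), ], labels), 0.75)
  expect_error(instance_accuracy(preds[0, ], labels), "no predictions")
})

test_that("feature projection computes the stated attribution by hand", {
  # single instance predicted as class 1 with phat = 0.5; values 2 and -1
  preds <- data.frame(sample_id = "s1", bag = 1, attention = 1,
                      predicted_class = 1L, phat_A = 0.5, phat_B = 0.5)
  profiles <- matrix(c(2, -1, 0), 1, 3,
                     dimnames = list("s1", c("gA", "gB", "gC")))
  s <- project_to_features(preds, profiles, 1, "per_class_max")
  expect_equal(unname(s), c(1.0, -0.5, 0))
  # diploid gene (x = 0) always scores 0
  expect_equal(s[["gC"]], 0)
  # l1 normalization: |scores| sum to 1
  s_l1 <- project_to_features(preds, profiles, 1, "l1")
  expect_equal(sum(abs(s_l1)), 1)
  # no instance predicted as the class: zero vector with a warning
  expect_warning(z <- project_to_features(preds, profiles, 2), "no instance")
  expect_equal(unname(z), c(0, 0, 0))
})

test_that("planted-block genes outscore background genes on simulation", {
  fx <- trained_fixture(seed = 53)
  co <- fx$sim$cohort
  bags <- make_bags(co, 8, seed = 2, mode = "epoch_partition")
  preds <- instance_predictions(fx$fit$params, bags)
  for (k in seq_along(co$class_names)) {
    s <- project_to_features(preds, co$matrix, k)
    gt <- fx$sim$ground_truth[[co$class_names[k]]]
    on_block <- abs(s[gt$gene])
    off_block <- abs(s[setdiff(names(s), unlist(lapply(fx$sim$ground_truth,
                                                       `[[`, "gene")))])
    expect_gt(min(on_block), max(off_block))
    # score signs follow the planted gain/loss directions
    expect_true(all(sign(s[gt$gene]) == gt$sign))
  }
})

test_that("signature extraction ranks by magnitude with stated tie-breaks", {
  scores <- list(k1 = c(A = 0.9, B = -0.9, C = 0.1))
  sig <- extract_signature(scores, N = 2)
  expect_identical(sig$top_genes$gene, c("A", "B")) # tie broken by gene id
  expect_identical(sig$top_genes$direction, c("dup", "del"))
  expect_identical(sig$top_genes$rank, 1:2)
  # N = gene count keeps everything; larger N warns and truncates
  expect_identical(extract_signature(scores, N = 3)$top_genes$gene,
                   c("A", "B", "C"))
  expect_warning(sig_all <- extract_signature(scores, N = 5), "exceeds")
  expect_identical(nrow(sig_all$top_genes), 3L)
  # idempotent and deterministic
  expect_identical(extract_signature(scores, N = 2), sig)
})

test_that("signatures round-trip through the TSV interface", {
  scores <- cbind(k1 = c(A = 0.52, B = -0.11), k2 = c(A = 0, B = 0.4))
  sig <- extract_signature(scores, N = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_signatures(sig, f, header = "test stamp")
  back <- read_signatures(f)
  expect_equal(back$score, sig$top_genes$score, tolerance = 1e-12)
  expect_identical(back$gene, sig$top_genes$gene)
})

test_that("per-class signatures recover planted blocks end to end", {
  # noise-light cohorts: per-class top genes should be disjoint and match
  # the planted blocks closely (Jaccard to ground truth, 3-seed average)
  jac <- c()
  for (s in 61:63) {
    sim <- simulate_cohort(simulation_config(penetrance = 0.95,
                                             background_rate = 0.01,
                                             seed = s))
    fit <- train_mil(sim$cohort, M = 32, L = 16,
                     config = train_config(epochs = 25, seed = s))
    bags <- make_bags(sim$cohort, 10, seed = s, mode = "epoch_partition")
    preds <- instance_predictions(fit$params, bags)
    scores <- sapply(seq_along(sim$cohort$class_names), function(k) {
      project_to_features(preds, sim$cohort$matrix, k)
    })
    colnames(scores) <- sim$cohort$class_names
    sig <- extract_signature(scores, N = 20)
    gene_sets <- lapply(sim$cohort$class_names,
                        function(cl) signature_genes(sig, cl))
    # pairwise disjoint
    expect_length(Reduce(intersect, gene_sets), 0)
    jac <- c(jac, mapply(function(gs, cl) {
      signature_jaccard(gs, sim$ground_truth[[cl]]$gene)
    }, gene_sets, sim$cohort$class_names))
  }
  expect_gte(mean(jac), 0.8)
})

test_that("gradient-times-input attribution agrees on planted blocks", {
  fx <- trained_fixture(seed = 55)
  co <- fx$sim$cohort
  bags <- make_bags(co, 8, seed = 3, mode = "epoch_partition")
  preds <- instance_predictions(fx$fit$params, bags)
  s_grad <- project_gradient_input(fx$fit$params, preds, co$matrix, 1)
  gt <- fx$sim$ground_truth[[co$class_names[1]]]
  top <- names(sort(abs(s_grad), decreasing = TRUE))[seq_len(nrow(gt))]
  expect_gte(mean(top %in% gt$gene), 0.8)
})
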