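#' Training configuration for the MIL classifier
#'
#' @param bag_size Instances per training bag (K >= 2).
#' @param bags_per_class_per_epoch Bags drawn per class per epoch in
#'   `"resample"` mode.
#' @param epochs Maximum training epochs.
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty coefficient applied to weight matrices
#'   and the attention projection (not to biases).
#' @param seed Integer seed; epoch-level bag draws use seeds derived from
#'   it, so the whole run is reproducible.
#' @param class_balancing `"equal_bags"` draws the same number of bags
#'   per class regardless of class size (equalized exposure is the safer
#'   default under strong class imbalance, where rare classes are the
#'   ones that suffer); `"proportional"` draws bags in proportion to
#'   class size.
#' @param early_stop_patience Stop when held-out bag NLL has not improved
#'   for this many epochs (only when a validation cohort is supplied).
#' @param mode Bag construction per epoch: `"resample"` (default) or
#'   `"epoch_partition"`; see [make_bags()].
#' @param init_sd Weight initialization scale.
#' @return A list of class `train_config`.
#' @export
train_config <- function(bag_size = 10, bags_per_class_per_epoch = 8,
                         epochs = 50, learning_rate = 1e-3,
                         weight_decay = 1e-4, seed = 1,
                         class_balancing = c("equal_bags", "proportional"),
                         early_stop_patience = 10,
                         mode = c("resample", "epoch_partition"),
                         init_sd = 0.01) {
  class_balancing <- match.arg(class_balancing)
  mode <- match.arg(mode)
  stopifnot(bag_size >= 2, learning_rate >= 0, epochs >= 1, weight_decay >= 0)
  structure(list(bag_size = bag_size,
                 bags_per_class_per_epoch = bags_per_class_per_epoch,
                 epochs = epochs, learning_rate = learning_rate,
                 weight_decay = weight_decay, seed = seed,
                 class_balancing = class_balancing,
                 early_stop_patience = early_stop_patience, mode = mode,
                 init_sd = init_sd),
            class = "train_config")
}

#' Build homogeneous bags from a labeled cohort
#'
#' Every bag contains instances of a single class and carries that class
#' as its label. `"epoch_partition"`: per class, shuffle the samples and
#' chunk into bags of `K`; a remainder of at least 2 samples is kept as a
#' smaller bag, a remainder of 1 is dropped for this epoch.
#' `"resample"`: draw `bags_per_class` bags of `K` samples each, sampled
#' without replacement within each bag (bags may overlap). A class with
#' fewer than `K` samples contributes whole-class bags. Deterministic
#' given `seed`; classes with a single sample are excluded with a
#' warning.
#'
#' @param cohort A [labeled_cohort()].
#' @param K Bag size.
#' @param seed Integer seed.
#' @param mode `"epoch_partition"` or `"resample"`.
#' @param bags_per_class Bags per class in `"resample"` mode (scalar or
#'   per-class vector in `class_names` order).
#' @return List of [mil_bag()]s with integer labels (positions in
#'   `class_names`).
#' @export
make_bags <- function(cohort, K, seed = 1,
                      mode = c("epoch_partition", "resample"),
                      bags_per_class = 8) {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "labeled_cohort"), K >= 1)
  x <- unclass(cohort$matrix)
  storage.mode(x) <- "numeric"
  if (length(bags_per_class) == 1) {
    bags_per_class <- rep(bags_per_class, length(cohort$class_names))
  }
  bags <- list()
  with_seed(seed, {
    for (ci in seq_along(cohort$class_names)) {
      cl <- cohort$class_names[ci]
      ids <- rownames(x)[cohort$labels == cl]
      if (length(ids) == 0) next
      if (length(ids) == 1) {
        warning("class '", cl, "' has a single sample; no bag formed")
        next
      }
      if (mode == "epoch_partition") {
        ids <- ids[sample.int(length(ids))]
        starts <- seq(1, length(ids), by = K)
        for (s in starts) {
          chunk <- ids[s:min(s + K - 1, length(ids))]
          if (length(chunk) < 2) next # singleton remainder dropped
          bags[[length(bags) + 1]] <-
            mil_bag(x[chunk, , drop = FALSE], chunk, label = ci)
        }
      } else {
        k_eff <- min(K, length(ids))
        for (b in seq_len(bags_per_class[ci])) {
          chunk <- sample(ids, k_eff)
          bags[[length(bags) + 1]] <-
            mil_bag(x[chunk, , drop = FALSE], chunk, label = ci)
        }
      }
    }
  })
  bags
}

adam_init <- function(params) {
  lapply(params[param_names()], function(p) {
    list(m = p * 0, v = p * 0)
  })
}

adam_step <- function(params, grads, state, lr, wd, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  decayed <- c("W1", "W2", "V", "U", "w", "Wc")
  for (nm in param_names()) {
    g <- grads[[nm]]
    if (nm %in% decayed && wd > 0) g <- g + wd * params[[nm]]
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

#' Train the attention-based MIL classifier
#'
#' Minimizes the mean multinomial bag negative log-likelihood by Adam,
#' one gradient step per bag, over bags regenerated each epoch with
#' epoch-derived seeds. When a validation cohort is given, held-out bag
#' NLL and accuracy are logged each epoch and early stopping returns the
#' best parameters seen. Deterministic given the config seed.
#'
#' @param cohort Training [labeled_cohort()]; if `selected_genes` is
#'   given the matrix is subset to those columns first.
#' @param selected_genes Optional gene subset (e.g. from
#'   [rfecv_select()]).
#' @param M,L Embedding and attention widths.
#' @param config A [train_config()].
#' @param validation Optional held-out [labeled_cohort()] for logging and
#'   early stopping.
#' @return A list of class `mil_fit`: `params` (a `mil_model_params`),
#'   and `log`, a data frame with per-epoch `train_loss`, `val_loss`,
#'   `val_bag_accuracy`.
#' @export
train_mil <- function(cohort, selected_genes = NULL, M = 64, L = 32,
                      config = train_config(), validation = NULL) {
  stopifnot(inherits(cohort, "labeled_cohort"), inherits(config, "train_config"))
  if (!is.null(selected_genes)) {
    cohort <- labeled_cohort(apply_selection(cohort$matrix, selected_genes),
                             cohort$labels, cohort$class_names)
    if (!is.null(validation)) {
      validation <- labeled_cohort(
        apply_selection(validation$matrix, selected_genes),
        validation$labels, validation$class_names)
    }
  }
  genes <- colnames(cohort$matrix)
  params <- mil_params_init(genes, cohort$class_names, M = M, L = L,
                            seed = derive_seed(config$seed, "init"),
                            init_sd = config$init_sd)
  state <- adam_init(params)
  t_step <- 0
  class_sizes <- as.numeric(table(factor(cohort$labels,
                                         levels = cohort$class_names)))
  bpc <- if (config$class_balancing == "equal_bags") {
    config$bags_per_class_per_epoch
  } else {
    pmax(1, ceiling(config$bags_per_class_per_epoch * length(class_sizes) *
                      class_sizes / sum(class_sizes)))
  }

  log_rows <- vector("list", config$epochs)
  best_val <- Inf
  best_params <- params
  stale <- 0
  for (epoch in seq_len(config$epochs)) {
    ep_seed <- derive_seed(config$seed, paste0("epoch", epoch))
    bags <- make_bags(cohort, config$bag_size, seed = ep_seed,
                      mode = config$mode, bags_per_class = bpc)
    ord <- with_seed(derive_seed(config$seed, paste0("order", epoch)),
                     sample.int(length(bags)))
    losses <- numeric(length(bags))
    for (i in seq_along(ord)) {
      bag <- bags[[ord[i]]]
      bk <- mil_backward(params, bag$profiles, bag$label)
      if (!is.finite(bk$loss)) {
        stop("training diverged (non-finite loss) at epoch ", epoch,
             ", bag ", i)
      }
      losses[i] <- bk$loss
      t_step <- t_step + 1
      upd <- adam_step(params, bk$grads, state, config$learning_rate,
                       config$weight_decay, t_step)
      params <- upd$params
      state <- upd$state
    }
    val_loss <- NA_real_
    val_acc <- NA_real_
    if (!is.null(validation)) {
      vb <- make_bags(validation, config$bag_size,
                      seed = derive_seed(config$seed, "validation"),
                      mode = "epoch_partition")
      vres <- vapply(vb, function(b) {
        out <- classify_bag(params, b)
        c(bag_nll(out$bag_probs, b$label),
          as.numeric(which.max(out$bag_probs) == b$label))
      }, numeric(2))
      val_loss <- mean(vres[1, ])
      val_acc <- mean(vres[2, ])
      if (val_loss < best_val - 1e-8) {
        best_val <- val_loss
        best_params <- params
        stale <- 0
      } else {
        stale <- stale + 1
      }
    }
    log_rows[[epoch]] <- data.frame(epoch = epoch, train_loss = mean(losses),
                                    val_loss = val_loss,
                                    val_bag_accuracy = val_acc)
    if (!is.null(validation) && stale >= config$early_stop_patience) break
  }
  final <- if (is.null(validation)) params else best_params
  structure(list(params = final,
                 log = do.call(rbind, log_rows[!vapply(log_rows, is.null,
                                                       logical(1))])),
            class = "mil_fit")
}

#' @export
print.mil_fit <- function(x, ...) {
  n <- nrow(x$log)
  cat("<mil_fit> ", n, " epochs, final train loss ",
      sprintf("%.4f", x$log$train_loss[n]), sep = "")
  if (!is.na(x$log$val_bag_accuracy[n])) {
    cat(", best val loss ", sprintf("%.4f", min(x$log$val_loss)), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Evaluate a trained model on a cohort
#'
#' Reports bag-level accuracy (argmax of [classify_bag()] over
#' deterministic epoch-partition bags), instance-level accuracy (argmax
#' of attention-normalized per-instance predictions, see
#' [instance_predictions()]), and the instance-level confusion matrix:
#' row r, column c is the fraction of samples of true class r assigned to
#' class c, so rows sum to 1.
#'
#' @param params A trained `mil_model_params`.
#' @param cohort A [labeled_cohort()] restricted to the model's genes.
#' @param K Bag size used for evaluation bags.
#' @param seed Seed for the bag partition.
#' @return A list of class `eval_report`: `bag_accuracy`,
#'   `instance_accuracy`, `confusion` (C x C row-stochastic matrix),
#'   `predictions` (the [instance_predictions()] data frame).
#' @export
evaluate_mil <- function(params, cohort, K = 10, seed = 1) {
  stopifnot(inherits(params, "mil_model_params"),
            inherits(cohort, "labeled_cohort"))
  if (!identical(colnames(cohort$matrix), params$genes)) {
    cohort <- labeled_cohort(apply_selection(cohort$matrix, params$genes),
                             cohort$labels, cohort$class_names)
  }
  bags <- make_bags(cohort, K, seed = seed, mode = "epoch_partition")
  bag_correct <- vapply(bags, function(b) {
    out <- classify_bag(params, b)
    as.numeric(which.max(out$bag_probs) == b$label)
  }, numeric(1))
  preds <- instance_predictions(params, bags)
  truth <- cohort$labels[preds$sample_id]
  pred_cls <- params$class_names[preds$predicted_class]
  C <- length(params$class_names)
  conf <- matrix(0, C, C,
                 dimnames = list(params$class_names, params$class_names))
  tab <- table(factor(truth, levels = params$class_names),
               factor(pred_cls, levels = params$class_names))
  counts <- rowSums(tab)
  nonzero <- counts > 0
  conf[nonzero, ] <- sweep(unclass(tab)[nonzero, , drop = FALSE], 1,
                           counts[nonzero], "/")
  structure(list(bag_accuracy = mean(bag_correct),
                 instance_accuracy = mean(pred_cls == truth),
                 confusion = conf, predictions = preds),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> bag accuracy %.3f, instance accuracy %.3f\n",
              x$bag_accuracy, x$instance_accuracy))
  invisible(x)
}
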