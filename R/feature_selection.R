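#' Configuration for recursive feature elimination with cross-validation
#'
#' @param estimator `"linear_multiclass"` (ridge-penalized multinomial
#'   logistic regression via \pkg{glmnet}; per-feature importance is the
#'   sum over classes of absolute coefficients) or `"tree_ensemble"`
#'   (random forest via \pkg{ranger}; impurity importance).
#' @param scoring `"balanced_accuracy"` (mean per-class recall; guards
#'   against the strong class imbalance of pan-cancer cohorts, where class
#'   sizes span more than an order of magnitude) or `"accuracy"`.
#' @param n_folds Stratified cross-validation folds (>= 2).
#' @param step_fraction Fraction of remaining features eliminated per
#'   round, in (0, 1).
#' @param min_features Smallest feature count evaluated on the path.
#' @param seed Integer seed controlling fold assignment and the tree
#'   ensemble.
#' @return A list of class `rfecv_config`.
#' @export
rfecv_config <- function(estimator = c("linear_multiclass", "tree_ensemble"),
                         scoring = c("balanced_accuracy", "accuracy"),
                         n_folds = 5, step_fraction = 0.1, min_features = 1,
                         seed = 1) {
  estimator <- match.arg(estimator)
  scoring <- match.arg(scoring)
  stopifnot(n_folds >= 2, step_fraction > 0, step_fraction < 1,
            min_features >= 1)
  structure(list(estimator = estimator, scoring = scoring, n_folds = n_folds,
                 step_fraction = step_fraction, min_features = min_features,
                 seed = seed),
            class = "rfecv_config")
}

# Stratified fold ids: per class, shuffle then deal round-robin.
# Depends only on seed, labels and sample order.
stratified_folds <- function(y, n_folds, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

# Estimator backends. Each returns list(predict(newx) -> labels,
# importance -> per-feature nonnegative score). A single-column matrix is
# padded with a zero dummy column for glmnet, whose coefficient is inert.
fit_estimator <- function(x, y, estimator, seed) {
  y <- factor(y)
  if (estimator == "linear_multiclass") {
    pad <- ncol(x) < 2
    xx <- if (pad) cbind(x, `.dummy` = 0) else x
    fit <- glmnet::glmnet(xx, y, family = "multinomial", alpha = 0,
                          lambda = 0.05, thresh = 1e-5, standardize = FALSE)
    coefs <- glmnet::coef.glmnet(fit, s = 0.05)
    imp <- Reduce(`+`, lapply(coefs, function(b) abs(as.numeric(b)[-1])))
    if (pad) imp <- imp[1]
    list(predict = function(newx) {
      nx <- if (pad) cbind(newx, `.dummy` = 0) else newx
      as.character(predict(fit, nx, s = 0.05, type = "class"))
    }, importance = imp)
  } else {
    df <- data.frame(.y = y, x, check.names = FALSE)
    fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                          num.trees = 200, importance = "impurity",
                          seed = seed, num.threads = 1)
    list(predict = function(newx) {
      as.character(predict(fit, data.frame(newx, check.names = FALSE),
                           num.threads = 1)$predictions)
    }, importance = unname(fit$variable.importance))
  }
}

score_predictions <- function(truth, pred, scoring) {
  if (scoring == "accuracy") return(mean(pred == truth))
  recalls <- vapply(unique(truth),
                    function(cl) mean(pred[truth == cl] == cl), numeric(1))
  mean(recalls)
}

# Mean stratified-CV score of a feature subset.
cv_score <- function(x, y, folds, estimator, scoring, seed) {
  scores <- vapply(sort(unique(folds)), function(f) {
    fit <- fit_estimator(x[folds != f, , drop = FALSE], y[folds != f],
                         estimator, seed)
    score_predictions(y[folds == f], fit$predict(x[folds == f, , drop = FALSE]),
                      scoring)
  }, numeric(1))
  mean(scores)
}

#' Recursive feature elimination with cross-validation
#'
#' Iteratively removes the least relevant gene features: each round fits
#' the estimator on the full cohort to rank features by importance,
#' records the mean stratified cross-validated score of the current
#' feature set, and drops the lowest-ranked
#' `ceiling(step_fraction * remaining)` features, down to `min_features`.
#' The selected set is the evaluated feature set with the maximal mean CV
#' score; ties break toward fewer features (parsimony).
#'
#' Feature selection is meant to run on the training split only; pass the
#' training part of [split_cohort()].
#'
#' @param cohort A [labeled_cohort()] with at least `n_folds` samples per
#'   class.
#' @param config An [rfecv_config()].
#' @return A list of class `rfecv_result`:
#'   \describe{
#'     \item{selected_genes}{kept gene ids, in matrix column order}
#'     \item{score_path}{data frame of `n_features`, `mean_cv_score` per
#'       evaluated round}
#'     \item{ranking}{named integer vector gene -> elimination round
#'       (1 = dropped first; kept genes share the final round)}
#'   }
#' @export
rfecv_select <- function(cohort, config = rfecv_config()) {
  stopifnot(inherits(cohort, "labeled_cohort"),
            inherits(config, "rfecv_config"))
  x <- unclass(cohort$matrix)
  storage.mode(x) <- "numeric"
  y <- unname(cohort$labels)
  sizes <- table(y)
  if (any(sizes < config$n_folds)) {
    stop("every class needs at least n_folds = ", config$n_folds,
         " samples; smallest has ", min(sizes))
  }
  genes <- colnames(x)
  folds <- stratified_folds(y, config$n_folds, config$seed)

  if (config$min_features >= length(genes)) {
    warning("min_features >= number of features; selection is a no-op")
    sc <- cv_score(x, y, folds, config$estimator, config$scoring, config$seed)
    return(structure(list(
      selected_genes = genes,
      score_path = data.frame(n_features = length(genes), mean_cv_score = sc),
      ranking = setNames(rep(1L, length(genes)), genes)),
      class = "rfecv_result"))
  }

  current <- genes
  ranking <- setNames(integer(length(genes)), genes)
  path_sets <- list()
  path_n <- integer(0)
  path_score <- numeric(0)
  round <- 0L
  repeat {
    round <- round + 1L
    xs <- x[, current, drop = FALSE]
    path_n <- c(path_n, length(current))
    path_score <- c(path_score,
                    cv_score(xs, y, folds, config$estimator, config$scoring,
                             config$seed))
    path_sets[[round]] <- current
    if (length(current) <= config$min_features) break
    fit <- fit_estimator(xs, y, config$estimator, config$seed)
    imp <- fit$importance
    n_drop <- min(ceiling(config$step_fraction * length(current)),
                  length(current) - config$min_features)
    # lowest importance first; ties resolved by gene id for determinism
    ord <- order(imp, current)
    drop_genes <- current[ord[seq_len(n_drop)]]
    ranking[drop_genes] <- round
    current <- current[!current %in% drop_genes]
  }
  ranking[current] <- round

  best <- which(path_score == max(path_score))
  best <- best[which.min(path_n[best])] # ties -> fewer features
  structure(list(selected_genes = path_sets[[best]],
                 score_path = data.frame(n_features = path_n,
                                         mean_cv_score = path_score),
                 ranking = ranking),
            class = "rfecv_result")
}

#' @export
print.rfecv_result <- function(x, ...) {
  cat("<rfecv_result> ", length(x$selected_genes), " genes selected (path: ",
      nrow(x$score_path), " rounds, best mean CV score ",
      sprintf("%.4f", max(x$score_path$mean_cv_score)), ")\n", sep = "")
  invisible(x)
}

#' Subset a CNA matrix to selected genes
#'
#' @param matrix A [cna_matrix()].
#' @param selected_genes Gene ids to keep; output columns follow this
#'   order. Must all be present in the matrix.
#' @return A [cna_matrix()] with the selected columns, sample order
#'   preserved.
#' @export
apply_selection <- function(matrix, selected_genes) {
  stopifnot(inherits(matrix, "cna_matrix"))
  unknown <- setdiff(selected_genes, colnames(matrix))
  if (length(unknown)) {
    stop("unknown gene(s): ", paste(head(unknown, 5), collapse = ", "))
  }
  cna_matrix(unclass(matrix)[, selected_genes, drop = FALSE])
}
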