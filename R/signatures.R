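#' Attention-normalized instance-level predictions
#'
#' For each bag, the attention weights `w_i` come from running the model
#' on the whole bag, and each instance's class-probability vector `p_i`
#' from running the model on the singleton bag containing just that
#' instance. The normalized weighted score is
#' `phat_i = (w_i / sum_j w_j) * p_i`, so the scores of all instances and
#' classes within a bag sum to 1, and the predicted class
#' `chat_i = argmax_k phat_ik` equals `argmax_k p_ik` (a positive scalar
#' preserves the argmax; ties break toward the lowest class index).
#'
#' @param params A trained `mil_model_params`.
#' @param bags A list of [mil_bag()]s (or a single bag).
#' @return A data frame with one row per instance: `sample_id`, `bag`,
#'   `attention`, `predicted_class` (integer index), one
#'   `phat_<class>` column per class, and matching `p_<class>` columns
#'   with the raw singleton probabilities.
#' @export
instance_predictions <- function(params, bags) {
  if (inherits(bags, "mil_bag")) bags <- list(bags)
  C <- params$dims$C
  rows <- lapply(seq_along(bags), function(bi) {
    bag <- bags[[bi]]
    out <- classify_bag(params, bag)
    K <- nrow(bag$profiles)
    p <- t(vapply(seq_len(K), function(k) {
      classify_bag(params, bag$profiles[k, , drop = FALSE])$bag_probs
    }, numeric(C)))
    w <- out$attention / sum(out$attention)
    phat <- p * w
    df <- data.frame(sample_id = bag$sample_ids, bag = bi, attention = w,
                     predicted_class = max.col(phat, ties.method = "first"),
                     stringsAsFactors = FALSE)
    colnames(p) <- paste0("p_", params$class_names)
    colnames(phat) <- paste0("phat_", params$class_names)
    cbind(df, phat, p)
  })
  do.call(rbind, rows)
}

#' Fraction of correctly predicted samples
#'
#' @param predictions Data frame from [instance_predictions()].
#' @param labels Named character vector, sample id -> true class name.
#' @param class_names Ordered class names mapping the integer
#'   `predicted_class` to names (defaults to the `phat_` column order).
#' @return Proportion in `[0, 1]`.
#' @export
instance_accuracy <- function(predictions, labels, class_names = NULL) {
  if (nrow(predictions) == 0) stop("no predictions given")
  if (is.null(class_names)) {
    class_names <- sub("^phat_", "",
                       grep("^phat_", names(predictions), value = TRUE))
  }
  truth <- labels[predictions$sample_id]
  if (anyNA(truth)) stop("some predicted samples have no label")
  mean(class_names[predictions$predicted_class] == truth)
}

#' Project attention-weighted predictions onto gene features
#'
#' Builds the per-gene score vector of one cancer type's signature:
#' `s_gk = mean over instances i predicted as class k of phat_ik * x_ig`,
#' where `x_ig` is the instance's own discrete call at gene g. The score
#' is linear in the instance predictions and sign-preserving — genes
#' recurrently gained in the class score positive (duplication-
#' associated), recurrently lost score negative (deletion-associated).
#'
#' @param predictions Data frame from [instance_predictions()].
#' @param profiles A [cna_matrix()] (or numeric matrix with sample row
#'   names) holding the instances' CNA values on the model's genes.
#' @param class_index Class k (integer position in `class_names`).
#' @param normalization `"per_class_max"` divides by the maximum absolute
#'   score (top gene scores +/-1), `"l1"` by the sum of absolute scores,
#'   `"none"` leaves raw means.
#' @return Named numeric vector of per-gene signed scores. If no instance
#'   is predicted as class k, a zero vector with a warning.
#' @export
project_to_features <- function(predictions, profiles, class_index,
                                normalization = c("per_class_max", "l1",
                                                  "none")) {
  normalization <- match.arg(normalization)
  x <- as.matrix(unclass(profiles))
  storage.mode(x) <- "numeric"
  sel <- predictions$predicted_class == class_index
  s <- setNames(numeric(ncol(x)), colnames(x))
  if (!any(sel)) {
    warning("no instance predicted as class ", class_index,
            "; returning zero scores")
    return(s)
  }
  phat_cols <- grep("^phat_", names(predictions), value = TRUE)
  wts <- predictions[sel, phat_cols[class_index]]
  xs <- x[predictions$sample_id[sel], , drop = FALSE]
  s[] <- colMeans(xs * wts)
  norm <- switch(normalization,
                 per_class_max = max(abs(s)),
                 l1 = sum(abs(s)),
                 none = 1)
  if (norm > 0) s <- s / norm
  s
}

#' Gradient-times-input feature attribution (alternative projection)
#'
#' An alternative interpretation of projecting instance predictions onto
#' features: the gradient of the class-k singleton-bag log-probability
#' with respect to the input, multiplied elementwise by the input, then
#' attention-weighted and averaged over instances predicted as class k.
#' Offered behind the same contract as [project_to_features()].
#'
#' @inheritParams project_to_features
#' @param params The trained model (needed for gradients).
#' @return Named numeric vector of per-gene signed scores.
#' @export
project_gradient_input <- function(params, predictions, profiles, class_index,
                                   normalization = c("per_class_max", "l1",
                                                     "none")) {
  normalization <- match.arg(normalization)
  x <- as.matrix(unclass(profiles))
  storage.mode(x) <- "numeric"
  sel <- which(predictions$predicted_class == class_index)
  s <- setNames(numeric(ncol(x)), colnames(x))
  if (!length(sel)) {
    warning("no instance predicted as class ", class_index,
            "; returning zero scores")
    return(s)
  }
  phat_cols <- grep("^phat_", names(predictions), value = TRUE)
  acc <- numeric(ncol(x))
  for (i in sel) {
    xi <- x[predictions$sample_id[i], , drop = FALSE]
    gx <- input_gradient(params, xi, class_index)
    acc <- acc + predictions[i, phat_cols[class_index]] * gx * as.numeric(xi)
  }
  s[] <- acc / length(sel)
  norm <- switch(normalization,
                 per_class_max = max(abs(s)),
                 l1 = sum(abs(s)),
                 none = 1)
  if (norm > 0) s <- s / norm
  s
}

# d log p_k / d x for a singleton bag (attention is constant 1 there).
input_gradient <- function(params, xi, k) {
  A1 <- as.numeric(params$W1 %*% t(xi)) + params$b1
  H1 <- pmax(A1, 0)
  h <- as.numeric(params$W2 %*% H1) + params$b2
  logits <- as.numeric(params$Wc %*% h) + params$bc
  p <- softmax(logits)
  dlogits <- -p
  dlogits[k] <- dlogits[k] + 1       # grad of log p_k
  dh <- as.numeric(crossprod(params$Wc, dlogits))
  dH1 <- as.numeric(crossprod(params$W2, dh))
  dA1 <- dH1 * (A1 > 0)
  as.numeric(crossprod(params$W1, dA1))
}

#' Extract per-class CNA signatures from gene score vectors
#'
#' Per class, keeps the N genes with the largest absolute score; ties
#' break alphabetically by gene id. Direction is `"dup"` for nonnegative
#' scores (duplication-associated) and `"del"` for negative ones. The
#' union of the per-class top genes is the pipeline's signature gene set.
#' Deterministic and idempotent: output depends only on the score
#' vectors and N.
#'
#' @param scores Named list (class name -> named score vector from
#'   [project_to_features()]) or a genes x classes matrix.
#' @param N Genes per class signature (default 50). If N exceeds the gene
#'   count, all genes are kept with a warning.
#' @return A list of class `signature_set`: `scores` (genes x classes
#'   matrix), `top_genes` (data frame `class`, `gene`, `score`,
#'   `direction`, `rank`), `N`.
#' @export
extract_signature <- function(scores, N = 50) {
  stopifnot(N >= 1)
  if (is.list(scores) && !is.data.frame(scores)) {
    scores <- do.call(cbind, scores)
  }
  scores <- as.matrix(scores)
  if (N > nrow(scores)) {
    warning("N exceeds the number of genes; keeping all ", nrow(scores))
    N <- nrow(scores)
  }
  rows <- lapply(colnames(scores), function(cl) {
    s <- scores[, cl]
    ord <- order(-abs(s), names(s))[seq_len(N)]
    data.frame(class = cl, gene = names(s)[ord], score = unname(s[ord]),
               direction = ifelse(s[ord] < 0, "del", "dup"),
               rank = seq_len(N), stringsAsFactors = FALSE)
  })
  structure(list(scores = scores, top_genes = do.call(rbind, rows), N = N),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat("<signature_set> ", ncol(x$scores), " classes, top ", x$N,
      " genes each (", length(unique(x$top_genes$gene)),
      " genes in the union)\n", sep = "")
  invisible(x)
}

#' Signature gene set of one class
#'
#' @param sig A [extract_signature()] result.
#' @param class_name Class to extract.
#' @return Character vector of the class's top signature genes.
#' @export
signature_genes <- function(sig, class_name) {
  stopifnot(inherits(sig, "signature_set"))
  sig$top_genes$gene[sig$top_genes$class == class_name]
}

#' Write signatures to TSV
#'
#' Columns: `class`, `gene`, `score`, `direction` (`dup`/`del`), `rank`.
#'
#' @param sig A [extract_signature()] result.
#' @param path Output TSV path.
#' @param header Optional comment line (without `#`) written first.
#' @return `path`, invisibly.
#' @export
write_signatures <- function(sig, path, header = NULL) {
  stopifnot(inherits(sig, "signature_set"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(format(sig$top_genes, digits = 15, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signature table written by [write_signatures()]
#'
#' @param path Signature TSV path.
#' @return Data frame with columns `class`, `gene`, `score`, `direction`,
#'   `rank`.
#' @export
read_signatures <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}
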