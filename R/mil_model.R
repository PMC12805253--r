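#' Construct a bag of instances
#'
#' The multiple-instance unit: an ordered collection of patient CNA
#' profiles sharing one cancer-type label. During training bags are
#' homogeneous — every instance belongs to the bag's class — so the
#' standard MIL assumption (the bag label is the maximum over instance
#' labels) holds trivially.
#'
#' @param profiles Numeric matrix, one row per instance, columns = the
#'   model's selected genes.
#' @param sample_ids Instance identifiers (defaults to row names).
#' @param label Class index (position in the cohort's `class_names`), or
#'   `NA` for unlabeled bags.
#' @return A list of class `mil_bag`.
#' @export
mil_bag <- function(profiles, sample_ids = rownames(profiles), label = NA) {
  profiles <- as.matrix(profiles)
  storage.mode(profiles) <- "numeric"
  if (nrow(profiles) < 1) stop("a bag needs at least one instance")
  if (is.null(sample_ids)) sample_ids <- paste0("inst", seq_len(nrow(profiles)))
  structure(list(profiles = profiles, sample_ids = sample_ids, label = label),
            class = "mil_bag")
}

#' Initialize MIL model parameters
#'
#' The model composes an instance embedder f (one hidden affine layer
#' with ReLU, then an affine map to embedding width M), gated attention
#' pooling with parameters V, U (both L x M) and gate projection w
#' (length L), and a bag classifier g (affine then softmax over C
#' classes). Weights are drawn from N(0, init_sd^2); with the small
#' default, a fresh model predicts near-uniform class probabilities.
#'
#' @param genes Character vector of the gene features the model consumes
#'   (defines input width D and column order).
#' @param class_names Ordered class names (defines C).
#' @param M Embedding width (default 128).
#' @param L Attention width (default 64).
#' @param seed Integer seed for the random initialization.
#' @param init_sd Standard deviation of the initial weights.
#' @return A list of class `mil_model_params` holding `W1, b1, W2, b2`
#'   (embedder), `V, U, w` (gated attention), `Wc, bc` (classifier),
#'   `dims`, `genes`, `class_names` and a checkpoint `version`.
#' @export
mil_params_init <- function(genes, class_names, M = 128, L = 64, seed = 1,
                            init_sd = 0.01) {
  D <- length(genes)
  C <- length(class_names)
  stopifnot(D >= 1, C >= 2, M >= 1, L >= 1)
  with_seed(seed, {
    p <- list(
      W1 = matrix(rnorm(M * D, sd = init_sd), M, D),
      b1 = numeric(M),
      W2 = matrix(rnorm(M * M, sd = init_sd), M, M),
      b2 = numeric(M),
      V = matrix(rnorm(L * M, sd = init_sd), L, M),
      U = matrix(rnorm(L * M, sd = init_sd), L, M),
      w = rnorm(L, sd = init_sd),
      Wc = matrix(rnorm(C * M, sd = init_sd), C, M),
      bc = numeric(C)
    )
  })
  p$dims <- list(D = D, M = M, L = L, C = C)
  p$genes <- as.character(genes)
  p$class_names <- as.character(class_names)
  p$version <- "cnamil-checkpoint-1"
  class(p) <- "mil_model_params"
  p
}

#' @export
print.mil_model_params <- function(x, ...) {
  d <- x$dims
  cat("<mil_model_params> D=", d$D, " M=", d$M, " L=", d$L, " C=", d$C,
      " (", length(unlist(x[param_names()])), " parameters)\n", sep = "")
  invisible(x)
}

param_names <- function() c("W1", "b1", "W2", "b2", "V", "U", "w", "Wc", "bc")

check_bag_width <- function(params, profiles) {
  if (ncol(profiles) != params$dims$D) {
    stop("instance width ", ncol(profiles), " does not match model input D = ",
         params$dims$D)
  }
}

#' Embed bag instances
#'
#' Applies the instance embedder f independently to each instance:
#' `h_k = W2 ReLU(W1 x_k + b1) + b2`. No cross-instance interaction
#' happens before pooling, so permuting instances permutes embedding rows
#' identically.
#'
#' @param params A [mil_params_init()] parameter set.
#' @param bag A [mil_bag()] or a K x D numeric matrix.
#' @return K x M matrix of instance embeddings (row k = embedding of
#'   instance k).
#' @export
embed_instances <- function(params, bag) {
  X <- if (inherits(bag, "mil_bag")) bag$profiles else as.matrix(bag)
  check_bag_width(params, X)
  A1 <- X %*% t(params$W1) + rep(params$b1, each = nrow(X))
  H1 <- pmax(A1, 0)
  H1 %*% t(params$W2) + rep(params$b2, each = nrow(X))
}

#' Gated attention weights over bag instances
#'
#' Computes per-instance attention by a trainable gating mechanism: a
#' tanh branch multiplied elementwise by a logistic-sigmoid gate, then
#' projected and softmax-normalized over the bag,
#' `a_k = softmax_k( w' (tanh(V h_k) * sigmoid(U h_k)) )`.
#' Weights are strictly positive and sum to 1; identical embeddings get
#' uniform weight 1/K.
#'
#' @param params A [mil_params_init()] parameter set.
#' @param embeddings K x M matrix from [embed_instances()].
#' @return Numeric K-vector of attention weights.
#' @export
gated_attention <- function(params, embeddings) {
  embeddings <- as.matrix(embeddings)
  stopifnot(ncol(embeddings) == params$dims$M, nrow(embeddings) >= 1)
  Tm <- tanh(embeddings %*% t(params$V))
  Sm <- sigmoid(embeddings %*% t(params$U))
  scores <- as.numeric((Tm * Sm) %*% params$w)
  softmax(scores)
}

#' Attention-pooled bag embedding
#'
#' `z = sum_k a_k h_k`: a convex combination of instance embeddings, and
#' therefore invariant to permuting instances together with their
#' weights.
#'
#' @param embeddings K x M matrix.
#' @param attention K-vector summing to 1.
#' @return Numeric M-vector.
#' @export
pool_bag <- function(embeddings, attention) {
  embeddings <- as.matrix(embeddings)
  stopifnot(length(attention) == nrow(embeddings))
  if (abs(sum(attention) - 1) > 1e-6) {
    stop("attention weights must sum to 1")
  }
  as.numeric(crossprod(embeddings, attention))
}

#' Classify a bag
#'
#' Composes embedding, gated attention, pooling and the softmax bag
#' classifier. The full composition is permutation-invariant in the bag's
#' instances.
#'
#' @param params A [mil_params_init()] parameter set.
#' @param bag A [mil_bag()] or K x D matrix.
#' @return A list of class `bag_output`: `bag_probs` (C-vector on the
#'   simplex, named by class), `attention` (K-vector) and `embeddings`
#'   (K x M).
#' @export
classify_bag <- function(params, bag) {
  H <- embed_instances(params, bag)
  a <- gated_attention(params, H)
  z <- pool_bag(H, a)
  logits <- as.numeric(params$Wc %*% z) + params$bc
  probs <- softmax(logits)
  names(probs) <- params$class_names
  structure(list(bag_probs = probs, attention = a, embeddings = H),
            class = "bag_output")
}

#' Multinomial bag negative log-likelihood
#'
#' The training loss: `-log p[label]` for the bag's class under the
#' predicted multinomial. A probability of exactly 0 at the label is
#' clamped at 1e-12 (with a message) to keep the loss finite.
#'
#' @param bag_probs C-vector on the probability simplex.
#' @param label Class index in `1..C`.
#' @return Nonnegative scalar.
#' @export
bag_nll <- function(bag_probs, label) {
  stopifnot(label >= 1, label <= length(bag_probs))
  p <- bag_probs[[label]]
  if (p <= 0) {
    message("bag probability at label clamped to 1e-12")
    p <- 1e-12
  }
  -log(p)
}

# Forward + analytic backward pass of bag_nll(classify_bag(params, X), y).
# Returns list(loss, grads) with grads matching param_names() shapes.
# The chain: X -> A1 -> H1 (ReLU) -> H -> {tanh(HV'), sigmoid(HU')} ->
# scores -> softmax a -> z = H'a -> logits -> softmax p -> -log p[y].
mil_backward <- function(params, X, y) {
  K <- nrow(X)
  A1 <- X %*% t(params$W1) + rep(params$b1, each = K)
  H1 <- pmax(A1, 0)
  H <- H1 %*% t(params$W2) + rep(params$b2, each = K)
  Tm <- tanh(H %*% t(params$V))
  Sm <- sigmoid(H %*% t(params$U))
  G <- Tm * Sm
  scores <- as.numeric(G %*% params$w)
  a <- softmax(scores)
  z <- as.numeric(crossprod(H, a))
  logits <- as.numeric(params$Wc %*% z) + params$bc
  p <- softmax(logits)
  loss <- -log(max(p[y], 1e-12))

  dlogits <- p
  dlogits[y] <- dlogits[y] - 1
  dWc <- outer(dlogits, z)
  dbc <- dlogits
  dz <- as.numeric(crossprod(params$Wc, dlogits))
  dH <- outer(a, dz)                       # through z = sum_k a_k h_k
  da <- as.numeric(H %*% dz)
  de <- a * (da - sum(a * da))             # softmax Jacobian
  dw <- as.numeric(crossprod(G, de))
  dG <- outer(de, params$w)
  dpreV <- dG * Sm * (1 - Tm^2)
  dpreU <- dG * Tm * Sm * (1 - Sm)
  dV <- crossprod(dpreV, H)
  dU <- crossprod(dpreU, H)
  dH <- dH + dpreV %*% params$V + dpreU %*% params$U
  dW2 <- crossprod(dH, H1)
  db2 <- colSums(dH)
  dH1 <- dH %*% params$W2
  dA1 <- dH1 * (A1 > 0)
  dW1 <- crossprod(dA1, X)
  db1 <- colSums(dA1)

  list(loss = loss,
       grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                    V = dV, U = dU, w = dw, Wc = dWc, bc = dbc))
}

#' Write a model checkpoint
#'
#' Serializes a parameter set, its dimensions, gene list and class names
#' to a single versioned JSON file.
#'
#' @param params A [mil_params_init()] parameter set.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mil_model <- function(params, path) {
  stopifnot(inherits(params, "mil_model_params"))
  obj <- lapply(params[param_names()], function(m) {
    if (is.matrix(m)) list(dim = dim(m), data = as.numeric(m))
    else list(dim = length(m), data = as.numeric(m))
  })
  out <- list(version = params$version, dims = params$dims,
              genes = params$genes, class_names = params$class_names,
              params = obj)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model checkpoint
#'
#' @param path A checkpoint written by [write_mil_model()].
#' @return A `mil_model_params` object.
#' @export
read_mil_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$version, "cnamil-checkpoint-1")) {
    stop("unsupported checkpoint version: ", obj$version %||% "<missing>")
  }
  p <- lapply(obj$params, function(e) {
    if (length(e$dim) == 2) matrix(e$data, e$dim[1], e$dim[2]) else e$data
  })
  p$dims <- as.list(obj$dims)
  p$genes <- obj$genes
  p$class_names <- obj$class_names
  p$version <- obj$version
  class(p) <- "mil_model_params"
  p
}
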