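# Shared fixture builders; everything is generated in code.

# A tiny hand-checkable CNA matrix.
tiny_matrix <- function() {
  cna_matrix(rbind(c(0L, 1L, -2L), c(2L, 0L, -1L)),
             sample_ids = c("s1", "s2"), gene_ids = c("A", "B", "C"))
}

# Balanced two-class cohort with two informative and two noise features.
# Class 1 sits at (f1, f2) = (1, 1); class 2 alternates (1, -1) / (-1, 1),
# so no single feature separates the classes but the pair does.
informative_pair_cohort <- function(n_per_class = 20, seed = 42) {
  n <- 2 * n_per_class
  f1 <- c(rep(1L, n_per_class), rep_len(c(1L, -1L), n_per_class))
  f2 <- c(rep(1L, n_per_class), rep_len(c(-1L, 1L), n_per_class))
  noise <- with_seed_test(seed, matrix(sample(c(-1L, 0L, 1L), 2 * n, TRUE),
                                       n, 2))
  m <- cbind(f1 = f1, f2 = f2, n1 = noise[, 1], n2 = noise[, 2])
  rownames(m) <- sprintf("s%02d", seq_len(n))
  labels <- setNames(rep(c("ca", "cb"), each = n_per_class), rownames(m))
  labeled_cohort(cna_matrix(m), labels)
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Small random model + bag for invariance checks.
random_model <- function(D = 6, C = 3, M = 4, L = 3, seed = 1, sd = 0.5) {
  mil_params_init(sprintf("g%d", seq_len(D)), paste0("cl", seq_len(C)),
                  M = M, L = L, seed = seed, init_sd = sd)
}

random_bag <- function(D = 6, K = 5, seed = 1) {
  with_seed_test(seed, {
    m <- matrix(sample(-2:2, K * D, TRUE), K, D)
    rownames(m) <- sprintf("i%d", seq_len(K))
    mil_bag(m, label = 1)
  })
}

# Independent scalar-arithmetic evaluation of the gated-attention formula:
# plain loops, no matrix ops, shared by unit and acceptance tests.
scalar_gated_attention <- function(V, U, w, H) {
  K <- nrow(H); L <- nrow(V); M <- ncol(H)
  scores <- numeric(K)
  for (k in seq_len(K)) {
    s_k <- 0
    for (l in seq_len(L)) {
      tv <- 0; uv <- 0
      for (m in seq_len(M)) {
        tv <- tv + V[l, m] * H[k, m]
        uv <- uv + U[l, m] * H[k, m]
      }
      s_k <- s_k + w[l] * tanh(tv) * (1 / (1 + exp(-uv)))
    }
    scores[k] <- s_k
  }
  e <- exp(scores)
  e / sum(e)
}
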