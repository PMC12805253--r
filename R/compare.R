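#' Gain/loss frequency profile of a cohort
#'
#' Per gene, the fraction of samples carrying a gain (call >= 1) and a
#' loss (call <= -1), in the style of Progenetix frequency tracks. Low-
#' and high-level events are merged by default; `high_level_only`
#' restricts counting to deep losses and amplifications (|call| = 2).
#' A sample's call is single-valued, so per gene
#' `gain_freq + loss_freq <= 1`.
#'
#' @param matrix A [cna_matrix()].
#' @param samples Optional sample-id subset (default: all samples).
#' @param high_level_only Count only +/-2 calls.
#' @return A data frame of class `frequency_profile` with columns `gene`,
#'   `gain_freq`, `loss_freq` and attribute `n_samples`.
#' @export
frequency_profile <- function(matrix, samples = NULL,
                              high_level_only = FALSE) {
  x <- unclass(matrix)
  if (!is.null(samples)) {
    missing <- setdiff(samples, rownames(x))
    if (length(missing)) stop("unknown samples: ",
                              paste(head(missing, 5), collapse = ", "))
    x <- x[samples, , drop = FALSE]
  }
  if (nrow(x) == 0) stop("empty sample subset")
  thr <- if (high_level_only) 2 else 1
  out <- data.frame(gene = colnames(x),
                    gain_freq = colMeans(x >= thr),
                    loss_freq = colMeans(x <= -thr),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_samples") <- nrow(x)
  class(out) <- c("frequency_profile", class(out))
  out
}

#' Write / read frequency profiles
#'
#' TSV columns: `gene`, `gain_freq`, `loss_freq`, `n`.
#'
#' @param profile A [frequency_profile()].
#' @param path TSV path.
#' @return `path` (writer) or a `frequency_profile` (reader).
#' @export
write_frequency_profile <- function(profile, path) {
  df <- as.data.frame(profile)
  df$n <- attr(profile, "n_samples")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frequency_profile
#' @export
read_frequency_profile <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  out <- df[, c("gene", "gain_freq", "loss_freq")]
  attr(out, "n_samples") <- df$n[1]
  class(out) <- c("frequency_profile", class(out))
  out
}

#' Aggregate gene-level values to chromosome arms
#'
#' Takes either a [frequency_profile()] (aggregating gain and loss
#' frequencies and their difference) or a named numeric vector of
#' per-gene scores (e.g. a signature column), and returns the unweighted
#' mean per chromosome arm over the annotated genes. Genes absent from
#' the annotation are skipped; the skip count is recorded in the
#' `n_skipped` attribute.
#'
#' @param x A `frequency_profile` or named numeric vector.
#' @param annotation A [gene_annotation()].
#' @return A data frame of class `arm_profile` with columns `arm`
#'   (e.g. `"chr1p"`), `n_genes`, and either `gain_freq`, `loss_freq`,
#'   `net` (mean gain - mean loss) or `score`.
#' @export
aggregate_to_arms <- function(x, annotation) {
  stopifnot(inherits(annotation, "gene_annotation"))
  if (inherits(x, "frequency_profile")) {
    genes <- x$gene
    vals <- data.frame(gain_freq = x$gain_freq, loss_freq = x$loss_freq)
  } else {
    if (is.null(names(x))) stop("scores must be a named vector")
    genes <- names(x)
    vals <- data.frame(score = as.numeric(x))
  }
  keep <- genes %in% annotation$gene
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    message(n_skipped, " gene(s) without annotation skipped")
  }
  if (!any(keep)) stop("no annotated genes to aggregate")
  genes <- genes[keep]
  vals <- vals[keep, , drop = FALSE]
  ann <- annotation[match(genes, annotation$gene), ]
  arm_key <- paste0(ann$chrom, ann$arm)
  agg <- aggregate(vals, by = list(arm = arm_key), FUN = mean)
  counts <- as.data.frame(table(arm = arm_key), stringsAsFactors = FALSE)
  out <- merge(agg, setNames(counts, c("arm", "n_genes")), by = "arm")
  out <- out[order(out$arm), ]
  rownames(out) <- NULL
  if ("gain_freq" %in% names(out)) out$net <- out$gain_freq - out$loss_freq
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("arm_profile", class(out))
  out
}

#' Spearman concordance of two arm profiles
#'
#' Rank-correlates the arm-level net score (mean gain frequency minus
#' mean loss frequency, or the mean signature score) of the arms shared
#' by both profiles, with average ranks for ties. Symmetric, and
#' invariant under strictly monotone transforms of either profile.
#'
#' @param a,b [aggregate_to_arms()] results.
#' @return Spearman rho in `[-1, 1]`.
#' @export
arm_spearman <- function(a, b) {
  val <- function(p) {
    if ("net" %in% names(p)) setNames(p$net, p$arm)
    else setNames(p$score, p$arm)
  }
  va <- val(a)
  vb <- val(b)
  shared <- intersect(names(va), names(vb))
  if (length(shared) < 3) {
    stop("need at least 3 shared arms, got ", length(shared))
  }
  cor(va[shared], vb[shared], method = "spearman")
}

#' Jaccard overlap of two gene sets
#'
#' `|A intersect B| / |A union B|`, the gene-level concordance measure
#' for comparing signature gene sets.
#'
#' @param genes_a,genes_b Character vectors (treated as sets).
#' @return Proportion in `[0, 1]`.
#' @export
signature_jaccard <- function(genes_a, genes_b) {
  a <- unique(genes_a)
  b <- unique(genes_b)
  if (length(a) == 0 && length(b) == 0) {
    stop("both gene sets are empty")
  }
  length(intersect(a, b)) / length(union(a, b))
}
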