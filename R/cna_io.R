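#' Construct and validate a CNA matrix
#'
#' A CNA matrix stores gene-level discrete copy-number calls for a cohort,
#' one row per sample and one column per gene, on the five-level scale
#' -2 (deep loss), -1 (shallow loss), 0 (diploid), 1 (low-level gain),
#' 2 (high-level amplification) as produced by GISTIC-style calling.
#'
#' @param values Integer matrix of calls, samples in rows, genes in columns.
#' @param sample_ids Character vector of unique sample identifiers
#'   (defaults to `rownames(values)`).
#' @param gene_ids Character vector of unique gene symbols (defaults to
#'   `colnames(values)`).
#' @return An integer matrix of class `cna_matrix` with sample row names
#'   and gene column names.
#' @examples
#' m <- cna_matrix(rbind(c(0L, 1L, -2L), c(2L, 0L, -1L)),
#'                 sample_ids = c("s1", "s2"), gene_ids = c("A", "B", "C"))
#' @export
cna_matrix <- function(values, sample_ids = rownames(values),
                       gene_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(sample_ids) || is.null(gene_ids)) {
    stop("sample_ids and gene_ids are required (or row/column names)")
  }
  sample_ids <- as.character(sample_ids)
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (nrow(values) != length(sample_ids) || ncol(values) != length(gene_ids)) {
    stop("matrix is ", nrow(values), " x ", ncol(values), " but there are ",
         length(sample_ids), " sample ids and ", length(gene_ids), " gene ids")
  }
  bad <- which(is.na(values) | values != round(values) |
                 values < -2 | values > 2, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop("invalid copy-number call at sample '", sample_ids[i], "', gene '",
         gene_ids[j], "': value ", values[i, j],
         " (calls must be integers in -2..2)")
  }
  storage.mode(values) <- "integer"
  dimnames(values) <- list(sample_ids, gene_ids)
  class(values) <- c("cna_matrix", class(values))
  values
}

#' @export
print.cna_matrix <- function(x, ...) {
  cat("<cna_matrix> ", nrow(x), " samples x ", ncol(x), " genes\n", sep = "")
  nz <- mean(x != 0)
  cat(sprintf("  non-diploid fraction: %.3f\n", nz))
  invisible(x)
}

#' Read a CNA matrix from a tab-separated file
#'
#' The file must be TSV with a header line; the first column holds row
#' identifiers. cBioPortal-style exports put genes in rows, so both
#' orientations are accepted and normalized to samples-as-rows.
#'
#' @param path Path to a TSV file.
#' @param dialect `"samples_as_rows"` or `"genes_as_rows"` (orientation of
#'   the file on disk).
#' @return A [cna_matrix()].
#' @seealso [write_cna_matrix()]
#' @export
read_cna_matrix <- function(path,
                            dialect = c("samples_as_rows", "genes_as_rows")) {
  dialect <- match.arg(dialect)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  if (ncol(df) < 2) stop("expected an identifier column plus data columns")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2,
                                              as.numeric))), arr.ind = TRUE)
    if (length(bad)) {
      stop("non-integer value in '", basename(path), "' at row '",
           ids[bad[1, 1]], "', column '", colnames(df)[-1][bad[1, 2]], "'")
    }
    storage.mode(m) <- "numeric"
  }
  rownames(m) <- ids
  if (dialect == "genes_as_rows") m <- t(m)
  cna_matrix(m)
}

#' Write a CNA matrix to a tab-separated file
#'
#' Writes samples-as-rows TSV with a `sample_id` identifier column;
#' [read_cna_matrix()] on the result reproduces the input exactly.
#'
#' @param x A [cna_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cna_matrix <- function(x, path) {
  stopifnot(inherits(x, "cna_matrix"))
  df <- data.frame(sample_id = rownames(x), unclass(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a labeled cohort
#'
#' Binds a CNA matrix to per-sample cancer-type labels and an ordered list
#' of class names. The class index used throughout the package is the
#' position in `class_names`.
#'
#' @param matrix A [cna_matrix()].
#' @param labels Named character vector (names = sample ids) or a
#'   data frame with columns `sample_id` and `cancer_type`.
#' @param class_names Ordered character vector of distinct class names;
#'   defaults to the sorted unique labels.
#' @return A list of class `labeled_cohort` with elements `matrix`,
#'   `labels` (named vector aligned to matrix rows) and `class_names`.
#' @export
labeled_cohort <- function(matrix, labels, class_names = NULL) {
  stopifnot(inherits(matrix, "cna_matrix"))
  if (is.data.frame(labels)) {
    labels <- setNames(as.character(labels[[2]]), as.character(labels[[1]]))
  }
  missing <- setdiff(rownames(matrix), names(labels))
  if (length(missing)) {
    stop("samples without a label: ", paste(head(missing, 5), collapse = ", "))
  }
  labels <- labels[rownames(matrix)]
  if (anyNA(labels)) stop("NA labels are not allowed")
  if (is.null(class_names)) class_names <- sort(unique(unname(labels)))
  unknown <- setdiff(labels, class_names)
  if (length(unknown)) {
    stop("labels outside class_names: ", paste(unknown, collapse = ", "))
  }
  structure(list(matrix = matrix, labels = labels, class_names = class_names),
            class = "labeled_cohort")
}

#' @export
print.labeled_cohort <- function(x, ...) {
  cat("<labeled_cohort> ", nrow(x$matrix), " samples x ", ncol(x$matrix),
      " genes, ", length(x$class_names), " classes\n", sep = "")
  print(table(factor(x$labels, levels = x$class_names)))
  invisible(x)
}

#' Read a sample label table
#'
#' @param path TSV with two columns: sample id and cancer type.
#' @return Named character vector, sample id to cancer type.
#' @export
read_labels <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2) stop("label table needs two columns")
  if (anyDuplicated(df[[1]])) stop("duplicate sample ids in label table")
  setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Write a sample label table
#'
#' @param labels Named character vector, sample id to cancer type.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  df <- data.frame(sample_id = names(labels), cancer_type = unname(labels),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct and validate a gene annotation table
#'
#' Maps each gene to a chromosome, an arm ("p" or "q") and a 0-based
#' half-open genomic interval (BED convention). Used for chromosome-arm
#' aggregation of frequency profiles and signature scores.
#'
#' @param chrom,start,end,gene,arm Per-gene vectors.
#' @return A data frame of class `gene_annotation` with those columns.
#' @export
gene_annotation <- function(chrom, start, end, gene, arm) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), gene = as.character(gene),
                   arm = as.character(arm), stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene)) stop("duplicate genes in annotation")
  if (any(df$start >= df$end)) stop("annotation intervals must have start < end")
  if (!all(df$arm %in% c("p", "q"))) stop("arm must be 'p' or 'q'")
  class(df) <- c("gene_annotation", class(df))
  df
}

#' Read a gene annotation table (BED-like TSV)
#'
#' @param path TSV with header columns `chrom`, `start`, `end`, `gene`,
#'   `arm`; coordinates 0-based half-open.
#' @return A [gene_annotation()] data frame.
#' @export
read_gene_annotation <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("chrom", "start", "end", "gene", "arm")
  if (!all(need %in% names(df))) {
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  }
  gene_annotation(df$chrom, df$start, df$end, df$gene, df$arm)
}

#' Write a gene annotation table
#'
#' @param ann A [gene_annotation()] data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(ann, path) {
  write.table(as.data.frame(ann)[, c("chrom", "start", "end", "gene", "arm")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align two CNA matrices on a shared gene set
#'
#' Cohorts assembled from different studies rarely share identical gene
#' panels; downstream comparison requires a common, consistently ordered
#' gene set.
#'
#' @param a,b [cna_matrix()] objects.
#' @param policy `"intersect"` keeps only shared genes; `"union_fill_zero"`
#'   keeps the union, filling absent genes with 0 (diploid is the neutral
#'   call).
#' @return List with elements `a` and `b`, both with an identical, sorted
#'   gene list.
#' @export
align_gene_sets <- function(a, b, policy = c("intersect", "union_fill_zero")) {
  policy <- match.arg(policy)
  stopifnot(inherits(a, "cna_matrix"), inherits(b, "cna_matrix"))
  if (policy == "intersect") {
    genes <- sort(intersect(colnames(a), colnames(b)))
    if (length(genes) == 0) stop("no genes shared between the two matrices")
    list(a = cna_matrix(unclass(a)[, genes, drop = FALSE]),
         b = cna_matrix(unclass(b)[, genes, drop = FALSE]))
  } else {
    genes <- sort(union(colnames(a), colnames(b)))
    fill <- function(m) {
      out <- matrix(0L, nrow(m), length(genes),
                    dimnames = list(rownames(m), genes))
      out[, colnames(m)] <- unclass(m)
      cna_matrix(out)
    }
    list(a = fill(a), b = fill(b))
  }
}

#' Stratified train/test split of a labeled cohort
#'
#' Splits a cohort into training and testing parts, stratified by cancer
#' type: per class, `floor(n * test_fraction)` samples (at least 1 when the
#' class has 2 or more samples) go to the test part. A class with a single
#' sample goes to training with a warning. Deterministic given `seed`.
#'
#' @param cohort A [labeled_cohort()].
#' @param test_fraction Proportion in (0, 1); the conventional split is
#'   0.2 test / 0.8 train.
#' @param seed Integer seed.
#' @return List with `train` and `test` labeled cohorts partitioning the
#'   input.
#' @export
split_cohort <- function(cohort, test_fraction = 0.2, seed = 1) {
  stopifnot(inherits(cohort, "labeled_cohort"),
            test_fraction > 0, test_fraction < 1)
  ids <- rownames(cohort$matrix)
  test_ids <- character(0)
  with_seed(seed, {
    for (cl in cohort$class_names) {
      cl_ids <- ids[cohort$labels == cl]
      n <- length(cl_ids)
      if (n == 0) next
      if (n == 1) {
        warning("class '", cl, "' has a single sample; kept in training")
        next
      }
      n_test <- max(1L, floor(n * test_fraction))
      test_ids <- c(test_ids, sample(cl_ids, n_test))
    }
  })
  take <- function(keep) {
    labeled_cohort(cna_matrix(unclass(cohort$matrix)[keep, , drop = FALSE]),
                   cohort$labels[keep], cohort$class_names)
  }
  list(train = take(setdiff(ids, test_ids)), test = take(test_ids))
}
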