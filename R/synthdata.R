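#' Configuration for the synthetic CNA cohort simulator
#'
#' The simulator emulates a multi-cancer-type cohort of five-level
#' discrete copy-number calls: each class carries a fixed set of planted,
#' contiguous gene blocks (segmental gains or losses) that a sample of the
#' class harbors with probability `penetrance`; all other positions are
#' sporadic background noise. Contiguity mimics segmental CNAs so that
#' chromosome-arm aggregation of the output is meaningful. Intra-class
#' heterogeneity — the reason the classifier is formulated over bags of
#' samples rather than single profiles — can be planted explicitly via
#' `subtype_spec`.
#'
#' @param n_classes Number of cancer types.
#' @param samples_per_class Samples per class (scalar or per-class vector).
#' @param n_genes Number of genes; must be at least
#'   `n_classes * blocks_per_class * block_size`.
#' @param blocks_per_class Contiguous planted blocks per class.
#' @param block_size Genes per planted block.
#' @param block_sign Signs of the planted blocks: +1 gain, -1 loss.
#'   A vector of length `blocks_per_class` (recycled across classes) or an
#'   `n_classes x blocks_per_class` matrix. Default alternates gain/loss.
#' @param penetrance Probability that a sample of the class carries each
#'   of its blocks (default 0.9: planted events are near-clonal in the
#'   class, as driver-level arm gains/losses are in real tumor cohorts).
#' @param high_level_fraction Probability a carried aberration is
#'   high-level (+2/-2) rather than single-copy (default 0.3).
#' @param background_rate Per-gene probability of a sporadic nonzero call
#'   in any sample (default 0.02).
#' @param subtype_spec Optional named list (class name -> list of
#'   subtypes). Each subtype is a list with `name`, `fraction`, and
#'   `blocks`: a list of `list(start, size, sign)` gene-index intervals.
#'   A class with subtypes uses the subtype blocks instead of
#'   auto-placed class blocks.
#' @param seed Integer seed; identical seeds reproduce identical cohorts.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_classes = 3, samples_per_class = 40,
                              n_genes = 500, blocks_per_class = 2,
                              block_size = 10, block_sign = NULL,
                              penetrance = 0.9, high_level_fraction = 0.3,
                              background_rate = 0.02, subtype_spec = NULL,
                              seed = 1) {
  stopifnot(n_classes >= 1, n_genes >= 1, blocks_per_class >= 0,
            block_size >= 1,
            penetrance >= 0, penetrance <= 1,
            high_level_fraction >= 0, high_level_fraction <= 1,
            background_rate >= 0, background_rate <= 1)
  if (length(samples_per_class) == 1) {
    samples_per_class <- rep(samples_per_class, n_classes)
  }
  stopifnot(length(samples_per_class) == n_classes, all(samples_per_class >= 1))
  if (n_genes < n_classes * blocks_per_class * block_size) {
    stop("n_genes too small for ", n_classes * blocks_per_class,
         " disjoint blocks of ", block_size, " genes")
  }
  if (is.null(block_sign)) {
    block_sign <- rep_len(c(1, -1), blocks_per_class)
  }
  if (!is.matrix(block_sign)) {
    block_sign <- matrix(rep_len(block_sign, n_classes * blocks_per_class),
                         n_classes, blocks_per_class, byrow = TRUE)
  }
  stopifnot(all(block_sign %in% c(-1, 1)))
  structure(list(n_classes = n_classes, samples_per_class = samples_per_class,
                 n_genes = n_genes, blocks_per_class = blocks_per_class,
                 block_size = block_size, block_sign = block_sign,
                 penetrance = penetrance,
                 high_level_fraction = high_level_fraction,
                 background_rate = background_rate,
                 subtype_spec = subtype_spec, seed = seed),
            class = "simulation_config")
}

# Auto-placed planted blocks: evenly spaced disjoint intervals, one slot
# per (class, block). Returns a list per class of list(start, size, sign).
planted_blocks <- function(config) {
  cls_names <- paste0("class", seq_len(config$n_classes))
  total <- config$n_classes * config$blocks_per_class
  out <- setNames(vector("list", config$n_classes), cls_names)
  if (total > 0) {
    gap <- floor(config$n_genes / total)
    slot <- 0
    for (c in seq_len(config$n_classes)) {
      blocks <- list()
      for (b in seq_len(config$blocks_per_class)) {
        blocks[[b]] <- list(start = slot * gap + 1, size = config$block_size,
                            sign = config$block_sign[c, b])
        slot <- slot + 1
      }
      out[[c]] <- blocks
    }
  } else {
    for (c in seq_len(config$n_classes)) out[[c]] <- list()
  }
  # subtype blocks replace a class's auto blocks
  if (!is.null(config$subtype_spec)) {
    for (cl in names(config$subtype_spec)) {
      if (!cl %in% cls_names) stop("subtype_spec names unknown class '", cl, "'")
      out[[cl]] <- unlist(lapply(config$subtype_spec[[cl]],
                                 function(s) s$blocks), recursive = FALSE)
    }
  }
  # disjointness across classes
  occupied <- integer(0)
  for (cl in cls_names) {
    for (b in out[[cl]]) {
      idx <- seq(b$start, length.out = b$size)
      if (any(idx > config$n_genes) || any(idx < 1)) {
        stop("planted block outside gene range in ", cl)
      }
      if (any(idx %in% occupied)) {
        stop("planted blocks of different classes overlap (", cl, ")")
      }
      occupied <- c(occupied, idx)
    }
  }
  out
}

#' Simulate a labeled multi-class CNA cohort
#'
#' Generates a [labeled_cohort()] according to a [simulation_config()]:
#' each sample's profile is per-gene background noise overlaid by its
#' class (or subtype) blocks; a planted value overwrites background at the
#' same locus, since a sample's call at a gene is a single observed state.
#' Carried blocks take magnitude 2 with probability `high_level_fraction`
#' (drawn once per carried block — a segmental event has one level),
#' otherwise 1, with the block's sign.
#'
#' @param config A [simulation_config()].
#' @return List with elements:
#'   \describe{
#'     \item{cohort}{a [labeled_cohort()] of simulated calls}
#'     \item{ground_truth}{per class, a data frame of planted `gene`
#'       (symbol), `gene_index` and `sign`}
#'     \item{subtypes}{named vector sample id -> subtype (only for classes
#'       with a `subtype_spec`)}
#'     \item{annotation}{a [gene_annotation()] placing genes uniformly on
#'       simulated chromosomes, p/q arms split at the midpoint}
#'   }
#' @examples
#' sim <- simulate_cohort(simulation_config(n_classes = 2,
#'   samples_per_class = 5, n_genes = 60, seed = 7))
#' table(sim$cohort$labels)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  blocks <- planted_blocks(config)
  cls_names <- names(blocks)
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  n_total <- sum(config$samples_per_class)
  m <- matrix(0L, n_total, config$n_genes)
  sample_ids <- character(n_total)
  labels <- character(n_total)
  subtypes <- character(0)

  with_seed(config$seed, {
    row <- 0
    for (c in seq_len(config$n_classes)) {
      cl <- cls_names[c]
      spec <- config$subtype_spec[[cl]]
      n_c <- config$samples_per_class[c]
      # deterministic subtype assignment counts, then shuffled order
      if (!is.null(spec)) {
        fr <- vapply(spec, function(s) s$fraction, numeric(1))
        counts <- floor(fr * n_c)
        rem <- n_c - sum(counts)
        if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1
        assign_st <- sample(rep(seq_along(spec), counts))
      }
      for (s in seq_len(n_c)) {
        row <- row + 1
        sid <- sprintf("%s_s%03d", cl, s)
        sample_ids[row] <- sid
        labels[row] <- cl
        prof <- integer(config$n_genes)
        # background: sporadic calls, sign uniform, level per
        # high_level_fraction
        hit <- runif(config$n_genes) < config$background_rate
        if (any(hit)) {
          sgn <- sample(c(-1L, 1L), sum(hit), replace = TRUE)
          lvl <- ifelse(runif(sum(hit)) < config$high_level_fraction, 2L, 1L)
          prof[hit] <- sgn * lvl
        }
        my_blocks <- blocks[[cl]]
        if (!is.null(spec)) {
          st <- assign_st[s]
          subtypes[sid] <- spec[[st]]$name
          my_blocks <- spec[[st]]$blocks
        }
        for (b in my_blocks) {
          if (runif(1) < config$penetrance) {
            lvl <- if (runif(1) < config$high_level_fraction) 2L else 1L
            idx <- seq(b$start, length.out = b$size)
            prof[idx] <- as.integer(b$sign * lvl)
          }
        }
        m[row, ] <- prof
      }
    }
  })

  dimnames(m) <- list(sample_ids, genes)
  cohort <- labeled_cohort(cna_matrix(m), setNames(labels, sample_ids),
                           cls_names)
  gt <- lapply(cls_names, function(cl) {
    rows <- do.call(rbind, lapply(blocks[[cl]], function(b) {
      idx <- seq(b$start, length.out = b$size)
      data.frame(gene = genes[idx], gene_index = idx, sign = b$sign)
    }))
    if (is.null(rows)) {
      data.frame(gene = character(0), gene_index = integer(0),
                 sign = numeric(0))
    } else rows
  })
  names(gt) <- cls_names
  structure(list(cohort = cohort, ground_truth = gt, subtypes = subtypes,
                 annotation = simulate_annotation(config$n_genes)),
            class = "simulated_cohort")
}

#' Auto-generated gene annotation for simulated cohorts
#'
#' Places `n_genes` uniformly on simulated chromosomes of
#' `genes_per_chrom` genes each; each chromosome's p arm is its first
#' half, the q arm the second. Coordinates are 0-based half-open with
#' 100 kb gene spacing and 10 kb gene length.
#'
#' @param n_genes Number of genes (ids `g0001`, `g0002`, ...).
#' @param genes_per_chrom Genes per simulated chromosome.
#' @return A [gene_annotation()] data frame.
#' @export
simulate_annotation <- function(n_genes, genes_per_chrom = 50) {
  idx <- seq_len(n_genes)
  chrom_i <- (idx - 1) %/% genes_per_chrom + 1
  pos_in <- (idx - 1) %% genes_per_chrom
  arm <- ifelse(pos_in < genes_per_chrom / 2, "p", "q")
  start <- pos_in * 1e5
  gene_annotation(chrom = paste0("chr", chrom_i), start = start,
                  end = start + 1e4, gene = sprintf("g%04d", idx), arm = arm)
}

#' Subtype assignment of a simulated cohort
#'
#' @param sim A `simulated_cohort` from [simulate_cohort()] whose config
#'   included a `subtype_spec`.
#' @return Named character vector, sample id -> subtype name, for samples
#'   of classes with subtypes.
#' @export
subtype_labels <- function(sim) {
  stopifnot(inherits(sim, "simulated_cohort"))
  if (length(sim$subtypes) == 0) {
    stop("cohort was simulated without a subtype_spec")
  }
  sim$subtypes
}

#' Write a simulated cohort's artifacts to a directory
#'
#' Writes `matrix.tsv`, `labels.tsv`, `annotation.tsv` (BED-like) and
#' `ground_truth.json` (planted gene sets with signs per class, plus
#' subtype assignments when present).
#'
#' @param sim A `simulated_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named vector of the written paths, invisibly.
#' @export
write_simulated_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "simulated_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "matrix.tsv"),
             labels = file.path(dir, "labels.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             ground_truth = file.path(dir, "ground_truth.json"))
  write_cna_matrix(sim$cohort$matrix, paths["matrix"])
  write_labels(sim$cohort$labels, paths["labels"])
  write_gene_annotation(sim$annotation, paths["annotation"])
  gt <- lapply(sim$ground_truth, function(df) {
    list(genes = df$gene, signs = df$sign)
  })
  jsonlite::write_json(list(ground_truth = gt,
                            subtypes = as.list(sim$subtypes)),
                       paths["ground_truth"], auto_unbox = TRUE)
  invisible(paths)
}
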