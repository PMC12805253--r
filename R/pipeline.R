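#' Pipeline configuration
#'
#' Bundles every stage's settings plus one global seed. Each stage draws
#' its own seed deterministically from the global seed via
#' [derive_seed()], so stages are decoupled: changing, say, the number of
#' training epochs never changes the train/test split.
#'
#' @param matrix_path,labels_path,annotation_path Input TSV paths
#'   (annotation optional; enables arm-level concordance output). Ignored
#'   when a cohort object is passed to [run_pipeline()] directly.
#' @param out_dir Output directory for artifacts.
#' @param test_fraction Held-out fraction for the stratified split.
#' @param rfecv An [rfecv_config()].
#' @param M,L Model embedding and attention widths.
#' @param train A [train_config()].
#' @param signature_n Genes per class signature.
#' @param eval_bag_size Bag size for evaluation.
#' @param seed Global integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix_path = NULL, labels_path = NULL,
                            annotation_path = NULL, out_dir = "cnamil_out",
                            test_fraction = 0.2, rfecv = rfecv_config(),
                            M = 64, L = 32, train = train_config(),
                            signature_n = 50, eval_bag_size = 10, seed = 1) {
  structure(list(matrix_path = matrix_path, labels_path = labels_path,
                 annotation_path = annotation_path, out_dir = out_dir,
                 test_fraction = test_fraction, rfecv = rfecv, M = M, L = L,
                 train = train, signature_n = signature_n,
                 eval_bag_size = eval_bag_size, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Unspecified fields take the [pipeline_config()] defaults; `rfecv` and
#' `train` sub-sections map onto [rfecv_config()] / [train_config()]
#' arguments.
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is needed to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  args <- obj
  if (!is.null(obj$rfecv)) args$rfecv <- do.call(rfecv_config, obj$rfecv)
  if (!is.null(obj$train)) args$train <- do.call(train_config, obj$train)
  do.call(pipeline_config, args)
}

#' Run the full pipeline
#'
#' Executes split -> feature selection -> training -> evaluation ->
#' signature generation in order and writes all artifacts to
#' `config$out_dir`, each stamped with a hash of the configuration and
#' the global seed. Reruns with an identical config produce
#' byte-identical signature output.
#'
#' Artifacts: `selected_genes.txt`, `score_path.tsv`, `model.json`,
#' `eval_report.json`, `confusion.tsv`, `signatures.tsv` and, when an
#' annotation is available, `arm_concordance.tsv` (per class, the
#' Spearman concordance between the class signature scores and the class
#' gain-minus-loss frequency profile, both aggregated to chromosome
#' arms).
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional in-memory [labeled_cohort()] (skips reading
#'   `matrix_path`/`labels_path`).
#' @param annotation Optional in-memory [gene_annotation()].
#' @return Invisibly, a list with the fitted objects (`split`, `rfecv`,
#'   `fit`, `report`, `signatures`) and `artifacts` (named file paths).
#' @export
run_pipeline <- function(config, cohort = NULL, annotation = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "input"
  result <- tryCatch({
    if (is.null(cohort)) {
      m <- read_cna_matrix(config$matrix_path)
      cohort <- labeled_cohort(m, read_labels(config$labels_path))
    }
    if (is.null(annotation) && !is.null(config$annotation_path)) {
      annotation <- read_gene_annotation(config$annotation_path)
    }
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    # hash the scientific configuration, not where it reads/writes
    hashed <- unclass(config)
    hashed[c("matrix_path", "labels_path", "annotation_path",
             "out_dir")] <- NULL
    hash <- config_hash(hashed)
    stamp <- paste0("cnamil config=", hash, " seed=", config$seed)

    stage <- "split"
    parts <- split_cohort(cohort, config$test_fraction,
                          seed = derive_seed(config$seed, "split"))

    stage <- "feature_selection"
    rcfg <- config$rfecv
    rcfg$seed <- derive_seed(config$seed, "rfecv")
    sel <- rfecv_select(parts$train, rcfg)
    genes_path <- file.path(config$out_dir, "selected_genes.txt")
    writeLines(c(paste0("# ", stamp), sel$selected_genes), genes_path)
    path_tsv <- file.path(config$out_dir, "score_path.tsv")
    stamped_table(sel$score_path, path_tsv, stamp)

    stage <- "training"
    tcfg <- config$train
    tcfg$seed <- derive_seed(config$seed, "train")
    fit <- train_mil(parts$train, selected_genes = sel$selected_genes,
                     M = config$M, L = config$L, config = tcfg,
                     validation = parts$test)
    model_path <- file.path(config$out_dir, "model.json")
    write_mil_model(fit$params, model_path)

    stage <- "evaluation"
    report <- evaluate_mil(fit$params, parts$test, K = config$eval_bag_size,
                           seed = derive_seed(config$seed, "evaluate"))
    report_path <- file.path(config$out_dir, "eval_report.json")
    jsonlite::write_json(list(bag_accuracy = report$bag_accuracy,
                              instance_accuracy = report$instance_accuracy,
                              config_hash = hash, seed = config$seed),
                         report_path, auto_unbox = TRUE, digits = NA)
    conf_path <- file.path(config$out_dir, "confusion.tsv")
    conf_df <- data.frame(class = rownames(report$confusion),
                          report$confusion, check.names = FALSE)
    stamped_table(conf_df, conf_path, stamp)

    stage <- "signatures"
    # signatures draw on every instance of each type, not just held-out ones
    full_sel <- apply_selection(cohort$matrix, sel$selected_genes)
    full_cohort <- labeled_cohort(full_sel, cohort$labels, cohort$class_names)
    sig_bags <- make_bags(full_cohort, config$eval_bag_size,
                          seed = derive_seed(config$seed, "signatures"),
                          mode = "epoch_partition")
    sig_preds <- instance_predictions(fit$params, sig_bags)
    scores <- sapply(seq_along(cohort$class_names), function(k) {
      suppressWarnings(
        project_to_features(sig_preds, full_sel, k))
    })
    colnames(scores) <- cohort$class_names
    sig <- extract_signature(scores, N = config$signature_n)
    sig_path <- file.path(config$out_dir, "signatures.tsv")
    write_signatures(sig, sig_path, header = stamp)

    artifacts <- c(selected_genes = genes_path, score_path = path_tsv,
                   model = model_path, eval_report = report_path,
                   confusion = conf_path, signatures = sig_path)

    if (!is.null(annotation)) {
      stage <- "comparison"
      rows <- lapply(cohort$class_names, function(cl) {
        ids <- rownames(cohort$matrix)[cohort$labels == cl]
        fp <- frequency_profile(cohort$matrix, ids)
        rho <- tryCatch(
          arm_spearman(aggregate_to_arms(sig$scores[, cl], annotation),
                       suppressMessages(aggregate_to_arms(fp, annotation))),
          error = function(e) NA_real_)
        data.frame(class = cl, arm_spearman = rho, n_samples = length(ids))
      })
      cmp_path <- file.path(config$out_dir, "arm_concordance.tsv")
      stamped_table(do.call(rbind, rows), cmp_path, stamp)
      artifacts["arm_concordance"] <- cmp_path
    }

    list(split = parts, rfecv = sel, fit = fit, report = report,
         signatures = sig, artifacts = artifacts)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

# TSV with a leading stamped comment line; numbers at full precision so
# reruns are byte-identical iff the values are.
stamped_table <- function(df, path, stamp) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", stamp), con)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 15, trim = TRUE,
                                                scientific = FALSE))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
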