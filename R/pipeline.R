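# End-to-end orchestration: preprocess -> entanglement discovery -> Grover
# combination mining -> higher-order Ising optimization -> quantum-kernel
# classification on a 7:3 train/test split -> assembled association report.
# Every stage draws its randomness from seeds derived from the master seed,
# so a report is a pure function of (input, config, seed).

#' Seeded train/test split
#'
#' Shuffles the records uniformly with the given seed and splits at
#' `floor(ratio * n)`. The two parts partition the input exactly.
#'
#' @param table a [feature_table()].
#' @param ratio training fraction in (0, 1); default 0.7 (the 7:3 split).
#' @param seed integer seed.
#' @return List with `train` and `test` feature tables.
#' @export
split_train_test <- function(table, ratio = 0.7, seed = 1L) {
  stopifnot(inherits(table, "feature_table"), ratio > 0, ratio < 1)
  n <- nrow(table$records)
  if (n < 2L) stop("at least 2 records are required to split")
  n_train <- floor(ratio * n)
  if (n_train < 1L || n_train >= n)
    stop("degenerate split: ", n_train, " train / ", n - n_train,
         " test records")
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  perm <- sample.int(n)
  mk <- function(rows) feature_table(table$records[rows, , drop = FALSE],
                                     roles = table$feature_roles)
  list(train = mk(sort(perm[seq_len(n_train)])),
       test = mk(sort(perm[(n_train + 1L):n])))
}

#' Classification metrics on a held-out table
#'
#' @param fit a `qsvm_fit` from [train_qsvm()].
#' @param test_table a [feature_table()] containing the disease feature and
#'   the predictor features the fit was trained on.
#' @param disease_feature name of the 0/1 outcome column (1 = positive
#'   class, mapped to label +1).
#' @param predictors character vector of predictor feature names, in the
#'   training order.
#' @return List with `accuracy`, `sensitivity`, `specificity` and the
#'   confusion counts `tp`, `tn`, `fp`, `fn` (summing to the test size).
#' @export
evaluate_classifier <- function(fit, test_table, disease_feature,
                                predictors) {
  stopifnot(inherits(fit, "qsvm_fit"), inherits(test_table, "feature_table"))
  if (!disease_feature %in% test_table$feature_names)
    stop("missing disease column: ", disease_feature)
  if (nrow(test_table$records) < 1L) stop("empty test table")
  X <- test_table$records[, predictors, drop = FALSE]
  truth <- 2 * test_table$records[, disease_feature] - 1
  pred <- predict(fit, X)
  tp <- sum(pred == 1 & truth == 1); tn <- sum(pred == -1 & truth == -1)
  fp <- sum(pred == 1 & truth == -1); fn <- sum(pred == -1 & truth == 1)
  list(accuracy = (tp + tn) / length(truth),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       tp = tp, tn = tn, fp = fp, fn = fn)
}

.stage_seed <- function(master, offset) (master + offset) %% 2147483647L

#' Run the full association-mining pipeline
#'
#' Executes, in order: table load (and optional median binarization);
#' pairwise entanglement scoring between gene-role and symptom-role
#' features; Grover-amplified mining of frequent gene-symptom-disease
#' combinations; higher-order Ising estimation plus annealing and coupling
#' ranking; and quantum-kernel SVM classification of the disease feature on
#' a seeded 7:3 split. Stages can be switched off via `config$stages`.
#' Stage failures are reported with the stage name; results of completed
#' stages are kept in the returned report.
#'
#' @param config a [pipeline_config()]; `input` is a CSV/TSV path (with
#'   `roles` a JSON path or named vector) or an in-memory
#'   [feature_table()].
#' @return A list of class `association_report` with sections
#'   `entanglement`, `mined`, `ising`, `classifier` and `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  table <- if (inherits(config$input, "feature_table")) config$input
  else read_feature_table(config$input,
                          roles_path = if (is.character(config$roles))
                            config$roles else NULL,
                          roles = if (!is.character(config$roles))
                            config$roles else NULL,
                          binarize = isTRUE(config$binarize))
  genes <- config$genes %||% features_by_role(table, "gene")
  symptoms <- config$symptoms %||% features_by_role(table, "symptom")
  diseases <- config$diseases %||% features_by_role(table, "disease")
  report <- list(entanglement = NULL, mined = NULL, ising = NULL,
                 classifier = NULL)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if ("entangle" %in% config$stages && length(genes) && length(symptoms)) {
    report$entanglement <- run_stage("entangle", {
      scores <- entanglement_matrix(table, genes, symptoms)
      edges <- data.frame(
        feature_a = rep(rownames(scores), times = ncol(scores)),
        feature_b = rep(colnames(scores), each = nrow(scores)),
        score = as.vector(scores))
      edges[order(-edges$score, edges$feature_a, edges$feature_b), ,
            drop = FALSE]
    })
  }
  if ("mine" %in% config$stages && length(c(genes, symptoms, diseases))) {
    report$mined <- run_stage("mine",
      mine_combinations(table, genes, symptoms, diseases,
                        min_support = config$min_support))
  }
  if ("ising" %in% config$stages) {
    report$ising <- run_stage("ising", {
      feats <- c(genes, symptoms, diseases)
      model <- estimate_ising(table, feats, max_order = config$max_order)
      sched <- anneal_schedule(
        n_sweeps = config$n_sweeps,
        temperature_start = config$temperature_start,
        temperature_end = config$temperature_end,
        transverse_field_start = config$transverse_field_start,
        transverse_field_end = config$transverse_field_end,
        n_trotter = config$n_trotter, n_restarts = config$n_restarts,
        seed = .stage_seed(config$seed, 101L))
      ground <- switch(config$annealer,
                       sa = simulated_annealing(model, sched),
                       sqa = simulated_quantum_annealing(model, sched),
                       bruteforce = ground_state_bruteforce(model))
      list(model = model,
           associations = model_to_associations(model),
           ground_state = ground$configuration,
           ground_energy = ground$energy,
           annealer = config$annealer)
    })
  }
  if ("classify" %in% config$stages) {
    report$classifier <- run_stage("classify", {
      disease <- config$disease_feature %||% diseases[1]
      if (is.null(disease) || is.na(disease))
        stop("no disease-role feature available to classify")
      predictors <- setdiff(table$feature_names, disease)
      parts <- split_train_test(table, ratio = config$split_ratio,
                                seed = .stage_seed(config$seed, 202L))
      Xtr <- parts$train$records[, predictors, drop = FALSE]
      ytr <- 2 * parts$train$records[, disease] - 1
      fit <- train_qsvm(Xtr, ytr, spec = kernel_spec(length(predictors)),
                        C = config$C, tolerance = config$kkt_tolerance)
      metrics <- evaluate_classifier(fit, parts$test, disease, predictors)
      train_acc <- mean(predict(fit, Xtr) == ytr)
      c(list(disease_feature = disease, n_train = nrow(Xtr),
             n_test = nrow(parts$test$records),
             training_accuracy = train_acc, fit = fit), metrics)
    })
  }
  cfgfile <- tempfile(fileext = ".json")
  cfg <- unclass(config)
  cfg$input <- if (inherits(cfg$input, "feature_table")) "<in-memory table>"
               else cfg$input
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), cfgfile)
  report$provenance <- list(
    config_hash = unname(tools::md5sum(cfgfile)),
    seed = config$seed,
    tool_version = as.character(utils::packageVersion("quantmine")))
  unlink(cfgfile)
  class(report) <- "association_report"
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.association_report <- function(x, ...) {
  cat("<association_report>\n")
  if (!is.null(x$entanglement))
    cat("  entanglement edges:", nrow(x$entanglement), "\n")
  if (!is.null(x$mined))
    cat("  mined combinations:", nrow(x$mined), "\n")
  if (!is.null(x$ising)) {
    top <- head(x$ising$associations, 3)
    cat("  top interactions:\n")
    for (r in seq_len(nrow(top)))
      cat(sprintf("    %d. [order %d] %s  coef %.4f\n", r, top$order[r],
                  top$features[r], top$coefficient[r]))
  }
  if (!is.null(x$classifier))
    cat(sprintf("  classifier: accuracy %.3f (train %.3f) on %d test records\n",
                x$classifier$accuracy, x$classifier$training_accuracy,
                x$classifier$n_test))
  invisible(x)
}

#' Write an association report to disk
#'
#' Writes `report.json` plus human-readable TSV sections
#' (`entanglement.tsv`, `mined.tsv`, `interactions.tsv`) into a directory.
#'
#' @param report an `association_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "association_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- list(provenance = report$provenance)
  if (!is.null(report$entanglement)) {
    out$entanglement <- report$entanglement
    utils::write.table(report$entanglement,
                       file.path(dir, "entanglement.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$mined)) {
    out$mined <- as.data.frame(report$mined)
    utils::write.table(as.data.frame(report$mined),
                       file.path(dir, "mined.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$ising)) {
    out$ising <- list(associations = report$ising$associations,
                      ground_state = report$ising$ground_state,
                      ground_energy = report$ising$ground_energy,
                      annealer = report$ising$annealer)
    utils::write.table(report$ising$associations,
                       file.path(dir, "interactions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$classifier))
    out$classifier <- report$classifier[setdiff(names(report$classifier),
                                                "fit")]
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                              dataframe = "columns", null = "null"),
             file.path(dir, "report.json"))
  invisible(dir)
}

#' Permutation-null filter for ranked interactions
#'
#' Optional multiplicity control: re-estimates the coupling of each of the
#' top interactions on tables whose target column is permuted, and reports
#' the fraction of permuted replicates with an absolute coefficient at
#' least as large (a permutation p-value). Off by default in the pipeline.
#'
#' @param table a [feature_table()].
#' @param associations data.frame from [model_to_associations()].
#' @param n_permutations number of seeded permutations (default 200).
#' @param seed integer seed.
#' @param top number of leading interactions to test (default 10).
#' @return The association rows with an added `p_permutation` column.
#' @export
permutation_filter <- function(table, associations, n_permutations = 200L,
                               seed = 1L, top = 10L) {
  stopifnot(inherits(table, "feature_table"))
  assoc <- head(associations, top)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  nrec <- nrow(table$records)
  pvals <- vapply(seq_len(nrow(assoc)), function(r) {
    feats <- strsplit(assoc$features[r], ":", fixed = TRUE)[[1]]
    sig <- 2 * table$records[, feats, drop = FALSE] - 1
    C <- sweep(sig, 2, colMeans(sig))
    obs <- abs(mean(apply(C, 1, prod)))
    exceed <- 0L
    for (p in seq_len(n_permutations)) {
      Cp <- C
      Cp[, ncol(Cp)] <- Cp[sample.int(nrec), ncol(Cp)]
      if (abs(mean(apply(Cp, 1, prod))) >= obs) exceed <- exceed + 1L
    }
    (exceed + 1) / (n_permutations + 1)
  }, numeric(1))
  assoc$p_permutation <- pvals
  assoc
}
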