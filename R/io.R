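# Readers/writers for the package's tabular and JSON formats, plus the run
# configuration loader. CSV dialect: comma-delimited, UTF-8, mandatory
# header row, first column = patient ID; TSV accepted via extension.

#' Patient-by-feature binary table
#'
#' @param records integer/numeric matrix of 0/1 values; columns are
#'   features (must be named), rows are patients.
#' @param roles named character vector mapping every feature to one of
#'   `gene`, `symptom`, `disease`, `environment`.
#' @return An object of class `feature_table` with fields `records`,
#'   `feature_names` and `feature_roles`.
#' @export
feature_table <- function(records, roles) {
  m <- as.matrix(records)
  if (is.null(colnames(m))) stop("feature columns must be named")
  if (anyDuplicated(colnames(m)))
    stop("duplicate feature names: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (anyNA(m)) stop("missing values are not allowed after preprocessing")
  if (!all(m %in% c(0, 1))) {
    bad <- which(!(m %in% c(0, 1)))[1]
    rc <- arrayInd(bad, dim(m))
    stop("non-binary cell at row ", rc[1], ", column '",
         colnames(m)[rc[2]], "' (value ", m[bad],
         "); binarize the input first")
  }
  storage.mode(m) <- "integer"
  roles <- unlist(roles)
  missing_role <- setdiff(colnames(m), names(roles))
  if (length(missing_role))
    stop("missing role for feature(s): ",
         paste(missing_role, collapse = ", "))
  roles <- roles[colnames(m)]
  if (!all(roles %in% c("gene", "symptom", "disease", "environment")))
    stop("roles must be one of gene, symptom, disease, environment")
  structure(list(records = m, feature_names = colnames(m),
                 feature_roles = roles),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$records), " patients x ",
      ncol(x$records), " features (",
      paste(sprintf("%s:%d", names(table(x$feature_roles)),
                    table(x$feature_roles)), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Features of a table having a given role
#'
#' @param table a [feature_table()].
#' @param role one of `gene`, `symptom`, `disease`, `environment`.
#' @return Character vector of feature names.
#' @export
features_by_role <- function(table, role) {
  stopifnot(inherits(table, "feature_table"))
  table$feature_names[table$feature_roles == role]
}

#' Read a feature table from CSV/TSV plus a roles sidecar
#'
#' The delimiter is chosen from the extension (`.tsv`/`.tab` = tab,
#' anything else = comma). The first column holds patient IDs; the sidecar
#' JSON maps each feature name to its role. Non-binary cells are rejected
#' unless `binarize = TRUE`, in which case each non-binary column is
#' thresholded at its median (values strictly above the median become 1).
#'
#' @param path CSV/TSV file.
#' @param roles_path JSON file of feature-to-role mappings; alternatively
#'   pass the mapping itself via `roles`.
#' @param roles optional named character vector used instead of
#'   `roles_path`.
#' @param binarize threshold non-binary columns at the column median.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, roles_path = NULL, roles = NULL,
                               binarize = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  tsv <- grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)
  df <- if (tsv) read.delim(path, check.names = FALSE)
        else read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L) stop("expected a patient-ID column plus features")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (binarize) {
    for (j in seq_len(ncol(m))) {
      v <- m[, j]
      if (!all(v %in% c(0, 1))) m[, j] <- as.integer(v > stats::median(v))
    }
  } else if (!all(m %in% c(0, 1))) {
    bad <- which(!(m %in% c(0, 1)))[1]
    rc <- arrayInd(bad, dim(m))
    stop("non-binary cell at row ", rc[1], " (patient '", ids[rc[1]],
         "'), column '", colnames(m)[rc[2]],
         "'; pass binarize = TRUE to threshold at the column median")
  }
  if (is.null(roles)) {
    if (is.null(roles_path)) stop("either roles_path or roles is required")
    roles <- unlist(jsonlite::fromJSON(roles_path))
  }
  feature_table(m, roles)
}

#' Write a feature table as CSV/TSV with a roles sidecar
#'
#' @param table a [feature_table()].
#' @param path CSV/TSV output file (extension picks the delimiter).
#' @param roles_path optional JSON sidecar path for the role map.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, roles_path = NULL) {
  stopifnot(inherits(table, "feature_table"))
  ids <- rownames(table$records)
  if (is.null(ids)) ids <- sprintf("P%04d", seq_len(nrow(table$records)))
  df <- data.frame(patient_id = ids, table$records, check.names = FALSE)
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(roles_path))
    writeLines(jsonlite::toJSON(as.list(table$feature_roles),
                                auto_unbox = TRUE), roles_path)
  invisible(path)
}

# Recognized configuration keys with their defaults (NULL = required or
# optional without default).
.config_defaults <- function() list(
  input = NULL, roles = NULL, output_dir = NULL,
  seed = NULL, split_ratio = 0.7, binarize = FALSE,
  stages = c("entangle", "mine", "ising", "classify"),
  genes = NULL, symptoms = NULL, diseases = NULL,
  min_support = 0.1, max_order = 3L, annealer = "sqa",
  n_sweeps = 2000L, temperature_start = 2.0, temperature_end = 0.05,
  transverse_field_start = 2.5, transverse_field_end = 0.01,
  n_trotter = 8L, n_restarts = 8L,
  C = 10, kkt_tolerance = 1e-3, disease_feature = NULL,
  entanglement_terms = 8L, entanglement_restarts = 16L
)

#' Load and validate a pipeline configuration
#'
#' Reads a YAML or JSON configuration, fills defaults, and fails closed:
#' unknown keys are rejected with a nearest-key suggestion, and basic range
#' checks run on every value.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON configuration file.
#' @return A validated list of class `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::fromJSON(path)
  do.call(pipeline_config, raw)
}

#' Construct a pipeline configuration
#'
#' @param ... configuration keys; see [load_config()] for the recognized
#'   set. `seed` is mandatory. `input` may be a file path or an in-memory
#'   [feature_table()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  supplied <- list(...)
  defaults <- .config_defaults()
  unknown <- setdiff(names(supplied), names(defaults))
  if (length(unknown)) {
    hints <- vapply(unknown, function(k) {
      d <- adist(k, names(defaults))
      names(defaults)[which.min(d)]
    }, character(1))
    stop("unknown config key(s): ",
         paste(sprintf("'%s' (did you mean '%s'?)", unknown, hints),
               collapse = ", "))
  }
  cfg <- defaults
  cfg[names(supplied)] <- supplied
  if (is.null(cfg$seed)) stop("config key 'seed' is required")
  cfg$seed <- as.integer(cfg$seed)
  if (!is.numeric(cfg$split_ratio) || cfg$split_ratio <= 0 ||
      cfg$split_ratio >= 1)
    stop("split_ratio must lie strictly inside (0, 1), got ",
         cfg$split_ratio)
  if (!all(cfg$stages %in% c("entangle", "mine", "ising", "classify")))
    stop("stages must be drawn from entangle, mine, ising, classify")
  if (!cfg$annealer %in% c("sa", "sqa", "bruteforce"))
    stop("annealer must be 'sa', 'sqa' or 'bruteforce'")
  if (cfg$min_support < 0 || cfg$min_support > 1)
    stop("min_support must lie in [0, 1]")
  cfg$max_order <- as.integer(cfg$max_order)
  if (!cfg$max_order %in% c(2L, 3L)) stop("max_order must be 2 or 3")
  structure(cfg, class = "pipeline_config")
}

#' Write a run manifest
#'
#' Records the configuration hash, master seed, package version and the
#' md5 checksum of every written artifact, sufficient to replay the run.
#'
#' @param config a `pipeline_config`.
#' @param artifacts character vector of artifact file paths.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, artifacts, path) {
  cfgfile <- tempfile(fileext = ".json")
  on.exit(unlink(cfgfile))
  cfg <- unclass(config)
  cfg$input <- if (inherits(cfg$input, "feature_table")) "<in-memory table>"
               else cfg$input
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), cfgfile)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfgfile)),
    seed = config$seed,
    tool_version = as.character(utils::packageVersion("quantmine")),
    artifacts = lapply(artifacts, function(a)
      list(path = a, md5 = unname(tools::md5sum(a)))))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             path)
  invisible(path)
}
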