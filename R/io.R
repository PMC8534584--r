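# Feature-matrix CSV round-trip and run configuration.

#' Write a feature matrix with metadata as CSV
#'
#' Columns: `id`, `participant_id`, `label`, then the feature columns in
#' manifest order. Values are written with 17 significant digits so the
#' round-trip is lossless at double precision.
#'
#' @param dataset A [cohort_dataset()] whose columns follow `manifest`.
#' @param path Output path.
#' @param manifest Manifest data.frame (default [feature_manifest()]);
#'   pass `NULL` to skip the column check.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(dataset, path,
                                 manifest = feature_manifest()) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  if (!is.null(manifest) && !identical(colnames(dataset$X), manifest$name))
    stop("feature columns do not match the manifest")
  pid <- dataset$participant_id
  if (is.null(pid)) pid <- rep(NA_character_, length(dataset$ids))
  header <- c("id", "participant_id", "label", colnames(dataset$X))
  lines <- vapply(seq_along(dataset$ids), function(i) {
    paste(c(dataset$ids[i], pid[i], dataset$y[i],
            sprintf("%.17g", dataset$X[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(paste(header, collapse = ","), lines), path)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path CSV path.
#' @param manifest Manifest to validate the columns against (`NULL` skips).
#' @return A [cohort_dataset()].
#' @export
read_feature_matrix <- function(path, manifest = feature_manifest()) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(id = "character",
                                       participant_id = "character"))
  stopifnot(all(c("id", "participant_id", "label") %in% names(df)))
  feat_cols <- setdiff(names(df), c("id", "participant_id", "label"))
  if (!is.null(manifest) && !identical(feat_cols, manifest$name))
    stop("feature columns do not match the manifest")
  X <- as.matrix(df[, feat_cols, drop = FALSE])
  pid <- if (all(is.na(df$participant_id))) NULL else df$participant_id
  if (nrow(df) == 0)
    return(structure(list(X = X, y = integer(0), ids = character(0),
                          participant_id = NULL),
                     class = "cohort_dataset"))
  cohort_dataset(X, df$label, ids = df$id, participant_id = pid)
}

#' Read and validate a run configuration
#'
#' YAML configuration with one section per stage. Unknown top-level keys
#' are rejected; missing keys fall back to package defaults. The resolved
#' configuration (defaults merged in) is returned so runs can persist it
#' alongside outputs.
#'
#' @param path YAML file path.
#' @return Named list: `seed`, `synthesis`, `channel`, `qc`, `pitch`,
#'   `split`, `cv`, `ranker`, `classifier`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    seed = 1L,
    synthesis = list(duration = 5, base_f0 = 150),
    channel = list(target_fs = 8000, bit_depth = 16,
                   passband = c(300, 3400)),
    qc = qc_thresholds(),
    pitch = list(f_min = 50, f_max = 500, voicing_threshold = 0.2),
    split = list(n_per_class = 1500),
    cv = list(folds = 10, iterations = 100, k_max = 30),
    ranker = "simba",
    classifier = "svm"
  )
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  for (nm in names(cfg)) {
    if (is.list(defaults[[nm]]) && is.list(cfg[[nm]])) {
      bad <- setdiff(names(cfg[[nm]]), names(defaults[[nm]]))
      if (length(bad) > 0)
        stop("unknown keys under '", nm, "': ", paste(bad, collapse = ", "))
      defaults[[nm]][names(cfg[[nm]])] <- cfg[[nm]]
    } else {
      defaults[[nm]] <- cfg[[nm]]
    }
  }
  defaults
}
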