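# Two-step evaluation protocol: balanced-subset construction, 10-fold CV
# with per-fold feature selection and a performance-vs-k curve, and final
# validation on the unbalanced held-out remainder.

#' Draw the balanced-subset / held-out split
#'
#' Uniform random sampling without replacement of `n_per_class` recordings
#' per class; the held-out set is the complement. With the study's class
#' counts (1987 PD / 9955 control) and `n_per_class = 1500` this yields a
#' balanced set of 3000 and a held-out set of 8942 (487 PD + 8455
#' control) for any seed.
#'
#' @param dataset A [cohort_dataset()].
#' @param n_per_class Recordings sampled per class (default 1500).
#' @param seed Integer seed.
#' @param by_participant Subject-wise mode: sample whole participants
#'   until each class's recording quota is filled (avoids the same
#'   participant appearing on both sides; changes the exact balanced
#'   count when participants contribute multiple phonations).
#' @return An object of class `split_plan` with `balanced_ids`,
#'   `heldout_ids`, `n_per_class`, `seed`.
#' @export
make_split <- function(dataset, n_per_class = 1500, seed = 1L,
                       by_participant = FALSE) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  counts <- table(factor(dataset$y, levels = c(0, 1)))
  if (any(counts < n_per_class))
    stop("insufficient class size for n_per_class = ", n_per_class)
  balanced <- with_local_seed(seed, {
    if (by_participant) {
      stopifnot(!is.null(dataset$participant_id))
      unlist(lapply(c(1L, 0L), function(cl) {
        idx <- which(dataset$y == cl)
        parts <- sample(unique(dataset$participant_id[idx]))
        chosen <- character(0)
        for (pt in parts) {
          if (length(chosen) >= n_per_class) break
          chosen <- c(chosen,
                      dataset$ids[idx[dataset$participant_id[idx] == pt]])
        }
        chosen
      }))
    } else {
      unlist(lapply(c(1L, 0L), function(cl)
        sample(dataset$ids[dataset$y == cl], n_per_class)))
    }
  })
  structure(list(balanced_ids = balanced,
                 heldout_ids = setdiff(dataset$ids, balanced),
                 n_per_class = n_per_class, seed = seed,
                 by_participant = by_participant),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> balanced %d, held-out %d (seed %d)\n",
              length(x$balanced_ids), length(x$heldout_ids), x$seed))
  invisible(x)
}

#' Subset a cohort dataset by recording ids
#'
#' @param dataset A [cohort_dataset()].
#' @param ids Recording ids to keep (order preserved).
#' @return A [cohort_dataset()].
#' @export
subset_dataset <- function(dataset, ids) {
  stopifnot(all(ids %in% dataset$ids))
  i <- match(ids, dataset$ids)
  cohort_dataset(dataset$X[i, , drop = FALSE], dataset$y[i], ids = ids,
                 participant_id = dataset$participant_id[i])
}

resolve_ranker <- function(ranker) {
  if (is.function(ranker)) return(ranker)
  switch(ranker,
    gso = function(X, y, seed) gso_rank(X, y),
    relief = function(X, y, seed) relief_rank(X, y),
    simba = function(X, y, seed) simba_rank(X, y, seed = seed),
    stop("unknown ranker: ", ranker))
}

#' Cross-validated performance-vs-k curve with per-fold feature selection
#'
#' Per iteration the balanced set is shuffled into `folds` stratified
#' folds; per fold, features are ranked on the training fold only, and for
#' each `k` in `1..k_max` a classifier is trained on the top-k features
#' and evaluated on the test fold. Reports mean and SD of balanced
#' accuracy, sensitivity and specificity per `k`, the vote tally of the
#' per-fold rankings, and `chosen_k` — the smallest `k` whose mean
#' balanced accuracy is within one SD of the maximum.
#'
#' @param balanced A balanced [cohort_dataset()].
#' @param ranker `"gso"`, `"relief"`, `"simba"`, or a function
#'   `(X, y, seed) -> feature_ranking`.
#' @param classifier_config A `classifier_config`; a single-row grid skips
#'   inner tuning (used for the reduced test profile).
#' @param folds CV folds (default 10).
#' @param iterations CV repetitions.
#' @param k_max Largest feature count examined (default 30).
#' @param inner_cv_folds Inner folds for hyper-parameter tuning.
#' @param seed Integer seed.
#' @return An object of class `performance_curve`: `curve` (data.frame per
#'   k), `chosen_k`, `tally` (a `vote_tally`), plus the settings.
#' @export
run_cv <- function(balanced, ranker = "simba",
                   classifier_config = svm_config(), folds = 10,
                   iterations = 100, k_max = 30, inner_cv_folds = 5,
                   seed = 1L) {
  stopifnot(inherits(balanced, "cohort_dataset"))
  rank_fn <- resolve_ranker(ranker)
  X <- balanced$X; y <- balanced$y
  acc <- array(NA_real_, dim = c(iterations, folds, k_max, 3),
               dimnames = list(NULL, NULL, NULL, c("sens", "spec", "ba")))
  rankings <- list()

  for (it in seq_len(iterations)) {
    it_seed <- (seed * 1000003 + it) %% 2147483647
    fold_id <- with_local_seed(it_seed, stratified_folds(y, folds))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      rk <- rank_fn(X[tr, , drop = FALSE], y[tr], it_seed + f)
      rankings[[length(rankings) + 1]] <- rk
      for (k in seq_len(k_max)) {
        feats <- rk$order[seq_len(k)]
        mdl <- tune_and_train(X[tr, feats, drop = FALSE], y[tr],
                              classifier_config,
                              inner_cv_folds = inner_cv_folds,
                              seed = it_seed + f)
        rep_k <- evaluate(mdl, X[!tr, feats, drop = FALSE], y[!tr])
        acc[it, f, k, ] <- c(rep_k$sensitivity, rep_k$specificity,
                             rep_k$balanced_accuracy)
      }
    }
  }
  curve <- data.frame(
    k = seq_len(k_max),
    ba_mean = apply(acc[, , , "ba", drop = FALSE], 3, mean, na.rm = TRUE),
    ba_sd = apply(acc[, , , "ba", drop = FALSE], 3, stats::sd, na.rm = TRUE),
    sens_mean = apply(acc[, , , "sens", drop = FALSE], 3, mean, na.rm = TRUE),
    sens_sd = apply(acc[, , , "sens", drop = FALSE], 3, stats::sd, na.rm = TRUE),
    spec_mean = apply(acc[, , , "spec", drop = FALSE], 3, mean, na.rm = TRUE),
    spec_sd = apply(acc[, , , "spec", drop = FALSE], 3, stats::sd, na.rm = TRUE)
  )
  i_max <- which.max(curve$ba_mean)
  chosen_k <- min(curve$k[curve$ba_mean >= curve$ba_mean[i_max] -
                            curve$ba_sd[i_max]])
  structure(list(curve = curve, chosen_k = chosen_k,
                 tally = vote(rankings), ranker = ranker,
                 folds = folds, iterations = iterations, seed = seed),
            class = "performance_curve")
}

#' @export
print.performance_curve <- function(x, ...) {
  i <- which.max(x$curve$ba_mean)
  cat(sprintf("<performance_curve> %d-fold x %d iterations; best mean BA %.1f%% at k=%d; chosen_k=%d\n",
              x$folds, x$iterations, x$curve$ba_mean[i], x$curve$k[i],
              x$chosen_k))
  invisible(x)
}

#' Train the final model and validate on the untouched held-out set
#'
#' Ranks features on the full balanced set, trains the final classifier on
#' the top `chosen_k` features (scaling and tuning on balanced data only),
#' and evaluates once on the held-out set, returning the full confusion
#' matrix. Errors if the two datasets share any recording id (provenance
#' guard).
#'
#' @param balanced,heldout [cohort_dataset()]s from a [make_split()] plan.
#' @param chosen_k Number of top-ranked features for the final model.
#' @param ranker As in [run_cv()].
#' @param classifier_config A `classifier_config`.
#' @param inner_cv_folds Inner folds for hyper-parameter tuning.
#' @param seed Integer seed.
#' @return List with `report` (an `eval_report`), `model`, `ranking`,
#'   `features` (selected column names).
#' @export
finalize_and_validate <- function(balanced, heldout, chosen_k,
                                  ranker = "simba",
                                  classifier_config = svm_config(),
                                  inner_cv_folds = 5, seed = 1L) {
  stopifnot(inherits(balanced, "cohort_dataset"),
            inherits(heldout, "cohort_dataset"))
  if (length(intersect(balanced$ids, heldout$ids)) > 0)
    stop("provenance violation: held-out ids overlap the balanced set")
  rk <- resolve_ranker(ranker)(balanced$X, balanced$y, seed)
  feats <- rk$order[seq_len(chosen_k)]
  mdl <- tune_and_train(balanced$X[, feats, drop = FALSE], balanced$y,
                        classifier_config, inner_cv_folds = inner_cv_folds,
                        seed = seed)
  rep_out <- evaluate(mdl, heldout$X[, feats, drop = FALSE], heldout$y)
  list(report = rep_out, model = mdl, ranking = rk,
       features = colnames(balanced$X)[feats])
}
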