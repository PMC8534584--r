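#' Specification of a synthetic two-class phonation cohort
#'
#' Emulates the structure of a telephone-voice screening cohort: two classes
#' of phonations (PD = label 1, control = label 0) differing in their
#' perturbation-parameter distributions, multiple phonations per participant,
#' and per-class demographics. Defaults mirror the study cohort structure
#' (1987 PD / 9955 control phonations from 1078 / 5453 participants; PD ages
#' 62.65 (12.03), controls 49.19 (15.89); male fractions 566/1078 and
#' 2976/5453), with the PD class given elevated perturbation means (2x the
#' control means) — a configurable separation, not a physiological claim.
#'
#' @param n_pd_recordings,n_control_recordings Phonation counts per class.
#' @param n_pd_participants,n_control_participants Participant counts per
#'   class (each participant contributes >= 1 recording).
#' @param pd_params,control_params Named lists of `c(mean, sd)` pairs for
#'   `jitter`, `shimmer`, `noise`, `base_f0`; values are clipped to valid
#'   [phonation_spec()] ranges.
#' @param pd_age,control_age `c(mean, sd)` of age in years per class.
#' @param pd_male_frac,control_male_frac Male proportion per class.
#' @param duration Phonation duration in seconds.
#' @param seed Integer seed; cohorts are fully reproducible from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pd_recordings = 1987, n_control_recordings = 9955,
                        n_pd_participants = 1078,
                        n_control_participants = 5453,
                        control_params = list(jitter = c(0.006, 0.002),
                                              shimmer = c(0.03, 0.01),
                                              noise = c(0.01, 0.005),
                                              base_f0 = c(140, 30)),
                        pd_params = list(jitter = c(0.012, 0.004),
                                         shimmer = c(0.06, 0.02),
                                         noise = c(0.02, 0.01),
                                         base_f0 = c(140, 30)),
                        pd_age = c(62.65, 12.03),
                        control_age = c(49.19, 15.89),
                        pd_male_frac = 566 / 1078,
                        control_male_frac = 2976 / 5453,
                        duration = 5, seed = 1L) {
  stopifnot(n_pd_recordings >= n_pd_participants,
            n_control_recordings >= n_control_participants,
            n_pd_participants >= 1, n_control_participants >= 1)
  structure(as.list(environment()), class = "cohort_spec")
}

# Draw per-participant parameters, clipped into valid spec ranges.
draw_class_params <- function(n, pars) {
  draw <- function(ms, lo, hi) pmin(pmax(stats::rnorm(n, ms[1], ms[2]), lo), hi)
  data.frame(
    jitter_level  = draw(pars$jitter, 0, 0.2),
    shimmer_level = draw(pars$shimmer, 0, 0.5),
    noise_level   = draw(pars$noise, 0, 1),
    base_f0       = draw(pars$base_f0, 60, 400)
  )
}

# Assign n_rec recordings to n_part participants, each getting >= 1.
assign_participants <- function(n_rec, n_part) {
  extra <- n_rec - n_part
  owner <- seq_len(n_part)
  if (extra > 0)
    owner <- c(owner, sample.int(n_part, extra, replace = TRUE))
  sample(owner)   # shuffle recording order
}

#' Generate a labelled synthetic phonation cohort
#'
#' Produces per-recording metadata (participant id, label, age, gender,
#' perturbation parameters, per-recording seed) for the requested class
#' counts. With `synthesize = TRUE` the phonation waveforms and their
#' ground truth are also realized (and channel-degraded when `channel` is
#' given); with `synthesize = FALSE` only metadata and per-recording
#' [phonation_spec()]s are returned and waveforms can be realized on demand
#' with [synthesize_phonation()].
#'
#' @param cs A [cohort_spec()].
#' @param synthesize Realize waveforms now? Default `FALSE`.
#' @param channel Optional [channel_spec()] applied to each realized
#'   waveform.
#' @return A list of class `phonation_cohort` with elements `metadata`
#'   (data.frame), `specs` (list of [phonation_spec()]), and, when
#'   `synthesize = TRUE`, `recordings` (list of `list(p, ground_truth)`).
#' @export
generate_cohort <- function(cs, synthesize = FALSE, channel = NULL) {
  stopifnot(inherits(cs, "cohort_spec"))
  with_local_seed(cs$seed, {
    build_class <- function(label, n_rec, n_part, pars, age_ms, male_frac,
                            part_prefix) {
      pp <- draw_class_params(n_part, pars)
      pp$age <- pmin(pmax(round(stats::rnorm(n_part, age_ms[1], age_ms[2])), 18), 95)
      pp$gender <- ifelse(stats::runif(n_part) < male_frac, "M", "F")
      owner <- assign_participants(n_rec, n_part)
      data.frame(
        participant_id = sprintf("%s%05d", part_prefix, owner),
        label = label,
        age = pp$age[owner], gender = pp$gender[owner],
        jitter_level = pp$jitter_level[owner],
        shimmer_level = pp$shimmer_level[owner],
        noise_level = pp$noise_level[owner],
        base_f0 = pp$base_f0[owner],
        stringsAsFactors = FALSE
      )
    }
    md <- rbind(
      build_class(1L, cs$n_pd_recordings, cs$n_pd_participants,
                  cs$pd_params, cs$pd_age, cs$pd_male_frac, "P"),
      build_class(0L, cs$n_control_recordings, cs$n_control_participants,
                  cs$control_params, cs$control_age, cs$control_male_frac, "C")
    )
    md$file <- sprintf("phon%06d.wav", seq_len(nrow(md)))
    md$seed <- as.integer((as.numeric(cs$seed) * 10007 + seq_len(nrow(md))) %%
                            2147483647)
    md <- md[, c("file", "participant_id", "label", "age", "gender",
                 "jitter_level", "shimmer_level", "noise_level",
                 "base_f0", "seed")]
    rownames(md) <- NULL

    specs <- lapply(seq_len(nrow(md)), function(i)
      phonation_spec(duration = cs$duration, base_f0 = md$base_f0[i],
                     jitter_level = md$jitter_level[i],
                     shimmer_level = md$shimmer_level[i],
                     noise_level = md$noise_level[i],
                     seed = md$seed[i]))

    out <- list(metadata = md, specs = specs)
    if (synthesize) {
      out$recordings <- lapply(seq_along(specs), function(i) {
        r <- synthesize_phonation(specs[[i]])
        if (!is.null(channel))
          r$p <- apply_telephone_channel(r$p, channel,
                                         noise_seed = md$seed[i] + 1L)
        r$p$meta <- c(r$p$meta, as.list(md[i, c("file", "participant_id",
                                                "label", "age", "gender")]))
        r
      })
    }
    structure(out, class = "phonation_cohort")
  })
}

#' Labelled feature-matrix dataset
#'
#' The container used by the selection and classification stages: a numeric
#' feature matrix with named columns, binary labels (1 = PD, 0 = control),
#' and per-row recording / participant ids for split bookkeeping.
#'
#' @param X Numeric matrix, one row per recording.
#' @param y Integer labels in `{0, 1}`.
#' @param ids Recording ids (default row numbers as strings).
#' @param participant_id Optional participant ids (for subject-wise splits).
#' @return An object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(X, y, ids = NULL, participant_id = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0L, 1L)))
  if (is.null(ids)) ids <- sprintf("rec%06d", seq_len(nrow(X)))
  stopifnot(length(ids) == nrow(X), !anyDuplicated(ids))
  rownames(X) <- ids
  structure(list(X = X, y = y, ids = as.character(ids),
                 participant_id = participant_id),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d recordings x %d features (%d PD / %d control)\n",
              nrow(x$X), ncol(x$X), sum(x$y == 1), sum(x$y == 0)))
  invisible(x)
}

#' Simulate a feature-level cohort with a known informative subset
#'
#' Draws a feature matrix of independent standard-normal columns and shifts
#' the mean of `n_informative` randomly chosen columns by `effect_size`
#' (in SD units) in the PD class. Used to validate the feature-selection and
#' classification stages under a known generative model, where the audio
#' generator cannot control which of the 304 measures carry signal.
#'
#' @param n_pd,n_control Recordings per class.
#' @param n_features Total feature count (default 304, the battery size).
#' @param n_informative Number of class-informative features.
#' @param effect_size Mean shift of informative features in the PD class,
#'   in within-class SD units.
#' @param seed Integer seed.
#' @return A list: `dataset` (a [cohort_dataset()]), `informative` (indices
#'   of the shifted columns).
#' @export
simulate_feature_cohort <- function(n_pd = 300, n_control = 300,
                                    n_features = 304, n_informative = 5,
                                    effect_size = 1, seed = 1L) {
  with_local_seed(seed, {
    n <- n_pd + n_control
    y <- c(rep(1L, n_pd), rep(0L, n_control))
    X <- matrix(stats::rnorm(n * n_features), n, n_features)
    informative <- sort(sample.int(n_features, n_informative))
    X[y == 1L, informative] <- X[y == 1L, informative] + effect_size
    colnames(X) <- sprintf("feat%03d", seq_len(n_features))
    perm <- sample.int(n)
    list(dataset = cohort_dataset(X[perm, , drop = FALSE], y[perm]),
         informative = informative)
  })
}
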