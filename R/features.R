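# The full 304-measure dysphonia battery: manifest and per-recording
# extraction.

#' Manifest of the 304 dysphonia measures
#'
#' Fixed enumeration of the feature battery: 13 families with counts
#' jitter 28, shimmer 21, hnr 4, gq 3, gne 6, vfer 9, emd 6, mfcc 39,
#' f0_related 3, wavelet 182, ppe 1, dfa 1, rpde 1 (total 304). Names and
#' order are frozen; downstream matrices must follow manifest order.
#'
#' @return data.frame with columns `name` and `family` (304 rows).
#' @export
feature_manifest <- function() {
  blocks <- list(
    jitter = jitter_names(), shimmer = shimmer_names(),
    hnr = hnr_names(), gq = gq_names(), gne = gne_names(),
    vfer = vfer_names(), emd = emd_er_names(), mfcc = mfcc_names(),
    f0_related = f0_related_names(), wavelet = wavelet_names(),
    ppe = "ppe.entropy", dfa = "dfa.alpha_norm", rpde = "rpde.entropy"
  )
  data.frame(name = unlist(blocks, use.names = FALSE),
             family = rep(names(blocks), lengths(blocks)),
             stringsAsFactors = FALSE)
}

#' Extract the full 304-measure dysphonia profile of one phonation
#'
#' Runs the complete per-recording analysis: F0 contour on the whole
#' recording, most-stationary 2 s segment selection, cycle extraction on
#' the segment, then every feature family in manifest order. The result is
#' exactly 304 finite values or an error of class `pdvoice_flag` naming
#' the failing family (recordings are flagged, never silently imputed).
#'
#' @param p A [phonation()] that passed quality screening.
#' @param meta List with `age` and `gender` (`"M"`/`"F"`) for the
#'   normative F0 comparisons.
#' @param norms A [normative_f0_table()].
#' @param f0 Optional precomputed full-recording contour.
#' @return Named numeric vector of length 304 in manifest order, with
#'   attribute `segment` (the selected window).
#' @export
extract_all <- function(p, meta = list(age = 60, gender = "M"),
                        norms = normative_f0_table(), f0 = NULL) {
  stopifnot(inherits(p, "phonation"))
  if (is.null(f0)) f0 <- estimate_f0_contour(p)
  win <- select_stationary_segment(p, f0)
  seg <- crop_phonation(p, win$start, win$end)
  f0_seg <- structure(list(
    times = f0$times[win$frame_idx] - win$start,
    f0 = f0$f0[win$frame_idx],
    strength = f0$strength[win$frame_idx],
    voicing_threshold = f0$voicing_threshold
  ), class = "f0_contour")
  cyc <- extract_cycles(seg, f0_seg)

  v <- c(jitter_family(cyc, f0_seg),
         shimmer_family(cyc, seg),
         hnr_nhr(seg, f0_seg),
         gq_family(cyc),
         gne_family(seg),
         vfer_family(seg),
         emd_er_family(seg),
         mfcc_family(seg),
         f0_related_family(f0_seg, meta$age, meta$gender, norms),
         wavelet_family(f0_seg),
         ppe(f0_seg),
         dfa(seg),
         rpde(seg))
  manifest <- feature_manifest()
  stopifnot(identical(names(v), manifest$name))
  if (!all(is.finite(v)))
    flag_family(manifest$family[which(!is.finite(v))[1]],
                "non-finite measure value")
  attr(v, "segment") <- win
  v
}

#' Extract the feature matrix of a synthesized cohort
#'
#' Applies [extract_all()] to each recording of a synthesized
#' `phonation_cohort`; flagged recordings are dropped with a message.
#'
#' @param cohort A [generate_cohort()] result with `recordings` realized.
#' @param norms A [normative_f0_table()].
#' @return A [cohort_dataset()] whose `X` columns follow the manifest.
#' @export
extract_cohort_features <- function(cohort, norms = normative_f0_table()) {
  stopifnot(inherits(cohort, "phonation_cohort"),
            !is.null(cohort$recordings))
  md <- cohort$metadata
  rows <- vector("list", nrow(md))
  ok <- logical(nrow(md))
  for (i in seq_len(nrow(md))) {
    res <- tryCatch(
      extract_all(cohort$recordings[[i]]$p,
                  meta = list(age = md$age[i], gender = md$gender[i]),
                  norms = norms),
      pdvoice_flag = function(e) e)
    if (inherits(res, "pdvoice_flag")) {
      message("recording ", md$file[i], " flagged: ", conditionMessage(res))
    } else {
      rows[[i]] <- res
      ok[i] <- TRUE
    }
  }
  X <- do.call(rbind, rows[ok])
  cohort_dataset(X, md$label[ok], ids = md$file[ok],
                 participant_id = md$participant_id[ok])
}
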