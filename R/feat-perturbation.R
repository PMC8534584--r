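# Jitter, shimmer and glottis-quotient families: cycle-to-cycle
# perturbation statistics of the period and peak-amplitude sequences.
#
# The family sizes (28 jitter, 21 shimmer, 3 GQ) are fixed; the classical
# measures (local, RAP, PPQ5, DDP; local shimmer, shimmer dB, APQ3/5/11,
# DDA) are mandatory members and systematic variants (aggregation x
# transform x source sequence, plus TKEO forms) fill each family to its
# count. The enumeration is frozen: names and order never depend on the
# input.

flag_family <- function(family, msg) {
  stop(structure(class = c("pdvoice_flag", "error", "condition"),
                 list(message = paste0(family, ": ", msg), call = NULL,
                      family = family)))
}

# k-point perturbation quotient: agg |s_i - mean(k-neighborhood)| / norm.
# agg is mean or median; norm = mean(s) (or 1 for already-log sequences).
pq_stat <- function(s, k, agg = mean, norm = mean(s)) {
  n <- length(s)
  h <- (k - 1) / 2
  if (n < k) return(NA_real_)
  i <- (h + 1):(n - h)
  neigh <- vapply(i, function(j) mean(s[(j - h):(j + h)]), numeric(1))
  agg(abs(s[i] - neigh)) / norm
}

local_stat <- function(s, agg = mean, norm = mean(s)) agg(abs(diff(s))) / norm
ddp_stat <- function(s, agg = mean, norm = mean(s)) {
  d <- diff(s)
  agg(abs(diff(d))) / norm
}

tkeo_stats <- function(s) {
  tk <- tkeo(s)
  if (length(tk) < 2) return(c(0, 0))
  c(mean(tk), stats::sd(tk))
}

jitter_names <- function() {
  base <- c("local", "abs", "rap", "ppq5", "ddp")
  c(paste0("jitter.", rep(base, each = 2), "_", c("mean", "median")),
    paste0("jitter.f0frame_", rep(base, each = 2), "_", c("mean", "median")),
    paste0("jitter.logT_", c("local", "rap", "ppq5", "ddp")),
    paste0("jitter.tkeo_", c("T_mean", "T_sd", "f0_mean", "f0_sd")))
}

#' Jitter family: 28 F0-perturbation measures
#'
#' Cycle-period perturbation statistics plus systematic variants. Sources:
#' the cycle-period sequence `T_i`, the 10 ms frame-level F0 sequence, and
#' the log-period sequence. Statistics: local (mean |T_i - T_i+1| / mean T),
#' absolute (seconds / Hz, un-normalized), RAP (3-point perturbation
#' quotient), PPQ5 (5-point), DDP (mean |second difference| / mean), each
#' with mean and median aggregation; log-period variants are un-normalized
#' (already scale-free); TKEO variants are the mean and SD of the
#' Teager-Kaiser energy of each source, normalized by the squared mean.
#'
#' @param c A [extract_cycles()] `cycle_sequence` with >= 12 periods.
#' @param f0 An [estimate_f0_contour()] contour (frame-level variants).
#' @return Named numeric vector of length 28.
#' @export
jitter_family <- function(c, f0) {
  Ti <- c$periods
  if (length(Ti) < 12) flag_family("jitter", "fewer than 12 periods")
  Fv <- f0$f0[!is.na(f0$f0)]
  if (length(Fv) < 12) flag_family("jitter", "fewer than 12 voiced frames")

  seq_block <- function(s) {
    m <- mean(s)
    c(local_stat(s, mean, m), local_stat(s, stats::median, m),
      local_stat(s, mean, 1), local_stat(s, stats::median, 1),
      pq_stat(s, 3, mean, m), pq_stat(s, 3, stats::median, m),
      pq_stat(s, 5, mean, m), pq_stat(s, 5, stats::median, m),
      ddp_stat(s, mean, m), ddp_stat(s, stats::median, m))
  }
  logT <- log(Ti)
  v <- c(seq_block(Ti), seq_block(Fv),
         local_stat(logT, mean, 1), pq_stat(logT, 3, mean, 1),
         pq_stat(logT, 5, mean, 1), ddp_stat(logT, mean, 1),
         tkeo_stats(Ti) / mean(Ti)^2, tkeo_stats(Fv) / mean(Fv)^2)
  stats::setNames(v, jitter_names())
}

shimmer_names <- function() {
  base <- c("local", "db", "apq3", "apq5", "apq11", "dda")
  c(paste0("shimmer.", rep(base, each = 2), "_", c("mean", "median")),
    paste0("shimmer.logA_", c("local", "apq3", "apq5")),
    paste0("shimmer.energy_", c("local", "apq3", "apq5")),
    paste0("shimmer.tkeo_", c("A_mean", "A_sd")),
    "shimmer.abs")
}

#' Shimmer family: 21 amplitude-perturbation measures
#'
#' Cycle peak-amplitude perturbation statistics: local shimmer
#' (mean |A_i - A_i+1| / mean A), shimmer in dB
#' (mean |20 log10(A_i+1 / A_i)|), APQ3, APQ5, APQ11, DDA, each with mean
#' and median aggregation (12); un-normalized log-amplitude variants (3);
#' the same statistics on the 25 ms frame RMS-energy sequence of the
#' analysis segment (3, falling back to the amplitude sequence when no
#' segment is supplied); TKEO mean/SD of the amplitude sequence normalized
#' by the squared mean (2); and the raw mean absolute difference (1).
#'
#' @param c A `cycle_sequence` with >= 12 cycles and positive amplitudes.
#' @param segment Optional [phonation()] segment for the frame-energy
#'   variants.
#' @return Named numeric vector of length 21.
#' @export
shimmer_family <- function(c, segment = NULL) {
  Ai <- c$amplitudes
  if (length(Ai) < 12) flag_family("shimmer", "fewer than 12 cycles")
  if (any(Ai <= 0)) flag_family("shimmer", "non-positive cycle amplitude")

  mA <- mean(Ai)
  db_seq <- abs(20 * log10(Ai[-1] / Ai[-length(Ai)]))
  Ei <- if (!is.null(segment)) {
    fr <- frame_signal(segment$samples, round(0.025 * segment$fs),
                       round(0.010 * segment$fs))
    e <- sqrt(colMeans(fr^2))
    e[e > 0]
  } else Ai
  if (length(Ei) < 12) Ei <- Ai
  mE <- mean(Ei)

  v <- c(local_stat(Ai, mean, mA), local_stat(Ai, stats::median, mA),
         mean(db_seq), stats::median(db_seq),
         pq_stat(Ai, 3, mean, mA), pq_stat(Ai, 3, stats::median, mA),
         pq_stat(Ai, 5, mean, mA), pq_stat(Ai, 5, stats::median, mA),
         pq_stat(Ai, 11, mean, mA), pq_stat(Ai, 11, stats::median, mA),
         ddp_stat(Ai, mean, mA), ddp_stat(Ai, stats::median, mA),
         local_stat(log(Ai), mean, 1), pq_stat(log(Ai), 3, mean, 1),
         pq_stat(log(Ai), 5, mean, 1),
         local_stat(Ei, mean, mE), pq_stat(Ei, 3, mean, mE),
         pq_stat(Ei, 5, mean, mE),
         tkeo_stats(Ai) / mA^2,
         local_stat(Ai, mean, 1))
  # APQ11 needs 11 cycles; with >= 12 it is defined, but guard NA anyway
  v[is.na(v)] <- 0
  stats::setNames(v, shimmer_names())
}

gq_names <- function() paste0("gq.", c("sd_rel", "range90_rel", "frac_dev5"))

#' Glottis quotient family: 3 cycle-duration-change measures
#'
#' (1) SD of cycle periods relative to the median period; (2) the 5th-95th
#' percentile range of periods relative to the median; (3) the fraction of
#' cycles deviating more than 5% from the median period.
#'
#' @param c A `cycle_sequence` with >= 12 cycles.
#' @return Named numeric vector of length 3.
#' @export
gq_family <- function(c) {
  Ti <- c$periods
  if (length(Ti) < 12) flag_family("gq", "fewer than 12 cycles")
  md <- stats::median(Ti)
  q <- stats::quantile(Ti, c(0.05, 0.95), names = FALSE)
  v <- c(stats::sd(Ti) / md, (q[2] - q[1]) / md,
         mean(abs(Ti - md) / md > 0.05))
  stats::setNames(v, gq_names())
}
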