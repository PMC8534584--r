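# Nonlinear measures: pitch period entropy, detrended fluctuation
# analysis, and recurrence period density entropy.

#' Pitch period entropy (PPE)
#'
#' The voiced F0 contour is mapped to semitones relative to its median
#' (`s_t = 12 log2(f0_t / median f0)`), whitened with an order-2 linear
#' predictor fit to the sequence (which absorbs natural smooth variation
#' such as slow drift), and the prediction residuals are histogrammed over
#' a fixed +/-12 semitone range with 60 bins. PPE is the normalized
#' Shannon entropy of that histogram, in \[0, 1\]. A constant contour is
#' defined to have PPE 0.
#'
#' @param f0 An [estimate_f0_contour()] contour with >= 50 voiced frames
#'   (or a numeric vector of F0 values).
#' @return PPE in \[0, 1\] (named scalar).
#' @export
ppe <- function(f0) {
  v <- if (inherits(f0, "f0_contour")) f0$f0[!is.na(f0$f0)] else
    f0[!is.na(f0)]
  if (length(v) < 50) flag_family("ppe", "fewer than 50 voiced frames")
  s <- 12 * log2(v / stats::median(v))
  if (stats::sd(s) < 1e-9) return(c(ppe.entropy = 0))
  n <- length(s)
  fit <- stats::lm(s[3:n] ~ s[2:(n - 1)] + s[1:(n - 2)])
  r <- stats::resid(fit)
  r <- r[abs(r) <= 12]
  if (length(r) < 2) return(c(ppe.entropy = 0))
  h <- graphics::hist(r, breaks = seq(-12, 12, length.out = 61),
                      plot = FALSE)$counts
  q <- h / sum(h)
  c(ppe.entropy = shannon_entropy(q[q > 0]) / log(60))
}

#' Detrended fluctuation analysis scaling exponent
#'
#' The mean-removed signal is integrated; for box sizes log-spaced in
#' `box_range` the RMS of the linearly detrended profile `F(L)` is
#' computed, and the scaling exponent `alpha` is the least-squares slope
#' of `log F` versus `log L`. White noise gives `alpha ~ 0.5`; a random
#' walk gives `alpha ~ 1.5`; the exponent is invariant to positive
#' rescaling of the signal.
#'
#' @param x Numeric vector (>= 4000 samples for a stable estimate).
#' @param box_range `c(min, max)` box sizes in samples.
#' @param n_boxes Number of log-spaced box sizes.
#' @return The scaling exponent `alpha`.
#' @export
dfa_exponent <- function(x, box_range = c(50, 1000), n_boxes = 15) {
  if (length(x) < 4000) flag_family("dfa", "fewer than 4000 samples")
  if (stats::sd(x) < 1e-12) flag_family("dfa", "constant signal")
  y <- cumsum(x - mean(x))
  n <- length(y)
  Ls <- unique(round(exp(seq(log(box_range[1]), log(min(box_range[2], n %/% 4)),
                             length.out = n_boxes))))
  FL <- vapply(Ls, function(L) {
    n_box <- n %/% L
    Y <- matrix(y[seq_len(n_box * L)], nrow = L)
    t <- seq_len(L)
    res <- qr.resid(qr(cbind(1, t)), Y)
    sqrt(mean(res^2))
  }, numeric(1))
  unname(stats::coef(stats::lm(log(FL) ~ log(Ls)))[2])
}

#' DFA measure (normalized exponent)
#'
#' The battery's DFA feature: the scaling exponent from [dfa_exponent()]
#' mapped through the logistic function `1 / (1 + exp(-alpha))` so the
#' measure is bounded in (0, 1).
#'
#' @param segment A [phonation()] analysis segment (>= 4000 samples).
#' @return Named scalar in (0, 1).
#' @export
dfa <- function(segment) {
  a <- dfa_exponent(segment$samples)
  c(dfa.alpha_norm = 1 / (1 + exp(-a)))
}

#' Recurrence period density entropy (RPDE)
#'
#' The signal is time-delay embedded (dimension `m`, delay `tau` samples);
#' for each embedded point the first return time into an `eps`-ball around
#' it (after first leaving the ball) is recorded; RPDE is the normalized
#' Shannon entropy of the return-time histogram up to `t_max`, in
#' \[0, 1\]. A strictly periodic signal returns at a single delay and
#' scores 0; broadband noise spreads the density and scores near 1.
#' Embedding defaults (m = 4, tau = 7 at 8 kHz, eps = 0.12 x embedded SD)
#' follow common practice for sustained vowels.
#'
#' @param segment A [phonation()] analysis segment (>= 4000 samples).
#' @param m Embedding dimension.
#' @param tau Embedding delay in samples.
#' @param eps_factor Ball radius as a multiple of the signal SD.
#' @param t_max Maximum return time (histogram support) in samples.
#' @return Named scalar in \[0, 1\].
#' @export
rpde <- function(segment, m = 4, tau = 7, eps_factor = 0.12, t_max = 1000) {
  x <- segment$samples
  if (length(x) < 4000) flag_family("rpde", "fewer than 4000 samples")
  s <- stats::sd(x)
  if (s < 1e-12) flag_family("rpde", "constant signal")
  tt <- rpde_return_times(x, m, tau, eps_factor * s * sqrt(m), t_max)
  if (length(tt) == 0) flag_family("rpde", "no recurrences found")
  h <- tabulate(tt, nbins = t_max)
  p <- h / sum(h)
  c(rpde.entropy = shannon_entropy(p[p > 0]) / log(t_max))
}

# Normalized entropy of a return-time histogram (exposed for the
# entropy-identity checks).
rpde_entropy <- function(counts, t_max = length(counts)) {
  p <- counts / sum(counts)
  shannon_entropy(p[p > 0]) / log(t_max)
}
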