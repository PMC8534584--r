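# Empirical mode decomposition by standard sifting with cubic-spline
# envelopes and the classical SD < 0.2 stopping criterion.

local_extrema <- function(x) {
  n <- length(x)
  d <- diff(x)
  s <- sign(d)
  # collapse plateaus so sign changes are detected once
  s[s == 0] <- NA
  s <- zoo_locf(s)
  turns <- which(diff(s) != 0) + 1L
  list(max = turns[s[turns - 1] > 0], min = turns[s[turns - 1] < 0])
}

# last-observation-carried-forward for the plateau handling above
zoo_locf <- function(v) {
  ok <- !is.na(v)
  if (!any(ok)) return(rep(1, length(v)))
  idx <- cummax(ifelse(ok, seq_along(v), 0L))
  idx[idx == 0L] <- which(ok)[1]
  v[idx]
}

spline_envelope <- function(idx, val, n) {
  # mirror the end extrema so the spline does not diverge at the edges
  xi <- c(2 - idx[1], idx, 2 * n - idx[length(idx)])
  yi <- c(val[1], val, val[length(val)])
  stats::spline(xi, yi, xout = seq_len(n))$y
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions (IMFs) by sifting:
#' upper/lower cubic-spline envelopes through the local extrema are averaged
#' and subtracted until the normalized squared change between consecutive
#' sifts drops below `sd_stop` (default 0.2) or `max_sift` iterations are
#' reached. Decomposition stops when the residue has fewer than 2 maxima
#' and 2 minima or `max_imf` IMFs have been extracted.
#'
#' @param x Numeric vector.
#' @param max_imf Maximum number of IMFs.
#' @param sd_stop Sifting stop criterion.
#' @param max_sift Maximum sifting iterations per IMF.
#' @return List with `imfs` (list of numeric vectors) and `residue`.
#' @export
emd_decompose <- function(x, max_imf = 10, sd_stop = 0.2, max_sift = 30) {
  imfs <- list()
  res <- x
  n <- length(x)
  for (k in seq_len(max_imf)) {
    ex <- local_extrema(res)
    if (length(ex$max) < 2 || length(ex$min) < 2) break
    h <- res
    for (s in seq_len(max_sift)) {
      ex <- local_extrema(h)
      if (length(ex$max) < 2 || length(ex$min) < 2) break
      upper <- spline_envelope(ex$max, h[ex$max], n)
      lower <- spline_envelope(ex$min, h[ex$min], n)
      m <- (upper + lower) / 2
      h_new <- h - m
      sd_val <- sum((h - h_new)^2) / max(sum(h^2), 1e-300)
      h <- h_new
      if (sd_val < sd_stop) break
    }
    imfs[[k]] <- h
    res <- res - h
  }
  list(imfs = imfs, residue = res)
}
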