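# Periodized discrete wavelet transform with Daubechies db8 (16-tap)
# filters. No DWT package ships with the dependency set, so the pyramid
# algorithm is implemented directly; band energies are verified in tests
# against frozen reference values.

db8_dec_lo <- c(
  -1.1747678412476953e-04, 6.7544940645056933e-04, -3.9174037337694705e-04,
  -4.8703529934515741e-03, 8.7460940474057766e-03, 1.3981027917398282e-02,
  -4.4088253930794755e-02, -1.7369301001807547e-02, 1.2874742662047847e-01,
  4.7248457391328279e-04, -2.8401554296154691e-01, -1.5829105256349306e-02,
  5.8535468365420673e-01, 6.7563073629728976e-01, 3.1287159091429995e-01,
  5.4415842243104008e-02
)

# One periodized analysis step: returns list(approx, detail), each length n/2.
dwt_step <- function(x, lo) {
  n <- length(x)
  stopifnot(n %% 2 == 0)
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1)   # quadrature mirror filter
  half <- n / 2
  idx <- outer(seq(0, n - 2, by = 2), seq_len(L) - 1L, "+") %% n + 1L
  Xm <- matrix(x[idx], nrow = half)
  list(approx = as.numeric(Xm %*% lo), detail = as.numeric(Xm %*% hi))
}

#' Multi-level periodized wavelet decomposition (db8)
#'
#' Decomposes `x` (length a multiple of `2^levels`; callers pad) into
#' `levels` detail bands plus one final approximation band using the 16-tap
#' Daubechies filter with periodic boundary handling. The transform is
#' orthogonal, so band energies sum to the signal energy.
#'
#' @param x Numeric vector, length divisible by `2^levels`.
#' @param levels Number of decomposition levels.
#' @return Named list: `d1` (finest detail) ... `d<levels>`, `a` (final
#'   approximation).
#' @export
dwt_db8 <- function(x, levels = 10) {
  n <- length(x)
  if (n %% 2^levels != 0)
    stop("length must be divisible by 2^levels (pad the input)")
  out <- vector("list", levels + 1)
  names(out) <- c(paste0("d", seq_len(levels)), "a")
  cur <- x
  for (j in seq_len(levels)) {
    st <- dwt_step(cur, db8_dec_lo)
    out[[paste0("d", j)]] <- st$detail
    cur <- st$approx
  }
  out$a <- cur
  out
}
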