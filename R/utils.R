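#' @useDynLib ssvepr, .registration = TRUE
#' @keywords internal
"_PACKAGE"

# Single-pass IIR filter (direct form II transposed), zero initial conditions.
iir_filter <- function(b, a, x) {
  if (a[1] != 1) {
    b <- b / a[1]
    a <- a / a[1]
  }
  .Call(C_iir_filter, as.double(b), as.double(a), as.double(x))
}

# Zero-phase (forward-backward) IIR filtering with odd reflection padding.
# `pad` defaults to the filter's ring-down length (where the impulse
# response has decayed to ~1e-9, from the slowest pole), capped by the
# signal length.
filtfilt_refl <- function(b, a, x, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) {
    rho <- max(Mod(polyroot(rev(a / a[1]))))
    pad <- if (rho < 1) ceiling(log(1e-9) / log(rho)) else n - 1L
  }
  pad <- max(1L, min(as.integer(pad), n - 1L))
  # odd (point-symmetric) reflection about the end samples
  head_pad <- 2 * x[1] - x[(pad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - pad)]
  xp <- c(head_pad, x, tail_pad)
  y <- iir_filter(b, a, xp)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}

# Evaluate the transfer function b(z)/a(z) at analog frequencies `freq` (Hz)
# for sampling rate `fs`. Returns complex response.
transfer_function <- function(b, a, freq, fs) {
  w <- 2 * pi * freq / fs
  z <- exp(-1i * w)
  m <- max(length(b), length(a))
  b <- c(b, rep(0, m - length(b)))
  a <- c(a, rep(0, m - length(a)))
  # Horner evaluation; common z^(m-1) factor cancels in the ratio
  num <- Reduce(function(acc, coef) acc * z + coef, b[-1], init = b[1] + 0i)
  den <- Reduce(function(acc, coef) acc * z + coef, a[-1], init = a[1] + 0i)
  num / den
}

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x
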