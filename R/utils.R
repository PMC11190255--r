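# Small numeric helpers shared across modules.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding used wherever percentages are reported in
#' table style. `base::round()` rounds half to even, which would turn 84.5
#' into 84; reported consumption totals and screen percentages use half-up.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep.
#' @return Numeric vector rounded half away from zero.
#' @examples
#' roundHalfUp(84.5)  # 85
#' roundHalfUp(6.345, 2)
#' @export
roundHalfUp <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Centered rolling median; shrinking windows at the edges.
rollMedian <- function(x, window = 5L) {
  if (window <= 1L || length(x) < 3L) return(x)
  window <- min(window, length(x))
  if (window %% 2L == 0L) window <- window - 1L
  as.numeric(stats::runmed(x, k = window, endrule = "median"))
}

# Least-squares slope of y on t over every window of `w` consecutive points.
# Returns slopes and the window-center times. O(n) via cumulative sums.
slidingSlopes <- function(t, y, w) {
  n <- length(t)
  stopifnot(w >= 2L, n >= w)
  csum <- function(v) c(0, cumsum(v))
  St <- csum(t); Sy <- csum(y); Stt <- csum(t * t); Sty <- csum(t * y)
  i <- seq_len(n - w + 1L)
  j <- i + w - 1L
  st <- St[j + 1L] - St[i]
  sy <- Sy[j + 1L] - Sy[i]
  stt <- Stt[j + 1L] - Stt[i]
  sty <- Sty[j + 1L] - Sty[i]
  denom <- w * stt - st^2
  slope <- (w * sty - st * sy) / denom
  list(slope = slope, center = st / w)
}

# Derive a 32-bit child seed from a master seed and a stream index.
childSeed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(index)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
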