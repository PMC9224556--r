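# Internal helpers shared across modules.

# Evaluate `code` with a temporarily fixed RNG state; NULL seed leaves the
# global stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Bilinear interpolation of a matrix at (possibly fractional) row/col
# positions, 1-based; positions outside the frame are clamped to the border.
sample_bilinear <- function(frame, r, c) {
  nr <- nrow(frame)
  nc <- ncol(frame)
  r <- clamp(as.vector(r), 1, nr)
  c <- clamp(as.vector(c), 1, nc)
  r0 <- pmin(floor(r), nr - 1L)
  c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0
  fc <- c - c0
  frame[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    frame[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    frame[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    frame[cbind(r0 + 1, c0 + 1)] * fr * fc
}

# Zero-phase moving-average smoothing with reflection padding (keeps the
# height of extrema that fall exactly on the signal boundary).
smooth_ma <- function(x, width) {
  width <- max(3L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  h <- width %/% 2L
  n <- length(x)
  h2 <- min(h, n - 1L)
  left <- rev(x[seq_len(h2) + 1L])
  right <- rev(x[n - seq_len(h2)])
  if (h2 < h) {
    left <- c(rep(x[1], h - h2), left)
    right <- c(right, rep(x[n], h - h2))
  }
  xp <- c(left, x, right)
  as.numeric(stats::filter(xp, rep(1 / width, width), sides = 2))[(h + 1):(h + n)]
}

# Local maxima of a numeric vector, boundary-inclusive, with a minimum
# separation in samples (taller peak wins within the separation window).
find_peaks <- function(x, min_sep = 1L) {
  n <- length(x)
  if (n < 2L) return(integer(0))
  is_peak <- logical(n)
  for (i in seq_len(n)) {
    left_ok <- i == 1L || x[i] >= x[i - 1L]
    right_ok <- i == n || x[i] >= x[i + 1L]
    strict <- (i > 1L && x[i] > x[i - 1L]) || (i < n && x[i] > x[i + 1L]) ||
      (i == 1L && x[i] > x[2L]) || (i == n && x[i] > x[n - 1L])
    is_peak[i] <- left_ok && right_ok && strict
  }
  peaks <- which(is_peak)
  if (length(peaks) <= 1L || min_sep <= 1L) return(peaks)
  # enforce separation: greedy by height
  ord <- peaks[order(x[peaks], decreasing = TRUE)]
  kept <- integer(0)
  for (p in ord) {
    if (all(abs(kept - p) >= min_sep)) kept <- c(kept, p)
  }
  sort(kept)
}

# Linear interpolation over station positions with constant extrapolation.
interp_linear <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, rule = 2)$y
}
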