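# Fixture builders shared across the suite.  Everything is generated in
# code; no stored binary data.

# Horizontal dark-band frame: lumen (low intensity) band of width_px pixels
# centred on band_center between bright walls.
band_frame <- function(nr = 120, nc = 160, band_center = 60.5,
                       width_px = 40, lumen = 30 / 255, wall = 200 / 255) {
  fr <- matrix(wall, nr, nc)
  rows <- matrix(seq_len(nr), nr, nc)
  fr[abs(rows - band_center) < width_px / 2] <- lumen
  fr
}

band_init <- function(portion_mm = 50) {
  tracking_init(rbind(c(20, 80), c(100, 80)), roi = c(30, 91, 20, 140),
                portion_mm = portion_mm)
}

# Tilted band in physical coordinates: perpendicular width in mm at a given
# axis angle, isotropic spacing.
tilted_band_frame <- function(theta, width_mm, n = 200, spacing = 0.5,
                              lumen = 30 / 255, wall = 200 / 255) {
  y <- matrix((seq_len(n) - n / 2) * spacing, n, n)
  x <- matrix((seq_len(n) - n / 2) * spacing, n, n, byrow = TRUE)
  dist <- y * cos(theta) - x * sin(theta)
  fr <- matrix(wall, n, n)
  fr[abs(dist) < width_mm / 2] <- lumen
  fr
}

# Frame with two Gaussian blobs (trackable features) at given centres.
blob_frame <- function(centers, nr = 120, nc = 120, base = 0.2,
                       amp = 0.7, noise_sd = 0.02) {
  fr <- matrix(base, nr, nc)
  for (k in seq_len(nrow(centers))) {
    r0 <- centers[k, 1]; c0 <- centers[k, 2]
    for (dr in -6:6) for (dc in -6:6) {
      fr[r0 + dr, c0 + dc] <- fr[r0 + dr, c0 + dc] + amp * exp(-(dr^2 + dc^2) / 8)
    }
  }
  fr <- fr + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
  pmin(pmax(fr, 0), 1)
}

# Pure-waveform diameter series (identical at all 5 stations).
sine_series <- function(freq_hz, duration_s = 3, fps = 30, d0 = 19,
                        p = 0.3, noise_frac = 0) {
  t <- seq(0, duration_s, by = 1 / fps)
  d <- d0 * (1 - p * (1 - cos(2 * pi * freq_hz * t)) / 2)
  if (noise_frac > 0) d <- d * (1 + noise_frac * rnorm(length(t)))
  diameter_series(t, matrix(rep(d, 5), ncol = 5),
                  seq(-7.5, 7.5, length.out = 5))
}

# Cohort with 3 informative clinical features, 3 pure-noise columns and
# reasonably balanced RAP classes.
selection_cohort <- function(seed, n = 200) {
  withr::with_seed(seed, {
    z1 <- rnorm(n); z2 <- rnorm(n); z3 <- rnorm(n)
    tab <- data.frame(PAWP = 15 + 7 * z1, TAPSE = 19 + 6 * z2,
                      IVCd = 19 + 5 * z3, noise1 = rnorm(n),
                      noise2 = rnorm(n), noise3 = rnorm(n))
    tab$RAP <- pmin(pmax(7.5 + 2.5 * z1 - 2 * z2 + 1.5 * z3 + rnorm(n, 0, 1),
                         0), 24)
    tab
  })
}

# Brute-force sliding-window median with edge replication (oracle for the
# compiled filter).
median_filter_oracle <- function(x, k) {
  h <- k %/% 2
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ri <- pmin(pmax((i - h):(i + h), 1), nr)
      cj <- pmin(pmax((j - h):(j + h), 1), nc)
      out[i, j] <- median(x[ri, cj])
    }
  }
  out
}

# Brute-force confusion-matrix tally (oracle).
confusion_oracle <- function(truth, pred) {
  m <- matrix(0L, 3, 3)
  for (i in seq_along(truth)) {
    m[truth[i], pred[i]] <- m[truth[i], pred[i]] + 1L
  }
  m
}

# Hand evaluation of the published six-feature linear model (independent
# of lm_predict / lm_design).
hand_lm <- function(pawp, tapse, ee, trd, cci, d) {
  0.26 + 11.59 * pawp / 33.7 + 3.89 * tapse / 35 - 8.28 * ee / 30 -
    2.3 * trd / 4 + 3.693 / (cci + 0.3) + 2.82 * d / 34
}
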