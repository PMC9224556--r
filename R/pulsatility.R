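#' Segment heartbeats from a diameter signal
#'
#' The five-station average diameter is low-pass smoothed and successive
#' local maxima (vessel most distended, between cardiac collapses) delimit
#' the beats.  Maxima at the signal boundaries count, so a clip starting at
#' peak distension contributes its first beat.  Inter-peak intervals must
#' be compatible with the admissible heart-rate range; intervals outside it
#' are discarded.
#'
#' @param series A [diameter_series()].
#' @param hr_range Admissible heart rate in beats per minute, default
#'   \code{c(40, 180)}.
#' @param smooth_s Moving-average smoothing window in seconds (default
#'   0.15 s).
#' @return List of beat intervals, each \code{c(start_index, end_index)}
#'   (frame indices of consecutive diameter maxima).
#' @export
segment_beats <- function(series, hr_range = c(40, 180), smooth_s = 0.2) {
  stopifnot(inherits(series, "diameter_series"))
  times <- series$times
  if (length(times) < 3L) stop("no complete beat detected: series too short")
  fs <- 1 / mean(diff(times))
  sig <- rowMeans(series$diameters)
  # two moving-average passes ~ triangular low-pass: strong speckle-noise
  # rejection with little attenuation at heart-rate frequencies
  w <- max(3L, round(smooth_s * fs))
  sig <- smooth_ma(smooth_ma(sig, w), w)
  min_sep <- max(2L, floor(60 / hr_range[2] * fs))
  peaks <- find_peaks(sig, min_sep = min_sep)
  # only candidates comparable in height to peak distension count: this
  # rejects residual noise bumps near the cycle minimum and clip
  # boundaries that merely cut the signal mid-slope
  amp <- diff(range(sig))
  if (amp > 0) {
    peaks <- peaks[sig[peaks] >= max(sig) - 0.35 * amp]
  }
  if (length(peaks) < 2L) stop("no complete beat detected")
  ok_int <- list()
  for (i in seq_len(length(peaks) - 1L)) {
    period <- times[peaks[i + 1L]] - times[peaks[i]]
    bpm <- 60 / period
    if (bpm >= hr_range[1] && bpm <= hr_range[2]) {
      ok_int[[length(ok_int) + 1L]] <- c(peaks[i], peaks[i + 1L])
    }
  }
  if (length(ok_int) == 0L) {
    stop("no complete beat detected within the heart-rate range ",
         hr_range[1], "-", hr_range[2], " bpm")
  }
  ok_int
}

#' Cardiac caval index and mean diameter
#'
#' For every diameter station and every heartbeat the cardiac caval index
#' is the fractional collapse (max - min) / max of that diameter within the
#' beat; all station-by-beat values are averaged into a single CCI.  The
#' mean diameter averages all stations over all frames.  An alternative
#' convention normalizing by the within-beat mean instead of the maximum is
#' available via \code{denominator = "mean"}.
#'
#' @param series A [diameter_series()].
#' @param beats Beat intervals from [segment_beats()].
#' @param denominator \code{"max"} (default, fractional decrease from peak
#'   distension) or \code{"mean"}.
#' @return Object of class \code{ivc_features}: \code{cci} (fraction),
#'   \code{mean_diameter_mm}, \code{n_beats} and the per-beat,
#'   per-station CCI matrix \code{per_beat_cci}.
#' @export
compute_cci <- function(series, beats, denominator = c("max", "mean")) {
  stopifnot(inherits(series, "diameter_series"))
  denominator <- match.arg(denominator)
  if (length(beats) < 1L) stop("at least one beat is required")
  nb <- length(beats)
  cci_mat <- matrix(NA_real_, nrow = nb, ncol = 5L)
  for (b in seq_len(nb)) {
    idx <- beats[[b]][1]:beats[[b]][2]
    for (d in 1:5) {
      tr <- series$diameters[idx, d]
      mx <- max(tr)
      if (mx <= 0) stop("degenerate diameter trace (max <= 0)")
      den <- if (denominator == "max") mx else mean(tr)
      cci_mat[b, d] <- (mx - min(tr)) / den
    }
  }
  structure(list(
    cci = mean(cci_mat),
    mean_diameter_mm = mean(series$diameters),
    n_beats = nb,
    per_beat_cci = cci_mat,
    denominator = denominator
  ), class = "ivc_features")
}

#' @export
print.ivc_features <- function(x, ...) {
  cat(sprintf("<ivc_features: CCI %.3f (%.1f%%), mean diameter %.2f mm, %d beat(s)>\n",
              x$cci, 100 * x$cci, x$mean_diameter_mm, x$n_beats))
  invisible(x)
}

#' Pulsatility features of a diameter series
#'
#' Convenience wrapper: beat segmentation followed by CCI computation.
#'
#' @inheritParams segment_beats
#' @inheritParams compute_cci
#' @return An \code{ivc_features} object.
#' @export
ivc_features <- function(series, hr_range = c(40, 180),
                         denominator = c("max", "mean")) {
  compute_cci(series, segment_beats(series, hr_range), denominator)
}

#' Measure CCI and mean diameter directly from a video
#'
#' Runs [track_ivc()] and [ivc_features()] in one step.
#'
#' @param seq An [ultrasound_sequence()].
#' @param init A [tracking_init()].
#' @param ... Passed to [track_ivc()].
#' @return An \code{ivc_features} object with the tracking result attached
#'   as attribute \code{"tracking"}.
#' @export
measure_ivc <- function(seq, init, ...) {
  tk <- track_ivc(seq, init, ...)
  feats <- ivc_features(tk$series)
  attr(feats, "tracking") <- tk
  feats
}
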