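#' Tracking initialization
#'
#' User-supplied first-frame information for the semi-automated delineation:
#' two reference points used to compensate vessel motion, a rectangular
#' region of interest bounding the IVC portion to analyze, an approximate
#' vessel-axis direction and the along-axis extent of the analyzed portion.
#'
#' @param ref_points 2x2 matrix of pixel coordinates (row, col), one row per
#'   reference point.
#' @param roi Rectangle \code{c(row_min, row_max, col_min, col_max)} in
#'   pixels.
#' @param axis_hint Approximate axis direction \code{c(drow, dcol)} in pixel
#'   units; normalized internally.  Defaults to the horizontal axis.
#' @param portion_mm Along-axis extent (mm) of the analyzed portion; must be
#'   at least 15 mm so the central 15 mm diameter span fits.
#' @return An object of class \code{tracking_init}.
#' @export
tracking_init <- function(ref_points, roi, axis_hint = c(0, 1),
                          portion_mm = 20) {
  ref_points <- matrix(as.numeric(ref_points), ncol = 2)
  if (nrow(ref_points) != 2L) stop("ref_points must be two (row, col) points")
  roi <- as.numeric(roi)
  if (length(roi) != 4L || roi[2] <= roi[1] || roi[4] <= roi[3]) {
    stop("roi must be c(row_min, row_max, col_min, col_max) with positive area")
  }
  axis_hint <- as.numeric(axis_hint)
  nv <- sqrt(sum(axis_hint^2))
  if (nv == 0) stop("axis_hint must be a nonzero direction")
  if (portion_mm < 15) {
    stop("portion_mm must be at least 15 mm (central diameter span)")
  }
  structure(list(ref_points = ref_points, roi = roi,
                 axis_hint = axis_hint / nv, portion_mm = portion_mm),
            class = "tracking_init")
}

#' Read/write tracking initialization as a JSON sidecar
#'
#' @param path JSON path.
#' @param init A [tracking_init()].
#' @return The initialization object / the path, invisibly.
#' @export
load_tracking_init <- function(path) {
  x <- jsonlite::fromJSON(path)
  tracking_init(matrix(unlist(x$ref_points), ncol = 2, byrow = is.list(x$ref_points)),
                x$roi, x$axis_hint, x$portion_mm)
}

#' @rdname load_tracking_init
#' @export
save_tracking_init <- function(init, path) {
  jsonlite::write_json(
    list(ref_points = unclass(init$ref_points), roi = init$roi,
         axis_hint = init$axis_hint, portion_mm = init$portion_mm),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Median-filter denoising of a frame
#'
#' 2D median filter with edge replication, the standard speckle-suppression
#' step before gradient-based border detection.
#'
#' @param frame Numeric matrix.
#' @param kernel_size Odd window size, default 5.
#' @return Filtered matrix of the same dimensions.
#' @export
denoise_frame <- function(frame, kernel_size = 5L) {
  kernel_size <- as.integer(kernel_size)
  if (kernel_size < 3L || kernel_size %% 2L == 0L) {
    stop("kernel_size must be an odd integer >= 3")
  }
  median_filter_cpp(frame, kernel_size)
}

#' Track the two reference points across frames
#'
#' Normalized cross-correlation of fixed first-frame templates inside a
#' bounded search window around each point's previous position.  The
#' per-frame displacement used for motion compensation is the average of
#' the two points' displacements from the first frame.
#'
#' @param seq An [ultrasound_sequence()].
#' @param init A [tracking_init()].
#' @param template_half Half-size of the square template (default 10, i.e.
#'   21x21 pixels).
#' @param search_half Half-size of the search window around the previous
#'   position (default 15 px).
#' @param corr_floor Minimum acceptable correlation; below it the point
#'   keeps its previous position and the frame is flagged low-confidence.
#' @return List with \code{displacement} (n_frames x 2 matrix of (drow,
#'   dcol) in px, first row zero), \code{positions} (per-point tracks) and
#'   \code{low_confidence} (logical per frame).
#' @export
track_references <- function(seq, init, template_half = 10L,
                             search_half = 15L, corr_floor = 0.5) {
  stopifnot(inherits(seq, "ultrasound_sequence"),
            inherits(init, "tracking_init"))
  f1 <- get_frame(seq, 1L)
  nr <- nrow(f1); nc <- ncol(f1)
  h <- as.integer(template_half)
  pts <- round(init$ref_points)
  templs <- vector("list", 2L)
  for (p in 1:2) {
    r <- pts[p, 1]; c <- pts[p, 2]
    if (r - h < 1 || r + h > nr || c - h < 1 || c + h > nc) {
      stop(sprintf("template around reference point %d falls outside frame", p))
    }
    templs[[p]] <- f1[(r - h):(r + h), (c - h):(c + h)]
  }
  nf <- n_frames(seq)
  pos <- array(NA_real_, dim = c(nf, 2L, 2L))  # frame x point x (row, col)
  pos[1, , ] <- pts
  lowconf <- logical(nf)
  for (t in seq_len(nf)[-1]) {
    ft <- get_frame(seq, t)
    for (p in 1:2) {
      prev <- pos[t - 1, p, ]
      res <- ncc_search_cpp(ft, templs[[p]],
                            as.integer(prev[1]) - 1L,
                            as.integer(prev[2]) - 1L,
                            as.integer(search_half))
      if (res$score < corr_floor) {
        pos[t, p, ] <- prev
        lowconf[t] <- TRUE
      } else {
        pos[t, p, ] <- c(res$row + 1L, res$col + 1L)
      }
    }
  }
  disp <- matrix(0, nrow = nf, ncol = 2L,
                 dimnames = list(NULL, c("drow", "dcol")))
  for (t in seq_len(nf)) {
    disp[t, ] <- colMeans(matrix(pos[t, , ], ncol = 2L)) - colMeans(pts)
  }
  list(displacement = disp, positions = pos, low_confidence = lowconf)
}

# Geometry helpers: all border work happens in physical (mm) coordinates
# x = (col - 1) * spacing_col, y = (row - 1) * spacing_row so that
# orthogonality and distances are correct for anisotropic pixels.
px_to_mm <- function(pts_px, spacing) {
  cbind((pts_px[, 1] - 1) * spacing[1], (pts_px[, 2] - 1) * spacing[2])
}

mm_to_px <- function(pts_mm, spacing) {
  cbind(pts_mm[, 1] / spacing[1] + 1, pts_mm[, 2] / spacing[2] + 1)
}

# Strongest dark-band bracket on a gradient profile: the pair i < j
# maximizing grad[j] - grad[i] (a bright->dark drop followed by a
# dark->bright rise).  O(m) prefix-minimum scan.
best_edge_pair <- function(grad) {
  m <- length(grad)
  pref_min_idx <- integer(m)
  best_i <- 1L
  for (i in seq_len(m)) {
    if (grad[i] < grad[best_i]) best_i <- i
    pref_min_idx[i] <- best_i
  }
  best_gain <- -Inf; bi <- NA_integer_; bj <- NA_integer_
  for (j in 2:m) {
    i <- pref_min_idx[j - 1L]
    gain <- grad[j] - grad[i]
    if (gain > best_gain) {
      best_gain <- gain; bi <- i; bj <- j
    }
  }
  list(i = bi, j = bj, gain = best_gain)
}

# Sub-sample refinement of an extremum by parabolic fit on three points.
parabolic_refine <- function(y, idx) {
  if (idx <= 1L || idx >= length(y)) return(0)
  denom <- y[idx - 1L] - 2 * y[idx] + y[idx + 1L]
  if (abs(denom) < .Machine$double.eps) return(0)
  clamp(0.5 * (y[idx - 1L] - y[idx + 1L]) / denom, -1, 1)
}

#' Delineate the two IVC borders in one frame
#'
#' At 30 stations equally spaced along the (motion-compensated) vessel axis,
#' a scan line orthogonal to the axis is cast and each border is placed at
#' the strongest intensity transition: the borders are the bright-to-dark
#' and dark-to-bright jumps bracketing the dark lumen, refined to sub-pixel
#' precision by a parabolic fit around the gradient extremum.  When a
#' previous trace is available the search is confined to a band around it
#' for temporal coherence.  Stations with no transition above the noise
#' floor are interpolated from their neighbours and flagged with confidence
#' zero.
#'
#' @param frame Denoised frame (matrix).
#' @param init A [tracking_init()].
#' @param pixel_spacing mm/px (row, col).
#' @param displacement Motion-compensation shift \code{c(drow, dcol)} in px
#'   for this frame (default none).
#' @param prev Optional previous \code{border_trace} for temporal coherence.
#' @param frame_index Stored in the trace.
#' @param band_mm Half-width (mm) of the search band around the previous
#'   border positions (default 2 mm).
#' @param noise_floor Minimum intensity range along a scan line for a
#'   detection to count (default 0.08 on unit-scaled intensities).
#' @return An object of class \code{border_trace}: station coordinates,
#'   upper/lower border offsets (mm), pixel-coordinate border and midline
#'   points (30 each), per-station confidence in \code{[0, 1]}, and the
#'   frame geometry needed to derive diameters.
#' @export
delineate_borders <- function(frame, init, pixel_spacing,
                              displacement = c(0, 0), prev = NULL,
                              frame_index = 1L, band_mm = 2,
                              noise_floor = 0.08, axis = NULL) {
  stopifnot(inherits(init, "tracking_init"))
  spacing <- rep(as.numeric(pixel_spacing), length.out = 2L)
  n_st <- 30L
  # axis: explicit override, else the previous frame's midline direction,
  # else the user's first-frame hint
  refine <- FALSE
  if (!is.null(axis)) {
    u <- axis / sqrt(sum(axis^2))
  } else if (!is.null(prev)) {
    u <- prev$axis
  } else {
    a <- init$axis_hint
    u <- c(a[1] * spacing[1], a[2] * spacing[2])  # px direction -> mm space
    u <- u / sqrt(sum(u^2))
    refine <- TRUE  # hint may be rough: re-run once with the fitted axis
  }
  nvec <- c(-u[2], u[1])
  if (nvec[1] < 0) nvec <- -nvec  # normal points toward increasing row (down)
  roi <- init$roi
  center_px <- c(mean(roi[1:2]), mean(roi[3:4])) + displacement
  center_mm <- c((center_px[1] - 1) * spacing[1], (center_px[2] - 1) * spacing[2])
  s <- seq(-init$portion_mm / 2, init$portion_mm / 2, length.out = n_st)
  # half-extent of the scan lines along the normal
  roi_h_mm <- (roi[2] - roi[1]) * spacing[1]
  roi_w_mm <- (roi[4] - roi[3]) * spacing[2]
  half_extent <- 0.5 * abs(roi_h_mm * nvec[1]) + 0.5 * abs(roi_w_mm * nvec[2])
  step <- min(spacing) / 4
  upper_off <- rep(NA_real_, n_st)
  lower_off <- rep(NA_real_, n_st)
  conf_raw <- rep(0, n_st)
  for (i in seq_len(n_st)) {
    if (!is.null(prev) && is.finite(prev$upper_off[i]) &&
        prev$quality[i] > 0) {
      w_lo <- prev$upper_off[i] - band_mm
      w_hi <- prev$lower_off[i] + band_mm
    } else {
      w_lo <- -half_extent
      w_hi <- half_extent
    }
    w <- seq(w_lo, w_hi, by = step)
    if (length(w) < 7L) next
    py <- center_mm[1] + s[i] * u[1] + w * nvec[1]
    px <- center_mm[2] + s[i] * u[2] + w * nvec[2]
    prof <- sample_bilinear(frame, py / spacing[1] + 1, px / spacing[2] + 1)
    prof <- smooth_ma(prof, 5L)
    if (diff(range(prof)) < noise_floor) next  # dropout: no usable contrast
    grad <- c(0, diff(prof)) / step
    pair <- best_edge_pair(grad)
    if (!is.finite(pair$gain) || pair$gain <= 0) next
    gi <- abs(grad[pair$i]); gj <- abs(grad[pair$j])
    if (max(gi, gj) * step < noise_floor / 4) next
    di <- parabolic_refine(-grad, pair$i)  # extremum of -grad (minimum)
    dj <- parabolic_refine(grad, pair$j)
    upper_off[i] <- w[pair$i] + di * step
    lower_off[i] <- w[pair$j] + dj * step
    conf_raw[i] <- min(gi, gj)
  }
  ok <- is.finite(upper_off) & is.finite(lower_off)
  if (!any(ok)) stop("no border transitions detected in frame ", frame_index)
  if (!all(ok)) {
    upper_off[!ok] <- interp_linear(s[ok], upper_off[ok], s[!ok])
    lower_off[!ok] <- interp_linear(s[ok], lower_off[ok], s[!ok])
  }
  # enforce non-crossing (upper strictly above lower along the normal)
  swap <- upper_off > lower_off
  if (any(swap)) {
    tmp <- upper_off[swap]
    upper_off[swap] <- lower_off[swap]
    lower_off[swap] <- tmp
  }
  quality <- conf_raw / max(conf_raw)
  quality[!ok] <- 0
  mid_off <- (upper_off + lower_off) / 2
  # axis update for the next frame: rotate by the mean midline slope
  slope <- unname(coef(lm(mid_off ~ s))[2])
  u_next <- u + slope * nvec
  u_next <- u_next / sqrt(sum(u_next^2))
  if (refine && abs(slope) > 0.02) {
    # first frame with a rough hint: redo the scan perpendicular to the
    # estimated midline so oblique-sampling bias does not accumulate
    return(delineate_borders(frame, init, pixel_spacing, displacement,
                             prev = NULL, frame_index = frame_index,
                             band_mm = band_mm, noise_floor = noise_floor,
                             axis = u_next))
  }
  point_mm <- function(off) {
    cbind(center_mm[1] + s * u[1] + off * nvec[1],
          center_mm[2] + s * u[2] + off * nvec[2])
  }
  up_mm <- point_mm(upper_off)
  lo_mm <- point_mm(lower_off)
  mid_mm <- point_mm(mid_off)
  structure(list(
    frame_index = frame_index,
    stations = s,
    upper_off = upper_off, lower_off = lower_off,
    upper_border = mm_to_px(up_mm, spacing),
    lower_border = mm_to_px(lo_mm, spacing),
    midline = mm_to_px(mid_mm, spacing),
    quality = quality,
    axis = u_next, axis_used = u, normal = nvec,
    center_mm = center_mm, pixel_spacing = spacing
  ), class = "border_trace")
}

#' Midline-orthogonal diameters over the central 15 mm
#'
#' Computes the vessel midline as the pointwise midpoint of the two borders
#' and measures 5 diameters orthogonal to the local midline tangent at
#' stations equally spaced over the central 15 mm of the analyzed portion
#' (extremities avoided).  The separation measured along the scan normal is
#' projected onto the midline-orthogonal direction, so a vessel tilted with
#' respect to the scan axis still yields its true perpendicular width.
#'
#' @param trace A \code{border_trace} from [delineate_borders()].
#' @param pixel_spacing mm/px (row, col); defaults to the spacing stored in
#'   the trace.
#' @param portion_mm Along-axis extent of the analyzed portion; defaults to
#'   the station span of the trace.  Must be at least 15 mm.
#' @return List with \code{diameters_mm} (length 5) and \code{stations_mm}
#'   (along-axis positions of the 5 stations, centred on the portion).
#' @export
compute_midline_diameters <- function(trace, pixel_spacing = NULL,
                                      portion_mm = NULL) {
  stopifnot(inherits(trace, "border_trace"))
  if (is.null(portion_mm)) portion_mm <- diff(range(trace$stations))
  if (portion_mm < 15) {
    stop("portion_mm must be at least 15 mm to place the 5 central stations")
  }
  st5 <- seq(-7.5, 7.5, length.out = 5L)
  s <- trace$stations
  # local linear fits across stations suppress the per-station jitter of
  # the edge detector (pixel-staircase aliasing on oblique borders)
  local_fit <- function(y, s0, hw = 3) {
    idx <- which(abs(s - s0) <= hw)
    while (length(idx) < 3L) {
      hw <- hw * 1.5
      idx <- which(abs(s - s0) <= hw)
    }
    b <- coef(lm(y[idx] ~ s[idx]))
    c(value = unname(b[1] + b[2] * s0), slope = unname(b[2]))
  }
  mid_off <- (trace$upper_off + trace$lower_off) / 2
  up <- vapply(st5, function(s0) local_fit(trace$upper_off, s0)["value"],
               numeric(1))
  lo <- vapply(st5, function(s0) local_fit(trace$lower_off, s0)["value"],
               numeric(1))
  slope <- vapply(st5, function(s0) local_fit(mid_off, s0)["slope"],
                  numeric(1))
  d <- (lo - up) / sqrt(1 + slope^2)
  if (any(d <= 0)) stop("degenerate (non-positive) diameter encountered")
  list(diameters_mm = d, stations_mm = st5)
}

#' Diameter time series of a tracked sequence
#'
#' @param times Seconds per frame.
#' @param diameters n_frames x 5 matrix of diameters in mm.
#' @param positions Along-axis station positions (mm, length 5).
#' @return An object of class \code{diameter_series}.
#' @export
diameter_series <- function(times, diameters, positions) {
  diameters <- as.matrix(diameters)
  if (ncol(diameters) != 5L) stop("expected 5 diameters per frame")
  if (nrow(diameters) != length(times)) {
    stop("times and diameters disagree in length")
  }
  if (any(!is.finite(diameters)) || any(diameters <= 0)) {
    stop("diameters must be finite and positive")
  }
  structure(list(times = as.numeric(times), diameters = diameters,
                 positions = as.numeric(positions)),
            class = "diameter_series")
}

#' Run the full edge-tracking pipeline on a sequence
#'
#' Denoises every frame with a 2D median filter, tracks the two reference
#' points to compensate vessel motion, delineates the borders frame by
#' frame (each frame's search band centred on the previous trace) and
#' derives the 5 midline-orthogonal diameters.
#'
#' @param seq An [ultrasound_sequence()].
#' @param init A [tracking_init()].
#' @param kernel_size Median-filter window (default 5).
#' @param ... Passed to [delineate_borders()].
#' @return List of class \code{ivc_tracking} with the \code{series}
#'   ([diameter_series()]), per-frame \code{traces} and the reference
#'   tracking result.
#' @export
track_ivc <- function(seq, init, kernel_size = 5L, ...) {
  stopifnot(inherits(seq, "ultrasound_sequence"))
  refs <- track_references(seq, init)
  nf <- n_frames(seq)
  traces <- vector("list", nf)
  prev <- NULL
  diam <- matrix(NA_real_, nrow = nf, ncol = 5L)
  positions <- NULL
  for (t in seq_len(nf)) {
    fr <- denoise_frame(get_frame(seq, t), kernel_size)
    tr <- delineate_borders(fr, init, seq$pixel_spacing,
                            displacement = refs$displacement[t, ],
                            prev = prev, frame_index = t, ...)
    dm <- compute_midline_diameters(tr, portion_mm = init$portion_mm)
    diam[t, ] <- dm$diameters_mm
    positions <- dm$stations_mm
    traces[[t]] <- tr
    prev <- tr
  }
  times <- (seq_len(nf) - 1L) / seq$frame_rate
  structure(list(series = diameter_series(times, diam, positions),
                 traces = traces, references = refs),
            class = "ivc_tracking")
}

#' Export per-frame diameters to CSV
#'
#' @param series A [diameter_series()].
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
save_diameter_series <- function(series, path) {
  stopifnot(inherits(series, "diameter_series"))
  df <- data.frame(time_s = series$times, series$diameters)
  names(df) <- c("time_s", sprintf("diameter_mm_%d", 1:5))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
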