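# Ground-truth generators: speckle videos of a pulsating vessel for the
# tracking pipeline, and patient cohorts with realistic feature moments for
# the RAP models.  Both are deterministic given their seed.

#' Configuration for the synthetic vessel video
#'
#' A quasi-cylindrical vein imaged in long axis: a dark lumen band of
#' instantaneous width \code{D(t) = D0 * (1 - p * (1 - cos(2 pi f t)) / 2)}
#' between bright speckled walls, rigidly translated by a slow respiratory
#' drift.  The wall texture is a static pattern that moves with the drift,
#' so template tracking has real structure to lock onto; an independent
#' per-frame noise component models electronic speckle decorrelation.
#' Defaults follow typical subcostal acquisitions: 19 mm baseline diameter
#' and 42% pulsatility (population means), 72 bpm, 30 fps, 0.2 mm/px,
#' 2 s clips.
#'
#' @param d0_mm Baseline (maximal) diameter in mm.
#' @param pulsatility Fractional cardiac collapse p in \code{[0, 1)}; this
#'   is the ground-truth CCI.
#' @param cardiac_freq_hz Heartbeat frequency (Hz).
#' @param resp_drift_px,resp_freq_hz Amplitude (px, row direction) and
#'   frequency of the sinusoidal respiratory drift.
#' @param axis_angle_deg Vessel axis angle from horizontal, degrees.
#' @param lumen_intensity,wall_intensity Mean intensities in \code{[0, 1]}.
#' @param speckle_sd Standard deviation of the per-frame additive noise.
#' @param texture_contrast Relative contrast of the static wall texture.
#' @param pixel_spacing mm/px (isotropic scalar or (row, col)).
#' @param frame_rate Frames per second; must exceed twice the cardiac
#'   frequency.
#' @param duration_s Clip length in seconds (>= 1 s).
#' @param seed RNG seed for reproducible frames.
#' @return List of class \code{vessel_sim_config}.
#' @export
vessel_sim_config <- function(d0_mm = 19, pulsatility = 0.42,
                              cardiac_freq_hz = 1.2, resp_drift_px = 2,
                              resp_freq_hz = 0.25, axis_angle_deg = 0,
                              lumen_intensity = 0.12, wall_intensity = 0.78,
                              speckle_sd = 0.05, texture_contrast = 0.35,
                              pixel_spacing = 0.2, frame_rate = 30,
                              duration_s = 2, seed = 1L) {
  if (pulsatility < 0 || pulsatility >= 1) stop("pulsatility must be in [0, 1)")
  if (frame_rate <= 2 * cardiac_freq_hz) {
    stop("frame_rate must exceed twice the cardiac frequency (Nyquist)")
  }
  if (duration_s < 1) stop("duration_s must be at least 1 s")
  structure(as.list(environment()), class = "vessel_sim_config")
}

#' Render a synthetic pulsating-vessel ultrasound video
#'
#' @param cfg A [vessel_sim_config()].
#' @return List with \code{sequence} (an [ultrasound_sequence()]),
#'   \code{init} (a ready-made [tracking_init()] for the rendered
#'   geometry) and \code{truth}: per-frame \code{times} and
#'   \code{width_mm}, the generating pulsatility \code{cci}, the mean
#'   width \code{mean_diameter_mm} and the applied per-frame
#'   \code{drift_px}.
#' @export
simulate_vessel_video <- function(cfg = vessel_sim_config()) {
  stopifnot(inherits(cfg, "vessel_sim_config"))
  spacing <- rep(as.numeric(cfg$pixel_spacing), length.out = 2L)
  nf <- round(cfg$duration_s * cfg$frame_rate)
  times <- (seq_len(nf) - 1L) / cfg$frame_rate
  width <- cfg$d0_mm * (1 - cfg$pulsatility * (1 - cos(2 * pi * cfg$cardiac_freq_hz * times)) / 2)
  drift_px <- cfg$resp_drift_px * sin(2 * pi * cfg$resp_freq_hz * times)
  theta <- cfg$axis_angle_deg * pi / 180
  # frame large enough for the band, drift, reference templates and margins
  half_need_mm <- cfg$d0_mm / 2 + 6 + abs(cfg$resp_drift_px) * spacing[1]
  nr <- 2L * (ceiling(half_need_mm / spacing[1]) + 28L)
  portion_mm <- 25
  nc <- ceiling((portion_mm + 10) / spacing[2]) + 40L
  cy <- (nr / 2) * spacing[1]
  cx <- (nc / 2) * spacing[2]
  ymm <- (seq_len(nr) - 1) * spacing[1]
  xmm <- (seq_len(nc) - 1) * spacing[2]
  Y <- matrix(ymm, nr, nc)
  X <- matrix(xmm, nr, nc, byrow = TRUE)
  edge_soft <- 0.15  # mm half-width of the wall/lumen intensity ramp
  frames <- with_seed(cfg$seed, {
    texture <- matrix(runif(nr * nc, -1, 1), nr, nc)
    texture <- median_filter_cpp(texture, 3L)  # correlated, trackable grain
    lapply(seq_len(nf), function(t) {
      dy <- drift_px[t] * spacing[1]
      # signed distance from the (drifted) midline, normal to the axis
      dist <- (Y - cy - dy) * cos(theta) - (X - cx) * sin(theta)
      cov <- clamp((abs(dist) - width[t] / 2 + edge_soft) / (2 * edge_soft), 0, 1)
      tex <- sample_bilinear(texture, Y / spacing[1] + 1 - drift_px[t],
                             X / spacing[2] + 1)
      tex <- matrix(tex, nr, nc)
      wall <- cfg$wall_intensity * (1 + cfg$texture_contrast * tex)
      img <- cfg$lumen_intensity + (wall - cfg$lumen_intensity) * cov
      img <- img + matrix(rnorm(nr * nc, 0, cfg$speckle_sd), nr, nc)
      matrix(round(clamp(img, 0, 1) * 65535) / 65535, nr, nc)
    })
  })
  seq_obj <- ultrasound_sequence(frames, spacing, cfg$frame_rate,
                                 id = "synthetic-vessel")
  ref_off_mm <- cfg$d0_mm / 2 + 3.5
  ref_px <- rbind(
    c((cy - ref_off_mm) / spacing[1] + 1, (cx - 6) / spacing[2] + 1),
    c((cy + ref_off_mm) / spacing[1] + 1, (cx + 6) / spacing[2] + 1))
  roi_h_mm <- cfg$d0_mm / 2 + 4
  roi <- c((cy - roi_h_mm) / spacing[1] + 1, (cy + roi_h_mm) / spacing[1] + 1,
           (cx - portion_mm / 2 - 2) / spacing[2] + 1,
           (cx + portion_mm / 2 + 2) / spacing[2] + 1)
  init <- tracking_init(ref_px, roi,
                        axis_hint = c(sin(theta), cos(theta)),
                        portion_mm = portion_mm)
  list(sequence = seq_obj, init = init,
       truth = list(times = times, width_mm = width,
                    cci = cfg$pulsatility,
                    mean_diameter_mm = mean(width),
                    drift_px = drift_px))
}

# Truncated-normal draws by inverse-CDF sampling (exact, vectorized).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  if (phi <= plo) stop("infeasible truncation bounds")
  qnorm(runif(n, plo, phi), mean, sd)
}

# Population feature moments: mean/SD with physiological truncation bounds
# for normal features, median/IQR for the log-normal biomarkers, and the
# rhythm mixture.  These are the generator's definition of a realistic
# cohort.
cohort_feature_moments <- function() {
  norm <- data.frame(
    feature = c("HR", "LVEF", "CI", "LVMi", "EoverEprime", "PAWP", "LAVi",
                "PVR", "TRV", "RAd", "RVd", "TAPSE", "RV_FAC", "TRd",
                "CCI", "IVCd", "eGFR"),
    mean = c(72, 52, 2.7, 103, 12, 15, 39, 3.3, 336, 46, 29, 19, 35,
             1.876, 0.42, 19, 74.4),
    sd = c(13, 18, 0.7, 36, 8, 7, 14, 2.2, 65, 8, 5, 6, 9, 0.864, 0.20,
           5, 26.9),
    lower = c(30, 10, 0.8, 30, 2, 2, 10, 0.3, 100, 20, 10, 5, 10, 0, 0,
              5, 5),
    upper = c(180, 80, 6, 300, 40, 40, 120, 15, 600, 80, 60, 40, 65, 4,
              0.95, 40, 160),
    stringsAsFactors = FALSE
  )
  lnorm <- data.frame(
    feature = c("NT_proBNP", "TnT_hs"),
    median = c(785, 16.34),
    q1 = c(231, 8.57),
    q3 = c(2429, 30.52),
    stringsAsFactors = FALSE
  )
  list(normal = norm, lognormal = lnorm,
       rhythm_probs = c(sinus = 0.65, afib = 0.28, pacing = 0.07))
}

# Per-column missingness rates of the modelled retrospective registry
# (counts out of 170 records).
cohort_missing_rates <- function() {
  c(HR = 1, CI = 6, LVMi = 2, LAVi = 1, RVd = 1, TAPSE = 3,
    NT_proBNP = 2, TnT_hs = 4, eGFR = 2) / 170
}

#' Configuration for the synthetic patient cohort
#'
#' @param n Number of patients (>= 10), default 170.
#' @param generating_spec [linear_model_spec()] producing the noiseless RAP
#'   from the features; default [published_lm_spec()].
#' @param noise_sd Gaussian noise added to RAP, mmHg.  The default 3.2
#'   corresponds to a mean absolute error of about 2.56 mmHg
#'   (\code{sd = mae * sqrt(pi / 2)}).
#' @param rap_range Admissible RAP range; patients whose noisy RAP falls
#'   outside are redrawn, so the noiseless feature-RAP relation stays
#'   exactly linear within the cohort.
#' @param missing_rates Named per-column missingness probabilities; default
#'   the registry rates, \code{NULL} for complete data.
#' @param seed RNG seed.
#' @return List of class \code{cohort_sim_config}.
#' @export
cohort_sim_config <- function(n = 170, generating_spec = published_lm_spec(),
                              noise_sd = 3.2, rap_range = c(0, 24),
                              missing_rates = cohort_missing_rates(),
                              seed = 20220607) {
  if (n < 10) stop("n must be at least 10")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (!is.null(missing_rates) && any(missing_rates >= 0.05)) {
    stop("missingness must stay below 5% per modelled feature")
  }
  structure(as.list(environment()), class = "cohort_sim_config")
}

draw_cohort_features <- function(n) {
  mom <- cohort_feature_moments()
  tab <- data.frame(row.names = seq_len(n))
  for (i in seq_len(nrow(mom$normal))) {
    m <- mom$normal[i, ]
    tab[[m$feature]] <- rtruncnorm(n, m$mean, m$sd, m$lower, m$upper)
  }
  for (i in seq_len(nrow(mom$lognormal))) {
    m <- mom$lognormal[i, ]
    meanlog <- log(m$median)
    sdlog <- log(m$q3 / m$q1) / (2 * qnorm(0.75))
    tab[[m$feature]] <- exp(rnorm(n, meanlog, sdlog))
  }
  tab$Rhythm <- sample(names(mom$rhythm_probs), n, replace = TRUE,
                       prob = mom$rhythm_probs)
  tab[, c(ivc_feature_columns())]
}

#' Simulate a patient cohort with known generating model
#'
#' Features are drawn independently from truncated normal distributions at
#' the population means/SDs (log-normal for the skewed biomarkers, a
#' multinomial rhythm mixture), RAP is produced by the generating linear
#' model plus Gaussian noise, and patients whose RAP falls outside the
#' admissible range are redrawn.  Missing values are then punched in at
#' the configured per-column rates.  Everything is reproducible from the
#' seed.
#'
#' @param cfg A [cohort_sim_config()]; individual fields can instead be
#'   passed directly (\code{n}, \code{seed}, \code{noise_sd}, ...).
#' @param ... Overrides forwarded to [cohort_sim_config()] when \code{cfg}
#'   is not supplied.
#' @return List with \code{table} (the feature table, including the
#'   \code{RAP} column in mmHg), \code{generating_spec} and \code{config}.
#' @export
simulate_cohort <- function(cfg = NULL, ...) {
  if (is.null(cfg)) cfg <- cohort_sim_config(...)
  stopifnot(inherits(cfg, "cohort_sim_config"))
  with_seed(cfg$seed, {
    tab <- draw_cohort_features(cfg$n)
    rap <- lm_predict(tab, cfg$generating_spec) +
      rnorm(cfg$n, 0, cfg$noise_sd)
    for (iter in 1:100) {
      bad <- which(rap < cfg$rap_range[1] | rap > cfg$rap_range[2])
      if (length(bad) == 0L) break
      redraw <- draw_cohort_features(length(bad))
      tab[bad, ] <- redraw
      rap[bad] <- lm_predict(redraw, cfg$generating_spec) +
        rnorm(length(bad), 0, cfg$noise_sd)
    }
    if (length(bad <- which(rap < cfg$rap_range[1] | rap > cfg$rap_range[2])) > 0) {
      stop("could not draw a cohort inside the admissible RAP range")
    }
    tab$RAP <- rap
    if (!is.null(cfg$missing_rates)) {
      for (nm in names(cfg$missing_rates)) {
        if (!nm %in% names(tab)) next
        miss <- runif(cfg$n) < cfg$missing_rates[[nm]]
        tab[[nm]][miss] <- NA
      }
    }
    list(table = tab, generating_spec = cfg$generating_spec, config = cfg)
  })
}
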