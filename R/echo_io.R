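#' Calibrated ultrasound image sequence
#'
#' Container for a B-mode cine loop: a stack of grayscale frames with the
#' physical calibration needed to convert pixels to millimetres and frame
#' indices to seconds.
#'
#' @param frames A numeric 3D array (rows x cols x frames) with intensities
#'   in \code{[0, 1]}, or a list of equally sized matrices.
#' @param pixel_spacing Millimetres per pixel, length 1 (isotropic) or 2
#'   (row, col).
#' @param frame_rate Frames per second.
#' @param id Free-text identifier.
#'
#' @return An object of class \code{ultrasound_sequence} with fields
#'   \code{frames}, \code{pixel_spacing}, \code{frame_rate}, \code{id}.
#' @export
ultrasound_sequence <- function(frames, pixel_spacing, frame_rate,
                                id = "sequence") {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) {
      stop("all frames must have identical dimensions")
    }
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1]], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("frames must be a rows x cols x frames array or a list of matrices")
  }
  if (dim(frames)[3] < 1L) stop("sequence needs at least one frame")
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  if (length(pixel_spacing) != 2L || any(!is.finite(pixel_spacing)) ||
      any(pixel_spacing <= 0)) {
    stop("pixel_spacing must be positive mm/px (row, col)")
  }
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L ||
      !is.finite(frame_rate) || frame_rate <= 0) {
    stop("frame_rate must be a positive scalar (frames per second)")
  }
  structure(
    list(frames = frames, pixel_spacing = pixel_spacing,
         frame_rate = frame_rate, id = as.character(id)),
    class = "ultrasound_sequence"
  )
}

#' @export
print.ultrasound_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<ultrasound_sequence '%s': %d frames %dx%d px, %.3g mm/px, %.4g fps, %.2f s>\n",
    x$id, d[3], d[1], d[2], x$pixel_spacing[1], x$frame_rate,
    sequence_duration(x)))
  invisible(x)
}

#' Duration of a sequence in seconds
#'
#' @param seq An \code{ultrasound_sequence}.
#' @return \code{n_frames / frame_rate} in seconds.
#' @export
sequence_duration <- function(seq) {
  dim(seq$frames)[3] / seq$frame_rate
}

n_frames <- function(seq) dim(seq$frames)[3]

get_frame <- function(seq, i) seq$frames[, , i]

# ITU-R 601 luminance; accepts rows x cols x channels arrays (3 or 4
# channels, alpha ignored).
to_grayscale <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L && dim(img)[3] >= 3L) {
    return(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
  }
  if (length(dim(img)) == 3L && dim(img)[3] == 1L) return(img[, , 1])
  stop("unsupported image layout: expected grayscale or RGB(A)")
}

read_image_file <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.png$", lower)) {
    img <- png::readPNG(path)
  } else if (grepl("\\.tiff?$", lower)) {
    img <- tiff::readTIFF(path)
  } else {
    stop("unreadable image file (expected .png or .tif/.tiff): ", path)
  }
  to_grayscale(img)
}

sidecar_path <- function(path) {
  if (dir.exists(path)) {
    file.path(path, "calibration.json")
  } else {
    paste0(sub("\\.[A-Za-z]+$", "", path), ".json")
  }
}

read_calibration <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) return(list())
  jsonlite::fromJSON(sc, simplifyVector = TRUE)
}

#' Load an ultrasound sequence from an image stack
#'
#' Reads either a multi-page TIFF file or a directory of PNG/TIFF frames
#' (sorted by file name).  Calibration (pixel spacing in mm and frame rate)
#' is taken from a JSON sidecar (\code{calibration.json} in a stack
#' directory, or \code{<stem>.json} next to a TIFF file) and can be
#' overridden by the arguments.  Color frames are converted to grayscale by
#' ITU-R 601 luminance.  Clips shorter than one second are rejected (too
#' short for beat-wise pulsatility analysis) unless \code{force = TRUE}.
#'
#' @param path Multi-page TIFF file or directory of image frames.
#' @param pixel_spacing,frame_rate Optional calibration overrides.
#' @param id Identifier; defaults to the file/directory name.
#' @param force Accept clips shorter than 1 s.
#' @return An [ultrasound_sequence()].
#' @export
load_sequence <- function(path, pixel_spacing = NULL, frame_rate = NULL,
                          id = NULL, force = FALSE) {
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tiff?)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) stop("no image frames found in directory: ", path)
    frames <- lapply(files, read_image_file)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    frames <- lapply(pages, to_grayscale)
  }
  cal <- read_calibration(path)
  ps <- if (!is.null(pixel_spacing)) pixel_spacing else cal$pixel_spacing_mm
  fr <- if (!is.null(frame_rate)) frame_rate else cal$frame_rate
  if (is.null(ps)) {
    stop("missing calibration field 'pixel_spacing_mm': provide a JSON ",
         "sidecar or the pixel_spacing override")
  }
  if (is.null(fr)) {
    stop("missing calibration field 'frame_rate': provide a JSON sidecar ",
         "or the frame_rate override")
  }
  if (is.null(id)) id <- basename(path)
  seq <- ultrasound_sequence(frames, ps, fr, id = id)
  if (!force && sequence_duration(seq) < 1) {
    stop(sprintf(
      "sequence duration %.2f s is below the 1 s minimum for analysis; ",
      sequence_duration(seq)), "use force = TRUE to override")
  }
  seq
}

#' Save a sequence as a multi-page TIFF with a JSON calibration sidecar
#'
#' Frames are stored as 16-bit grayscale; intensities must lie in
#' \code{[0, 1]}.  The sidecar records pixel spacing, frame rate and id so
#' that [load_sequence()] can restore the object.
#'
#' @param seq An [ultrasound_sequence()].
#' @param path Output TIFF path.
#' @return \code{path}, invisibly.
#' @export
save_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "ultrasound_sequence"))
  frames <- lapply(seq_len(n_frames(seq)), function(i) get_frame(seq, i))
  rng <- range(unlist(lapply(frames, range)))
  if (rng[1] < 0 || rng[2] > 1) stop("frame intensities must be in [0, 1]")
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(pixel_spacing_mm = seq$pixel_spacing, frame_rate = seq$frame_rate,
         id = seq$id),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Canonical feature-table column names
#'
#' Column names for patient feature tables, using the standard
#' echocardiographic/biomarker abbreviations (heart rate, rhythm, left- and
#' right-heart indices, IVC measures, biomarkers).  \code{RAP} holds the
#' invasively measured right atrial pressure in mmHg when available.
#'
#' @return Character vector of column names.
#' @export
ivc_feature_columns <- function() {
  c("HR", "Rhythm", "LVEF", "CI", "LVMi", "EoverEprime", "PAWP", "LAVi",
    "PVR", "TRV", "RAd", "RVd", "TAPSE", "RV_FAC", "TRd", "CCI", "IVCd",
    "NT_proBNP", "TnT_hs", "eGFR")
}

rhythm_levels <- function() c("sinus", "afib", "pacing")

numeric_feature_columns <- function() {
  setdiff(ivc_feature_columns(), "Rhythm")
}

#' Write a patient feature table to CSV
#'
#' Missing values are written as empty cells.  Numeric values survive a
#' round trip through [load_table()] to at least 12 significant digits.
#'
#' @param records Data frame with (a subset of) the canonical columns of
#'   [ivc_feature_columns()] plus optional \code{RAP}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
save_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) {
      out[[nm]] <- ifelse(is.na(out[[nm]]), NA_character_,
                          formatC(out[[nm]], digits = 15, format = "g"))
    }
  }
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a patient feature table from CSV
#'
#' Empty cells become \code{NA}.  Columns outside the canonical schema are
#' kept with a warning; a non-numeric entry in a numeric column is an error
#' reporting the offending row.
#'
#' @param path CSV path written by [save_table()] or following the same
#'   schema.
#' @return Data frame of patient records.
#' @export
load_table <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                  colClasses = "character", check.names = FALSE)
  known <- c(ivc_feature_columns(), "RAP", "id")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    warning("unknown column(s) kept as-is: ", paste(unknown, collapse = ", "))
  }
  num_cols <- setdiff(names(raw), c("Rhythm", "id"))
  for (nm in num_cols) {
    vals <- suppressWarnings(as.numeric(raw[[nm]]))
    bad <- which(!is.na(raw[[nm]]) & is.na(vals))
    if (length(bad) > 0L) {
      stop(sprintf("malformed numeric value in column '%s', row %d: '%s'",
                   nm, bad[1], raw[[nm]][bad[1]]))
    }
    raw[[nm]] <- vals
  }
  if ("Rhythm" %in% names(raw)) {
    bad <- which(!is.na(raw$Rhythm) & !(raw$Rhythm %in% rhythm_levels()))
    if (length(bad) > 0L) {
      stop(sprintf("invalid Rhythm value in row %d: '%s'", bad[1],
                   raw$Rhythm[bad[1]]))
    }
  }
  raw
}

#' Fraction of non-missing values per column
#'
#' @param table Patient feature table.
#' @return Named numeric vector of presence fractions in \code{[0, 1]}.
#' @export
presence_fraction <- function(table) {
  vapply(table, function(col) mean(!is.na(col)), numeric(1))
}

#' Screen features by presence
#'
#' Retrospective tables carry variables that were not recorded for every
#' patient; only columns observed in more than the given fraction of
#' subjects are retained for modelling.
#'
#' @param table Patient feature table.
#' @param columns Candidate columns (default: all canonical feature columns
#'   present in the table).
#' @param threshold Minimum presence fraction (default 0.95).
#' @return List with \code{kept} and \code{dropped} column names and the
#'   \code{presence} vector.
#' @export
screen_features <- function(table, columns = NULL, threshold = 0.95) {
  if (is.null(columns)) {
    columns <- intersect(ivc_feature_columns(), names(table))
  }
  pres <- presence_fraction(table[columns])
  list(kept = columns[pres > threshold],
       dropped = columns[pres <= threshold],
       presence = pres)
}
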