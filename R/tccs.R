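#' Spectrogram axis calibration
#'
#' Pixel-to-physical mapping for a spectral-Doppler image: seconds per
#' pixel column, cm/s per pixel row, the column of t = 0 and the row of
#' the zero-velocity baseline. Calibration is supplied by the user (read
#' off the device's axis annotations); it is not auto-detected.
#'
#' @param time_per_px seconds per image column (> 0).
#' @param vel_per_px cm/s per image row (> 0).
#' @param origin_px column index of t = 0 (default 1).
#' @param baseline_row row index (1 = top) of the zero-velocity baseline.
#' @export
spectrogram_calibration <- function(time_per_px, vel_per_px, origin_px = 1,
                                    baseline_row) {
  if (!is.finite(time_per_px) || time_per_px <= 0)
    stop("time_per_px must be positive")
  if (!is.finite(vel_per_px) || vel_per_px <= 0)
    stop("vel_per_px must be positive")
  structure(list(time_per_px = time_per_px, vel_per_px = vel_per_px,
                 origin_px = as.integer(origin_px),
                 baseline_row = as.integer(baseline_row)),
            class = "spectrogram_calibration")
}

#' Load a spectral-Doppler image
#'
#' Reads a BMP or PNG spectrogram into a grayscale intensity matrix
#' (0..1, row 1 = top of image) together with its axis calibration.
#' Colour images are converted by Rec. 601 luminance.
#'
#' @param path image file (`.bmp` or `.png`).
#' @param calibration a [spectrogram_calibration()] (required).
#' @return object of class `spectrogram`: list with `pixels` (matrix) and
#'   `calibration`.
#' @export
load_spectrogram <- function(path, calibration) {
  if (missing(calibration) || is.null(calibration))
    stop("calibration is required")
  stopifnot(inherits(calibration, "spectrogram_calibration"))
  if (!file.exists(path)) stop("unreadable image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                bmp = read_bmp(path),
                stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3L)
    img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  if (calibration$baseline_row < 1 || calibration$baseline_row > nrow(img))
    stop("baseline row outside image")
  structure(list(pixels = img, calibration = calibration),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat("spectrogram:", nrow(x$pixels), "x", ncol(x$pixels), "px,",
      format(x$calibration$time_per_px), "s/px,",
      format(x$calibration$vel_per_px), "cm/s per px\n")
  invisible(x)
}

# ---- minimal uncompressed 24-bit BMP I/O --------------------------------

read_bmp <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readChar(con, 2, useBytes = TRUE)
  if (!identical(sig, "BM")) stop("not a BMP file")
  invisible(readBin(con, "integer", 2, size = 4, endian = "little"))
  offset <- readBin(con, "integer", 1, size = 4, endian = "little")
  hdrsz <- readBin(con, "integer", 1, size = 4, endian = "little")
  width <- readBin(con, "integer", 1, size = 4, endian = "little")
  height <- readBin(con, "integer", 1, size = 4, endian = "little")
  invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
  bpp <- readBin(con, "integer", 1, size = 2, endian = "little")
  compression <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (bpp != 24L || compression != 0L)
    stop("only uncompressed 24-bit BMP supported")
  seek(con, offset)
  rowbytes <- 4L * ceiling(3L * width / 4L)
  raw <- readBin(con, "raw", rowbytes * abs(height))
  img <- matrix(0, abs(height), width)
  topdown <- height < 0
  height <- abs(height)
  for (r in seq_len(height)) {
    row <- as.integer(raw[((r - 1) * rowbytes + 1):((r - 1) * rowbytes + 3 * width)])
    bgr <- matrix(row, 3, width)
    lum <- (0.299 * bgr[3, ] + 0.587 * bgr[2, ] + 0.114 * bgr[1, ]) / 255
    dest <- if (topdown) r else height - r + 1  # BMP rows usually bottom-up
    img[dest, ] <- lum
  }
  img
}

write_bmp <- function(img, path) {
  img <- pmin(pmax(img, 0), 1)
  h <- nrow(img); w <- ncol(img)
  rowbytes <- 4L * ceiling(3L * w / 4L)
  datasize <- rowbytes * h
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("BM", con, eos = NULL, useBytes = TRUE)
  writeBin(as.integer(54 + datasize), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")
  writeBin(54L, con, size = 4, endian = "little")
  writeBin(40L, con, size = 4, endian = "little")
  writeBin(as.integer(w), con, size = 4, endian = "little")
  writeBin(as.integer(h), con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(24L, con, size = 2, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")
  writeBin(as.integer(datasize), con, size = 4, endian = "little")
  writeBin(c(2835L, 2835L, 0L, 0L), con, size = 4, endian = "little")
  pad <- rowbytes - 3L * w
  g8 <- round(img * 255)
  for (r in h:1) {  # bottom-up
    bgr <- as.raw(rep(g8[r, ], each = 3L))
    writeBin(c(bgr, as.raw(rep(0L, pad))), con)
  }
  invisible(path)
}

#' Extract the maximal-velocity envelope from a spectrogram
#'
#' For each image column, the envelope velocity is the calibrated distance
#' from the baseline to the highest (topmost) pixel above the baseline
#' whose intensity reaches `intensity_threshold` times the image maximum.
#' Only antegrade flow (above baseline) is digitized. The envelope is
#' median-smoothed over `smooth_window` columns; columns with no
#' super-threshold signal are linearly interpolated from their neighbours.
#'
#' @param img a [load_spectrogram()] result.
#' @param intensity_threshold fraction of maximum intensity (default 0.2).
#' @param smooth_window odd number of columns for the running median
#'   (default 5; 1 disables smoothing).
#' @param min_run isolated-speckle rejection: the envelope pixel must head
#'   a vertical run of at least this many consecutive super-threshold
#'   pixels (default 3; 1 accepts single pixels).
#' @return an (uncropped) [waveform()].
#' @export
extract_envelope <- function(img, intensity_threshold = 0.2,
                             smooth_window = 5, min_run = 3) {
  stopifnot(inherits(img, "spectrogram"))
  cal <- img$calibration
  px <- img$pixels
  thr <- intensity_threshold * max(px)
  if (max(px) <= 0) stop("blank image: no signal")
  nc <- ncol(px)
  base <- cal$baseline_row
  env_px <- rep(NA_real_, nc)
  for (j in seq_len(nc)) {
    col <- px[seq_len(base - 1L), j] >= thr
    if (min_run > 1L && any(col)) {
      # keep only pixels heading a downward run of >= min_run hits
      r <- rle(col)
      r$values <- r$values & r$lengths >= min_run
      col <- inverse.rle(r)
    }
    hit <- which(col)
    if (length(hit)) env_px[j] <- base - hit[1]  # topmost = highest velocity
  }
  if (!any(is.finite(env_px))) stop("blank image: no signal above threshold")
  if (any(!is.finite(env_px))) {
    ok <- which(is.finite(env_px))
    env_px <- stats::approx(ok, env_px[ok], xout = seq_len(nc), rule = 2)$y
  }
  if (smooth_window > 1) {
    k <- smooth_window + (smooth_window %% 2 == 0)  # force odd
    env_px <- stats::runmed(env_px, k, endrule = "median")
  }
  v <- env_px * cal$vel_per_px
  t <- (seq_len(nc) - cal$origin_px) * cal$time_per_px
  waveform(t, v, cropped = FALSE)
}

#' Velocity waveform
#'
#' @param times seconds, strictly increasing.
#' @param velocities cm/s.
#' @param cropped whether the waveform spans exactly one cardiac cycle.
#' @param period cycle duration T (s), set when cropped.
#' @return object of class `waveform`.
#' @export
waveform <- function(times, velocities, cropped = FALSE, period = NA_real_) {
  times <- as.numeric(times); velocities <- as.numeric(velocities)
  if (length(times) != length(velocities)) stop("times/velocities mismatch")
  if (length(times) == 0L) stop("empty waveform")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(velocities))) stop("velocities must be finite")
  structure(list(times = times, velocities = velocities,
                 cropped = isTRUE(cropped), period = period),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("waveform: %d samples over %.3f s%s\n", length(x$times),
              diff(range(x$times)),
              if (x$cropped) sprintf(" (one cycle, T = %.3f s)", x$period) else ""))
  invisible(x)
}

#' Crop a waveform to a single cardiac cycle
#'
#' With `method = "autocorrelation"` the cycle length is found as the lag
#' maximizing the normalized autocorrelation of the demeaned velocity
#' trace (the trace must span at least two cycles); the cycle is then
#' started at end-diastole (the velocity minimum within the first period).
#' With `method = "markers"`, the supplied `[t0, t1)` window is cropped
#' as-is.
#'
#' @param w a [waveform()].
#' @param method `"autocorrelation"` or `"markers"`.
#' @param markers numeric `c(t0, t1)` for the marker method.
#' @param min_corr minimum autocorrelation peak treated as periodic.
#' @return a cycle-cropped [waveform()] with `period` set.
#' @export
single_cycle <- function(w, method = c("autocorrelation", "markers"),
                         markers = NULL, min_corr = 0.5) {
  stopifnot(inherits(w, "waveform"))
  method <- match.arg(method)
  t <- w$times; v <- w$velocities
  if (method == "markers") {
    if (is.null(markers) || length(markers) != 2L) stop("markers = c(t0, t1) required")
    keep <- t >= markers[1] & t < markers[2]
    if (sum(keep) < 2L) stop("marker window contains too few samples")
    return(waveform(t[keep] - markers[1], v[keep], cropped = TRUE,
                    period = diff(markers)))
  }
  n <- length(v)
  if (n < 8L) stop("waveform too short for periodicity detection")
  x <- v - mean(v)
  if (sum(x^2) == 0) stop("no detectable periodicity (constant waveform)")
  lags <- seq(2L, floor(n / 2))
  r <- vapply(lags, function(L) {
    a <- x[1:(n - L)]; b <- x[(L + 1):n]
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }, numeric(1))
  # the cycle peak is the autocorrelation maximum beyond the first
  # negative dip; signals that never dip are aperiodic over the window
  dip <- which(r < 0)[1]
  if (is.na(dip)) stop("no detectable periodicity")
  search <- dip:length(lags)
  best <- lags[search[which.max(r[search])]]
  if (max(r[search]) < min_corr) stop("no detectable periodicity")
  dt <- mean(diff(t))
  period_n <- best
  i0 <- which.min(v[seq_len(period_n)])
  if (i0 + period_n - 1L > n) i0 <- n - period_n + 1L
  keep <- i0:(i0 + period_n - 1L)
  waveform(t[keep] - t[i0], v[keep], cropped = TRUE, period = period_n * dt)
}

#' Clinical velocity indices of a cycle-cropped waveform
#'
#' Vps (peak systolic) is the maximum, Ved (end-diastolic) the velocity at
#' the cycle end point (configurable to the global minimum), and Vm the
#' trapezoidal time-average over the cycle.
#'
#' @param w a cycle-cropped [waveform()].
#' @param ved `"end"` (velocity at cycle end, the default) or `"min"`.
#' @return list with `Vps`, `Ved`, `Vm` (cm/s) and `T` (s).
#' @export
waveform_indices <- function(w, ved = c("end", "min")) {
  stopifnot(inherits(w, "waveform"))
  ved <- match.arg(ved)
  if (!w$cropped) stop("waveform must be cycle-cropped first")
  wt <- trapezoid_weights(w$times)
  vm <- sum(w$velocities * wt) / diff(range(w$times))
  list(Vps = max(w$velocities),
       Ved = if (ved == "end") w$velocities[length(w$velocities)]
             else min(w$velocities),
       Vm = vm, T = w$period)
}

#' Export a waveform as a solver-ready inlet profile
#'
#' Two-column ASCII file (time in s, velocity in m/s — converted from
#' cm/s), `#`-prefixed header, fixed 9-decimal format. The companion
#' [import_inlet_profile()] reads the file back.
#'
#' @param w a cycle-cropped [waveform()].
#' @param path output file.
#' @export
export_inlet_profile <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  if (!w$cropped) stop("waveform must be cycle-cropped first")
  if (length(w$times) == 0L) stop("empty waveform")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# inlet velocity profile",
               sprintf("# period_s %.9f", w$period),
               "# columns: time_s velocity_m_per_s"), con)
  writeLines(sprintf("%.9f %.9f", w$times, w$velocities / 100), con)
  invisible(path)
}

#' Read back an exported inlet profile
#'
#' @param path file written by [export_inlet_profile()].
#' @return a cycle-cropped [waveform()] (velocities in cm/s).
#' @export
import_inlet_profile <- function(path) {
  lines <- readLines(path)
  per <- as.numeric(sub("^# period_s ", "", grep("^# period_s", lines, value = TRUE)[1]))
  dat <- lines[!grepl("^#", lines)]
  m <- do.call(rbind, lapply(strsplit(trimws(dat), "\\s+"), as.numeric))
  waveform(m[, 1], m[, 2] * 100, cropped = TRUE, period = per)
}

#' Parametric cardiac-cycle velocity waveform
#'
#' Idealised MCA Doppler waveform: a half-rectified sinusoidal systolic
#' upstroke on an end-diastolic pedestal, starting at end-diastole.
#' Defaults mirror typical middle-cerebral-artery velocities (peak
#' systolic around 97 cm/s, end-diastolic around 44 cm/s).
#'
#' @param vps peak systolic velocity (cm/s).
#' @param ved end-diastolic velocity (cm/s).
#' @param period cardiac period (s).
#' @param n_cycles number of cycles to generate.
#' @param dt sample spacing (s).
#' @return a [waveform()]; cycle-cropped when `n_cycles == 1`.
#' @export
make_doppler_waveform <- function(vps = 97.4, ved = 44.0, period = 0.9,
                                  n_cycles = 1, dt = 0.0025) {
  if (vps <= ved) stop("need vps > ved")
  if (period <= 0 || dt <= 0 || n_cycles < 1) stop("invalid timing parameters")
  t <- seq(0, n_cycles * period, by = dt)
  v <- ved + (vps - ved) * pmax(0, sin(2 * pi * t / period))
  waveform(t, v, cropped = (n_cycles == 1), period = period)
}

#' Render a synthetic spectral-Doppler image of a known waveform
#'
#' Draws the Doppler spectral band (baseline up to the waveform velocity)
#' on a pixel grid, optionally corrupted by seeded speckle noise (bright
#' specks in the background and dropouts inside the band). This is the
#' fixture generator for envelope-extraction round trips.
#'
#' @param w a [waveform()] (velocities in cm/s).
#' @param size `c(rows, cols)` of the image.
#' @param calibration optional [spectrogram_calibration()]; derived from
#'   the waveform and image size when `NULL` (velocity axis headroom 25%).
#' @param noise_level fraction in `[0, 1]` controlling speckle density.
#' @param seed integer seed for the speckle (ignored when
#'   `noise_level = 0`).
#' @param path optional output image path (`.png` or `.bmp`).
#' @return the rendered `spectrogram` object (invisibly written to `path`
#'   when given).
#' @export
render_spectrogram <- function(w, size = c(160L, 400L), calibration = NULL,
                               noise_level = 0, seed = 1L, path = NULL) {
  stopifnot(inherits(w, "waveform"))
  rows <- size[1]; cols <- size[2]
  if (is.null(calibration)) {
    baseline <- rows - 4L
    vmax <- max(w$velocities)
    calibration <- spectrogram_calibration(
      time_per_px = diff(range(w$times)) / (cols - 1),
      vel_per_px = 1.25 * vmax / (baseline - 1L),
      origin_px = 1L, baseline_row = baseline)
  }
  cal <- calibration
  tcol <- (seq_len(cols) - cal$origin_px) * cal$time_per_px
  vcol <- stats::approx(w$times, w$velocities, xout = tcol, rule = 2)$y
  if (any(vcol > (cal$baseline_row - 1L) * cal$vel_per_px + 1e-9))
    stop("waveform exceeds velocity axis range")
  px <- matrix(0.03, rows, cols)
  env_px <- round(vcol / cal$vel_per_px)
  for (j in seq_len(cols)) {
    if (env_px[j] >= 1) {
      rr <- (cal$baseline_row - env_px[j]):(cal$baseline_row - 1L)
      px[rr, j] <- 0.85
    }
  }
  if (noise_level > 0) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    sig <- px > 0.5
    speck <- matrix(stats::runif(rows * cols) < 0.5 * noise_level, rows, cols)
    px[speck & !sig] <- stats::runif(sum(speck & !sig), 0.3, 1)
    drop <- matrix(stats::runif(rows * cols) < 0.5 * noise_level, rows, cols)
    px[drop & sig] <- stats::runif(sum(drop & sig), 0, 0.1)
  }
  sp <- structure(list(pixels = px, calibration = cal), class = "spectrogram")
  if (!is.null(path)) {
    ext <- tolower(tools::file_ext(path))
    switch(ext,
           png = png::writePNG(px, path),
           bmp = write_bmp(px, path),
           stop("unsupported image format: ", ext))
  }
  sp
}
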