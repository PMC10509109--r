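#' Signal and noise in a circular ROI
#'
#' Measures mean attenuation (signal), its sample standard deviation
#' (noise) and their ratio (SNR) over a circular single-slice region of
#' interest; by convention a 20 mm diameter ROI placed in the aortic root.
#'
#' @param volume An [image_volume()].
#' @param center Numeric length-3 `(slice, row, col)` ROI center (pixels;
#'   row/col may be fractional).
#' @param diameter ROI diameter in mm (default 20).
#' @return List with `signal` (HU), `noise` (HU), `snr` (NA with a warning
#'   when noise is zero) and `n_pixels`.
#' @export
roi_stats <- function(volume, center, diameter = 20) {
  stopifnot(inherits(volume, "image_volume"), length(center) == 3L)
  d <- dim(volume$voxels)
  s <- as.integer(round(center[1]))
  if (s < 1 || s > d[3]) stop("ROI slice outside the volume", call. = FALSE)
  r_px <- diameter / 2 / volume$pixel_spacing
  if (center[2] - r_px < 0.5 || center[2] + r_px > d[1] + 0.5 ||
      center[3] - r_px < 0.5 || center[3] + r_px > d[2] + 0.5)
    stop("ROI extends outside the image grid", call. = FALSE)
  px <- .rasterize_disc(center[2:3], r_px, d[1], d[2])
  vals <- volume$voxels[cbind(px, s)]
  signal <- mean(vals)
  noise <- stats::sd(vals)
  snr <- if (noise > 0) signal / noise else {
    warning("zero noise in ROI: SNR undefined", call. = FALSE)
    NA_real_
  }
  list(signal = signal, noise = noise, snr = snr, n_pixels = nrow(px))
}

#' Effective dose from the dose-length product
#'
#' Effective dose (mSv) = DLP (mGy cm) x a tube-voltage-dependent
#' conversion factor: 0.0145 mSv/(mGy cm) at 120 kVp and 0.0147 at 80 and
#' 70 kVp.
#'
#' @param dlp Dose-length product in mGy cm (>= 0).
#' @param kvp Tube voltage (70, 80 or 120).
#' @return Effective dose in mSv.
#' @examples
#' effective_dose(100, 120)  # 1.45
#' @export
effective_dose <- function(dlp, kvp) {
  kvp <- .check_kvp(kvp)
  if (any(dlp < 0)) stop("`dlp` must be >= 0", call. = FALSE)
  dlp * c(`120` = 0.0145, `80` = 0.0147, `70` = 0.0147)[[as.character(kvp)]]
}

#' Parametric dose-length product model
#'
#' A simple simulator attachment: DLP = c(kVp) x tube current x scan
#' length, with per-voltage output constants reflecting the roughly
#' quadratic-to-cubic dependence of tube output on voltage. The constants
#' are configuration values of the simulator, not measured physics, and
#' dose outputs are reported for context only.
#'
#' @param kvp Tube voltage (70, 80 or 120).
#' @param tube_current Tube current in mA.
#' @param scan_length_cm z-coverage in cm (default 14, the middle of the
#'   12--16 cm protocol range).
#' @return DLP in mGy cm.
#' @export
dlp_model <- function(kvp, tube_current, scan_length_cm = 14) {
  kvp <- .check_kvp(kvp)
  const <- c(`120` = 0.0133, `80` = 0.004435, `70` = 0.002743)[[as.character(kvp)]]
  const * tube_current * scan_length_cm
}
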