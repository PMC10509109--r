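#' Specify a calcific lesion for a digital phantom
#'
#' Lesions are uniform discs: every pixel of the rasterized disc carries the
#' lesion's peak attenuation, which makes ground-truth density scores exact.
#' The disc radius is derived from the requested area
#' (`radius = sqrt(area / pi)`); the rasterized area (pixels whose centers
#' fall inside the disc, times pixel area) generally differs from
#' `target_area` by quantization and is what the ground truth uses.
#'
#' @param slice 1-based slice index the lesion lives on.
#' @param center Numeric length-2 `(row, col)` center in pixel coordinates
#'   (may be fractional).
#' @param target_area Requested disc area in mm^2 (> 0).
#' @param peak_hu Peak attenuation in HU at the 120 kVp reference (>= 0).
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(slice, center, target_area, peak_hu) {
  stopifnot(length(slice) == 1L, slice >= 1, length(center) == 2L,
            is.numeric(center))
  if (!is.numeric(target_area) || target_area <= 0)
    stop("`target_area` must be > 0 (mm^2)", call. = FALSE)
  if (peak_hu < 0) stop("`peak_hu` must be >= 0", call. = FALSE)
  structure(list(slice = as.integer(slice), center = as.numeric(center),
                 target_area = target_area, peak_hu = peak_hu, shape = "disc"),
            class = "lesion_spec")
}

#' Digital patient phantom
#'
#' Ground truth for one synthetic subject: a set of disc lesions, a BMI
#' (which drives the noise model), and an aortic-root blood pool used for
#' signal/noise measurement. Defaults follow a non-contrast cardiac CT
#' reconstruction: 25 cm displayed field of view on a 512 matrix
#' (0.488 mm pixels) and 2.5 mm slices.
#'
#' @param lesions List of [lesion_spec()] objects (possibly empty).
#' @param bmi Body-mass index in kg/m^2, in [15, 60].
#' @param grid Integer length-3 `(n_slices, n_rows, n_cols)`.
#' @param pixel_spacing In-plane pixel size in mm (default 250/512).
#' @param slice_thickness Slice thickness in mm.
#' @param aortic_center `(slice, row, col)` center of the aortic blood pool;
#'   default: center of slice 1.
#' @param blood_pool_hu Blood-pool attenuation at 120 kVp (HU).
#' @param blood_pool_diameter Diameter of the blood-pool cylinder in mm;
#'   must comfortably contain the 20 mm measurement ROI.
#' @return An object of class `patient_phantom`.
#' @export
patient_phantom <- function(lesions = list(), bmi = 26,
                            grid = c(3L, 512L, 512L),
                            pixel_spacing = 250 / 512,
                            slice_thickness = 2.5,
                            aortic_center = NULL,
                            blood_pool_hu = 48.5,
                            blood_pool_diameter = 25) {
  stopifnot(length(grid) == 3L, all(grid >= 1))
  grid <- as.integer(grid)
  if (bmi < 15 || bmi > 60) stop("`bmi` must lie in [15, 60] kg/m^2", call. = FALSE)
  if (pixel_spacing <= 0) stop("`pixel_spacing` must be > 0", call. = FALSE)
  if (is.null(aortic_center))
    aortic_center <- c(1, (grid[2] + 1) / 2, (grid[3] + 1) / 2)
  ph <- structure(list(lesions = lesions, bmi = bmi, grid = grid,
                       pixel_spacing = pixel_spacing,
                       slice_thickness = slice_thickness,
                       aortic_center = as.numeric(aortic_center),
                       blood_pool_hu = blood_pool_hu,
                       blood_pool_diameter = blood_pool_diameter),
                  class = "patient_phantom")
  .validate_phantom(ph)
  ph
}

#' @export
print.patient_phantom <- function(x, ...) {
  cat(sprintf("patient_phantom: %d lesion(s), BMI %.1f, grid %d x %d x %d\n",
              length(x$lesions), x$bmi, x$grid[2], x$grid[3], x$grid[1]))
  invisible(x)
}

# pixel (row, col) coordinates of a disc: pixels whose centers lie within
# `radius_px` of `center` (row, col; possibly fractional)
.rasterize_disc <- function(center, radius_px, nrow, ncol) {
  r0 <- max(1L, floor(center[1] - radius_px))
  r1 <- min(nrow, ceiling(center[1] + radius_px))
  c0 <- max(1L, floor(center[2] - radius_px))
  c1 <- min(ncol, ceiling(center[2] + radius_px))
  if (r0 > r1 || c0 > c1) return(cbind(row = integer(0), col = integer(0)))
  rr <- r0:r1; cc <- c0:c1
  dr2 <- (rr - center[1])^2
  dc2 <- (cc - center[2])^2
  inside <- outer(dr2, dc2, `+`) <= radius_px^2
  idx <- which(inside, arr.ind = TRUE)
  cbind(row = rr[idx[, 1]], col = cc[idx[, 2]])
}

.lesion_radius_px <- function(lesion, pixel_spacing)
  sqrt(lesion$target_area / pi) / pixel_spacing

.validate_phantom <- function(ph) {
  nr <- ph$grid[2]; nc <- ph$grid[3]; ns <- ph$grid[1]
  roi_r_px <- 10 / ph$pixel_spacing  # 20 mm measurement ROI radius
  ac <- ph$aortic_center
  if (ac[1] < 1 || ac[1] > ns ||
      ac[2] - roi_r_px < 0.5 || ac[2] + roi_r_px > nr + 0.5 ||
      ac[3] - roi_r_px < 0.5 || ac[3] + roi_r_px > nc + 0.5)
    stop("aortic ROI (20 mm diameter) does not fit inside the grid", call. = FALSE)
  pool_r_px <- ph$blood_pool_diameter / 2 / ph$pixel_spacing
  for (i in seq_along(ph$lesions)) {
    le <- ph$lesions[[i]]
    if (!inherits(le, "lesion_spec")) stop("lesion ", i, " is not a lesion_spec")
    r_px <- .lesion_radius_px(le, ph$pixel_spacing)
    if (le$slice < 1 || le$slice > ns ||
        le$center[1] - r_px < 0.5 || le$center[1] + r_px > nr + 0.5 ||
        le$center[2] - r_px < 0.5 || le$center[2] + r_px > nc + 0.5)
      stop(sprintf("lesion %d extends outside the image grid", i), call. = FALSE)
    # lesions must not intrude into the blood-pool cylinder (any slice)
    d_pool <- sqrt((le$center[1] - ac[2])^2 + (le$center[2] - ac[3])^2)
    if (d_pool < pool_r_px + r_px + 1)
      stop(sprintf("lesion %d overlaps the aortic blood pool", i), call. = FALSE)
  }
  # pairwise overlap on the same slice is rejected: ground truth stays unambiguous
  if (length(ph$lesions) > 1) {
    for (i in seq_len(length(ph$lesions) - 1)) {
      for (j in (i + 1):length(ph$lesions)) {
        a <- ph$lesions[[i]]; b <- ph$lesions[[j]]
        if (a$slice != b$slice) next
        d <- sqrt(sum((a$center - b$center)^2))
        ra <- .lesion_radius_px(a, ph$pixel_spacing)
        rb <- .lesion_radius_px(b, ph$pixel_spacing)
        if (d < ra + rb + 1.5)
          stop(sprintf("lesions %d and %d overlap on slice %d", i, j, a$slice),
               call. = FALSE)
      }
    }
  }
  invisible(ph)
}

#' Build the noiseless 120 kVp reference volume of a phantom
#'
#' Background soft tissue at `background_hu`, a blood-pool cylinder through
#' all slices around the aortic center, and each lesion's pixels set to its
#' peak attenuation (uniform disc).
#'
#' @param phantom A [patient_phantom()].
#' @param background_hu Soft-tissue background in HU (default 40).
#' @return An [image_volume()].
#' @export
build_phantom <- function(phantom, background_hu = 40) {
  stopifnot(inherits(phantom, "patient_phantom"))
  ns <- phantom$grid[1]; nr <- phantom$grid[2]; nc <- phantom$grid[3]
  vol <- array(as.integer(round(background_hu)), dim = c(nr, nc, ns))
  pool <- .rasterize_disc(phantom$aortic_center[2:3],
                          phantom$blood_pool_diameter / 2 / phantom$pixel_spacing,
                          nr, nc)
  pool_hu <- as.integer(round(phantom$blood_pool_hu))
  for (s in seq_len(ns)) vol[cbind(pool, s)] <- pool_hu
  for (le in phantom$lesions) {
    px <- .rasterize_disc(le$center, .lesion_radius_px(le, phantom$pixel_spacing),
                          nr, nc)
    vol[cbind(px, le$slice)] <- as.integer(round(le$peak_hu))
  }
  image_volume(vol, phantom$pixel_spacing, phantom$slice_thickness)
}

# linear voxel indices (into the (nr, nc, ns) array) of all lesion pixels;
# this is the calcium mask used by simulate_scan
.calcium_indices <- function(phantom) {
  nr <- phantom$grid[2]; nc <- phantom$grid[3]
  idx <- lapply(phantom$lesions, function(le) {
    px <- .rasterize_disc(le$center, .lesion_radius_px(le, phantom$pixel_spacing),
                          nr, nc)
    px[, 1] + (px[, 2] - 1L) * nr + (le$slice - 1L) * nr * nc
  })
  as.integer(unlist(idx))
}

#' Ground-truth lesion table and Agatston score of a phantom
#'
#' Computes, from the rasterized geometry alone (no image needed), each
#' lesion's achievable area, its 120 kVp density weight and lesion score,
#' and the total noiseless Agatston score with the minimum-area rule
#' applied. This is the reference against which simulated scans are judged.
#'
#' @param phantom A [patient_phantom()].
#' @param min_area Minimum lesion area in mm^2 (default 1).
#' @return A list with `lesions` (data frame: slice, n_pixels, area_mm2,
#'   peak_hu, weight, score, counted), `total_score` and `risk_class`.
#' @export
ground_truth_score <- function(phantom, min_area = 1.0) {
  pa <- phantom$pixel_spacing^2
  tab <- threshold_table(120)
  rows <- lapply(phantom$lesions, function(le) {
    px <- .rasterize_disc(le$center, .lesion_radius_px(le, phantom$pixel_spacing),
                          phantom$grid[2], phantom$grid[3])
    k <- nrow(px)
    peak <- round(le$peak_hu)
    w <- density_weight(peak, tab)
    area <- k * pa
    counted <- area >= min_area && w >= 1
    data.frame(slice = le$slice, n_pixels = k, area_mm2 = area, peak_hu = peak,
               weight = w, score = if (counted) w * area else 0,
               counted = counted)
  })
  lesions <- if (length(rows)) do.call(rbind, rows) else
    data.frame(slice = integer(0), n_pixels = integer(0), area_mm2 = numeric(0),
               peak_hu = numeric(0), weight = integer(0), score = numeric(0),
               counted = logical(0))
  total <- sum(lesions$score)
  list(lesions = lesions, total_score = total, risk_class = risk_class(total))
}
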