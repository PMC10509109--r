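#' CT-like attenuation volume
#'
#' A 3D grid of integer attenuation values (Hounsfield units) with in-plane
#' pixel spacing and slice thickness. Dimensions are (rows, columns, slices).
#'
#' @param voxels 3D integer array of HU values, dim (nrow, ncol, nslice).
#' @param pixel_spacing In-plane pixel edge length in mm.
#' @param slice_thickness Slice thickness in mm.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, pixel_spacing, slice_thickness = 2.5) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array", call. = FALSE)
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 1L || pixel_spacing <= 0)
    stop("`pixel_spacing` must be a single positive number (mm)", call. = FALSE)
  if (slice_thickness <= 0) stop("`slice_thickness` must be positive (mm)", call. = FALSE)
  if (is.double(voxels)) {
    if (max(abs(voxels - round(voxels))) > 1e-8)
      stop("HU values must be integers; round the volume first", call. = FALSE)
    storage.mode(voxels) <- "integer"
  }
  structure(list(voxels = voxels, pixel_spacing = pixel_spacing,
                 slice_thickness = slice_thickness),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_volume: %d x %d x %d voxels, %.4f mm pixels, %.2f mm slices\n",
              d[1], d[2], d[3], x$pixel_spacing, x$slice_thickness))
  cat(sprintf("  HU range [%d, %d]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$voxels)

#' Area of one pixel in mm^2
#' @param volume An [image_volume()] (or a `patient_phantom`).
#' @return Pixel area in mm^2.
#' @export
pixel_area <- function(volume) volume$pixel_spacing^2

#' Read or write a volume as NIfTI
#'
#' Single-file NIfTI-1 export with spacing metadata, so simulated phantoms
#' can be inspected in standard medical-image viewers.
#'
#' @param volume An [image_volume()].
#' @param path File path ending in `.nii` or `.nii.gz`.
#' @return `write_volume()` returns `path` invisibly; `read_volume()`
#'   returns an [image_volume()].
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  img <- RNifti::asNifti(volume$voxels)
  # single-slice volumes are 2D to NIfTI; slice thickness is then not
  # representable and is restored to the default on read
  pd <- c(volume$pixel_spacing, volume$pixel_spacing, volume$slice_thickness)
  RNifti::pixdim(img) <- pd[seq_along(RNifti::pixdim(img))]
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  d <- dim(img)
  if (length(d) == 2L) d <- c(d, 1L)  # single-slice volumes drop the z dim
  arr <- array(as.integer(round(img)), dim = d)
  st <- if (length(pd) >= 3 && pd[3] > 0) pd[3] else 2.5
  image_volume(arr, pixel_spacing = pd[1], slice_thickness = st)
}

# round-half-up, the convention used for score -> risk-class integ
.round_half_up <- function(x) floor(x + 0.5)
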