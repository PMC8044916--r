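#' @useDynLib nactrad, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile rnorm runif rbinom sd var setNames
#' @importFrom utils head tail read.csv write.csv
NULL

#' Create a 3D image volume
#'
#' The basic carrier of all image arithmetic in the package: a 3D scalar
#' lattice with physical voxel spacing (mm) and a world-space origin (mm).
#' World coordinates follow `origin + index * spacing` with 0-based indices.
#'
#' @param values 3D numeric array of voxel intensities.
#' @param spacing numeric length-3, voxel size in mm per axis (positive).
#' @param origin numeric length-3, world-space position of voxel (0,0,0) in mm.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array, got dimensionality ",
         length(dim(values)))
  if (length(values) == 0L) stop("image lattice must be nonempty")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values")
  if (any(!is.finite(values)))
    stop("image values must all be finite")
  storage.mode(values) <- "double"
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<image_volume> %d x %d x %d, spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g], origin (%.4g, %.4g, %.4g) mm\n",
              min(x$values), max(x$values),
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$values)

is_image_volume <- function(x) inherits(x, "image_volume")

#' Create a binary mask paired with an image lattice
#'
#' @param values 3D array with values in \{0, 1\} (logical accepted).
#' @inheritParams image_volume
#' @param require_foreground if TRUE (default), at least one voxel must be 1.
#' @return An object of classes `binary_mask` and `image_volume`.
#' @export
binary_mask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        require_foreground = TRUE) {
  if (is.logical(values)) {
    v <- array(as.double(values), dim = dim(values))
  } else v <- values
  if (!all(v %in% c(0, 1)))
    stop("mask values must be 0 or 1")
  if (require_foreground && sum(v) < 1)
    stop("ROI mask must contain at least one foreground voxel")
  out <- image_volume(v, spacing, origin)
  class(out) <- c("binary_mask", class(out))
  out
}

mask_logical <- function(mask) mask$values > 0.5

stopifnot_same_lattice <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)))
    stop("volumes must share the same lattice dimensions")
  if (max(abs(a$spacing - b$spacing)) > 1e-8)
    stop("volumes must share the same voxel spacing")
  invisible(TRUE)
}

#' Create a DCE series
#'
#' An ordered dynamic contrast-enhanced acquisition: one precontrast frame
#' (S0) followed by one or more postcontrast frames, all on the same lattice.
#'
#' @param frames list of `image_volume`, frame 1 is the precontrast S0.
#' @param times numeric, acquisition times in seconds from injection
#'   (same length as `frames`).
#' @return An object of class `dce_series`.
#' @export
dce_series <- function(frames, times = NULL) {
  if (length(frames) < 2L)
    stop("a DCE series needs a precontrast frame plus >= 1 postcontrast frame")
  if (!all(vapply(frames, is_image_volume, logical(1))))
    stop("all frames must be image_volume objects")
  for (i in seq_along(frames)[-1]) stopifnot_same_lattice(frames[[1]], frames[[i]])
  if (is.null(times)) times <- seq(0, by = 60, length.out = length(frames))
  if (length(times) != length(frames))
    stop("`times` must match the number of frames")
  structure(list(frames = frames, times = as.numeric(times)),
            class = "dce_series")
}

#' @export
print.dce_series <- function(x, ...) {
  cat(sprintf("<dce_series> %d frames (S0 + %d postcontrast)\n",
              length(x$frames), length(x$frames) - 1L))
  invisible(x)
}

#' Create a displacement field
#'
#' Per-voxel 3-vector displacement in mm, defined on the baseline lattice.
#' The field maps baseline world coordinates x to follow-up coordinates
#' x + u(x).
#'
#' @param components 4D numeric array (nx, ny, nz, 3) of mm displacements.
#' @inheritParams image_volume
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(components, spacing = c(1, 1, 1),
                               origin = c(0, 0, 0)) {
  d <- dim(components)
  if (length(d) != 4L || d[4] != 3L)
    stop("`components` must be a 4D (nx, ny, nz, 3) array")
  if (any(!is.finite(components)))
    stop("displacement components must all be finite")
  if (any(spacing <= 0)) stop("`spacing` must be strictly positive")
  storage.mode(components) <- "double"
  structure(list(components = components, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  d <- dim(x$components)
  mags <- sqrt(rowSums(matrix(x$components, ncol = 3)^2))
  cat(sprintf("<displacement_field> %d x %d x %d, |u| mean %.3g mm, max %.3g mm\n",
              d[1], d[2], d[3], mean(mags), max(mags)))
  invisible(x)
}

#' Read a 3D NIfTI volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return An `image_volume` with spacing and origin taken from the header.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D payload, file has dimensionality ", length(d))
  sp <- RNifti::pixdim(img)[1:3]
  if (any(sp <= 0)) stop("non-positive voxel spacing in header: ",
                         paste(sp, collapse = " x "))
  xf <- RNifti::xform(img)
  image_volume(array(as.numeric(img), dim = d), spacing = sp,
               origin = as.numeric(xf[1:3, 4]))
}

#' Write a 3D volume (or displacement field) as NIfTI
#'
#' Volumes are stored as 64-bit floats so that a write/read round trip is
#' bit-exact. Displacement fields are written as 4D 3-component images.
#'
#' @param volume an `image_volume` or `displacement_field`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (inherits(volume, "displacement_field")) {
    arr <- volume$components
  } else if (is_image_volume(volume)) {
    arr <- volume$values
  } else stop("`volume` must be an image_volume or displacement_field")
  img <- RNifti::asNifti(structure(arr, pixdim = volume$spacing))
  mat <- diag(c(volume$spacing, 1))
  mat[1:3, 4] <- volume$origin
  RNifti::sform(img) <- structure(mat, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a displacement field from a 4D NIfTI file
#'
#' @param path path to a 4D (nx, ny, nz, 3) NIfTI file.
#' @return A `displacement_field`.
#' @export
read_field <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4] != 3L)
    stop("expected a 4D 3-component payload, got dims ",
         paste(d, collapse = " x "))
  xf <- RNifti::xform(img)
  displacement_field(array(as.numeric(img), dim = d),
                     spacing = RNifti::pixdim(img)[1:3],
                     origin = as.numeric(xf[1:3, 4]))
}

#' Resample a volume to a new voxel spacing
#'
#' The physical extent of the image is preserved (to within one voxel);
#' intensities are interpolated at the requested order. Masks should be
#' resampled with `order = 0` (nearest neighbour), which is done
#' automatically when `volume` is a `binary_mask`.
#'
#' @param volume an `image_volume`.
#' @param target_spacing numeric length-3 (or scalar, recycled), mm.
#' @param order interpolation order: 0 (nearest) or 1 (trilinear).
#' @return The resampled `image_volume` (a `binary_mask` stays a mask).
#' @export
resample_volume <- function(volume, target_spacing, order = 1L) {
  stopifnot(is_image_volume(volume))
  target_spacing <- rep_len(as.numeric(target_spacing), 3L)
  if (any(!is.finite(target_spacing)) || any(target_spacing <= 0))
    stop("`target_spacing` must be strictly positive")
  is_mask <- inherits(volume, "binary_mask")
  if (is_mask) order <- 0L
  d <- dim(volume$values)
  extent <- d * volume$spacing
  nd <- pmax(1L, as.integer(round(extent / target_spacing)))
  # Voxel-centre coordinates of the output grid, expressed on the input grid.
  gx <- (seq_len(nd[1]) - 1) * target_spacing[1] / volume$spacing[1]
  gy <- (seq_len(nd[2]) - 1) * target_spacing[2] / volume$spacing[2]
  gz <- (seq_len(nd[3]) - 1) * target_spacing[3] / volume$spacing[3]
  coords <- cbind(rep(gx, times = nd[2] * nd[3]),
                  rep(rep(gy, each = nd[1]), times = nd[3]),
                  rep(gz, each = nd[1] * nd[2]))
  vals <- cpp_interp3(as.numeric(volume$values), d, coords, as.integer(order))
  arr <- array(vals, dim = nd)
  if (is_mask) {
    binary_mask(arr, spacing = target_spacing, origin = volume$origin,
                require_foreground = FALSE)
  } else {
    image_volume(arr, spacing = target_spacing, origin = volume$origin)
  }
}

#' Physical volume of a mask in cubic millimetres
#'
#' @param mask a `binary_mask`.
#' @return Foreground voxel count times voxel volume (mm^3).
#' @export
mask_volume_mm3 <- function(mask) {
  sum(mask$values > 0.5) * prod(mask$spacing)
}

# Gaussian smoothing of a plain 3D array, sigma in mm.
smooth_array <- function(arr, sigma_mm, spacing) {
  sig <- rep_len(sigma_mm, 3L) / spacing
  if (all(sig <= 0)) return(arr)
  array(cpp_gaussian_smooth3(as.numeric(arr), dim(arr), sig), dim = dim(arr))
}
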