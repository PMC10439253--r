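#' Construct a CT volume
#'
#' A `ct_volume` is a 3D voxel grid of Hounsfield-unit (HU) intensities with
#' physical voxel spacing in millimetres. Axial slices are the third array
#' axis; indices are voxel-based.
#'
#' @param voxels 3D numeric array of HU intensities.
#' @param spacing numeric length-3, voxel spacing (dx, dy, dz) in mm.
#' @param origin numeric length-3, physical position of voxel (1,1,1) in mm.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L || any(dim(voxels) < 1L))
    stop("'voxels' must be a non-empty 3D array")
  if (!all(is.finite(voxels))) stop("HU values must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive values (mm)")
  structure(list(voxels = voxels, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "ct_volume")
}

#' Construct a binary region-of-interest mask
#'
#' @param voxels 3D array; non-zero marks the tumor.
#' @param spacing,origin as in [ct_volume()]; must match the paired volume.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(voxels, spacing, origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L) stop("'voxels' must be a 3D array")
  voxels <- (voxels > 0.5) * 1L
  storage.mode(voxels) <- "integer"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive values (mm)")
  structure(list(voxels = voxels, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "roi_mask")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("CT volume: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, HU range [%.1f, %.1f]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ROI mask: %d x %d x %d voxels, %d foreground\n",
              d[1], d[2], d[3], sum(x$voxels)))
  invisible(x)
}

#' HU window specification
#'
#' Intensities are clipped to `[lo, hi]` and rescaled to `[0, 1]`. The
#' default window of -150 to +150 HU emphasises soft-tissue contrast.
#'
#' @param lo,hi lower/upper HU bound, `lo < hi`.
#' @export
window_spec <- function(lo = -150, hi = 150) {
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop("window requires finite lo < hi")
  structure(list(lo = lo, hi = hi), class = "window_spec")
}

#' Read an aligned CT image / tumor mask pair from NIfTI files
#'
#' @param image_path,mask_path paths to NIfTI (.nii / .nii.gz) files encoding
#'   3D volumes on the same grid.
#' @param spacing_tol relative tolerance for spacing agreement.
#' @return list with elements `volume` ([ct_volume]) and `mask` ([roi_mask]).
#' @export
read_case <- function(image_path, mask_path, spacing_tol = 1e-3) {
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  di <- dim(img); dm <- dim(msk)
  if (length(di) != 3L || length(dm) != 3L)
    stop("expected 3D volumes: ", image_path)
  if (!identical(di, dm))
    stop(sprintf("grid mismatch: image %s vs mask %s",
                 paste(di, collapse = "x"), paste(dm, collapse = "x")))
  si <- RNifti::pixdim(img); sm <- RNifti::pixdim(msk)
  if (any(abs(si - sm) > spacing_tol * pmax(si, sm)))
    stop("grid mismatch: image and mask spacings differ")
  if (!any(msk > 0.5)) stop("empty mask: no foreground voxel in ", mask_path)
  list(volume = ct_volume(as.array(img), si),
       mask = roi_mask(as.array(msk), si))
}

#' Write a CT volume or mask to a NIfTI file
#'
#' @param x a [ct_volume] or [roi_mask].
#' @param path output path (.nii or .nii.gz).
#' @export
write_nifti_volume <- function(x, path) {
  arr <- x$voxels
  storage.mode(arr) <- "double"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

## 1D linear interpolation index/weight pairs for resampling one axis.
## Output voxel centres sit at i * s_out, input centres at j * s_in (0-based),
## so target spacing == source spacing is exactly the identity.
.lin_coeff <- function(n_in, s_in, n_out, s_out) {
  x <- (seq_len(n_out) - 1) * s_out / s_in  # position in input index units
  x <- pmin(pmax(x, 0), n_in - 1)
  i0 <- pmin(floor(x), n_in - 2)
  f <- x - i0
  list(i0 = as.integer(i0) + 1L, f = f)
}

#' Resample a CT volume to a target spacing by trilinear interpolation
#'
#' The output grid keeps the input origin; the number of voxels per axis is
#' chosen so the physical extent is preserved to within one voxel. Resampling
#' to the input's own spacing is the identity.
#'
#' @param vol a [ct_volume].
#' @param target_spacing numeric length-3 spacing in mm.
#' @return A resampled [ct_volume].
#' @export
resample_volume <- function(vol, target_spacing) {
  stopifnot(inherits(vol, "ct_volume"))
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(target_spacing <= 0))
    stop("target spacing must be 3 positive values")
  d <- dim(vol$voxels)
  if (any(d < 2L)) stop("degenerate volume: every dimension must be >= 2")
  n_out <- pmax(2L, as.integer(round((d - 1) * vol$spacing / target_spacing)) + 1L)
  cx <- .lin_coeff(d[1], vol$spacing[1], n_out[1], target_spacing[1])
  cy <- .lin_coeff(d[2], vol$spacing[2], n_out[2], target_spacing[2])
  cz <- .lin_coeff(d[3], vol$spacing[3], n_out[3], target_spacing[3])
  v <- vol$voxels
  ## interpolate axis by axis
  a <- v[cx$i0, , , drop = FALSE] * (1 - cx$f) + v[cx$i0 + 1L, , , drop = FALSE] * cx$f
  a <- sweep(a[, cy$i0, , drop = FALSE], 2, 1 - cy$f, "*") +
       sweep(a[, cy$i0 + 1L, , drop = FALSE], 2, cy$f, "*")
  a <- sweep(a[, , cz$i0, drop = FALSE], 3, 1 - cz$f, "*") +
       sweep(a[, , cz$i0 + 1L, drop = FALSE], 3, cz$f, "*")
  ct_volume(a, target_spacing, vol$origin)
}

#' Resample a binary mask to a target spacing (nearest neighbour)
#'
#' @inheritParams resample_volume
#' @param mask a [roi_mask].
#' @return A resampled [roi_mask].
#' @export
resample_mask <- function(mask, target_spacing) {
  stopifnot(inherits(mask, "roi_mask"))
  target_spacing <- as.numeric(target_spacing)
  d <- dim(mask$voxels)
  if (any(d < 2L)) stop("degenerate volume: every dimension must be >= 2")
  n_out <- pmax(2L, as.integer(round((d - 1) * mask$spacing / target_spacing)) + 1L)
  nn <- function(n_in, s_in, n_out, s_out) {
    x <- (seq_len(n_out) - 1) * s_out / s_in
    pmin(pmax(as.integer(round(x)) + 1L, 1L), n_in)
  }
  v <- mask$voxels[nn(d[1], mask$spacing[1], n_out[1], target_spacing[1]),
                   nn(d[2], mask$spacing[2], n_out[2], target_spacing[2]),
                   nn(d[3], mask$spacing[3], n_out[3], target_spacing[3]),
                   drop = FALSE]
  roi_mask(v, target_spacing, mask$origin)
}

#' Window-normalize HU intensities to the unit interval
#'
#' Applies `clip((v - lo) / (hi - lo), 0, 1)` voxelwise.
#'
#' @param vol a [ct_volume] (or bare numeric array).
#' @param w a [window_spec].
#' @return Same type as `vol`, values in `[0, 1]` (unitless).
#' @export
window_normalize <- function(vol, w = window_spec()) {
  stopifnot(inherits(w, "window_spec"))
  f <- function(v) pmin(pmax((v - w$lo) / (w$hi - w$lo), 0), 1)
  if (inherits(vol, "ct_volume")) {
    vol$voxels <- f(vol$voxels)
    vol
  } else f(vol)
}

#' Index of the axial slice with the largest in-slice tumor area
#'
#' Area is foreground voxel count times dx*dy (mm^2); ties are broken by the
#' lowest slice index.
#'
#' @param mask a [roi_mask].
#' @return Integer slice index (1-based, third array axis).
#' @export
select_largest_slice <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  areas <- apply(mask$voxels, 3, sum) * mask$spacing[1] * mask$spacing[2]
  if (max(areas) == 0) stop("empty mask: no foreground voxel")
  which.max(areas)  # first maximum = lowest index
}

## Bilinear resize of a 2D matrix to out_h x out_w (pixel-centre alignment).
bilinear_resize <- function(img, out_h, out_w) {
  h <- nrow(img); w <- ncol(img)
  sx <- h / out_h; sy <- w / out_w
  gx <- pmin(pmax((seq_len(out_h) - 0.5) * sx + 0.5 - 1, 0), h - 1)
  gy <- pmin(pmax((seq_len(out_w) - 0.5) * sy + 0.5 - 1, 0), w - 1)
  i0 <- pmin(floor(gx), h - 2); fx <- gx - i0
  j0 <- pmin(floor(gy), w - 2); fy <- gy - j0
  i0 <- as.integer(i0) + 1L; j0 <- as.integer(j0) + 1L
  a <- img[i0, j0, drop = FALSE] * ((1 - fx) %o% (1 - fy)) +
       img[i0 + 1L, j0, drop = FALSE] * (fx %o% (1 - fy)) +
       img[i0, j0 + 1L, drop = FALSE] * ((1 - fx) %o% fy) +
       img[i0 + 1L, j0 + 1L, drop = FALSE] * (fx %o% fy)
  a
}

## Nearest-neighbour resize (keeps binary masks binary).
nearest_resize <- function(img, out_h, out_w) {
  h <- nrow(img); w <- ncol(img)
  gi <- pmin(pmax(as.integer(ceiling((seq_len(out_h) - 0.5) * h / out_h)), 1L), h)
  gj <- pmin(pmax(as.integer(ceiling((seq_len(out_w) - 0.5) * w / out_w)), 1L), w)
  img[gi, gj, drop = FALSE]
}

#' Build the 3-channel network input for one case
#'
#' Selects the axial slice with the largest tumor area, window-normalizes it,
#' crops the square bounding box of the in-slice mask expanded by a margin
#' fraction (clipped at the image border), and resizes to `size` x `size`:
#' bilinear for the image channel, nearest-neighbour for the mask channel.
#' Channels are (1) the full CT crop, (2) the CT crop with background zeroed
#' outside the mask, (3) the binary mask.
#'
#' @param vol a [ct_volume], already resampled to the analysis spacing.
#' @param mask the aligned [roi_mask].
#' @param w a [window_spec].
#' @param size output side length in pixels (default 64).
#' @param margin margin fraction added around the mask bounding box
#'   (default 0.25).
#' @param case_id identifier carried into the result.
#' @return An object of class `model_input`: list with `channels`
#'   (size x size x 3 array in `[0,1]`), `slice_index`, `case_id`.
#' @export
build_input <- function(vol, mask, w = window_spec(), size = 64L,
                        margin = 0.25, case_id = NA_character_) {
  stopifnot(inherits(vol, "ct_volume"), inherits(mask, "roi_mask"))
  if (!identical(dim(vol$voxels), dim(mask$voxels)))
    stop("grid mismatch between volume and mask")
  k <- select_largest_slice(mask)
  sl <- window_normalize(vol$voxels[, , k], w)
  ms <- mask$voxels[, , k]
  idx <- which(ms == 1L, arr.ind = TRUE)
  r1 <- min(idx[, 1]); r2 <- max(idx[, 1])
  c1 <- min(idx[, 2]); c2 <- max(idx[, 2])
  side <- max(r2 - r1 + 1L, c2 - c1 + 1L)
  half <- ceiling(side * (1 + 2 * margin) / 2)
  rc <- floor((r1 + r2) / 2); cc <- floor((c1 + c2) / 2)
  rows <- max(1L, rc - half):min(nrow(sl), rc + half)
  cols <- max(1L, cc - half):min(ncol(sl), cc + half)
  ch1 <- bilinear_resize(sl[rows, cols, drop = FALSE], size, size)
  ch3 <- nearest_resize(ms[rows, cols, drop = FALSE], size, size)
  ch1 <- pmin(pmax(ch1, 0), 1)
  channels <- array(0, c(size, size, 3))
  channels[, , 1] <- ch1
  channels[, , 2] <- ch1 * ch3
  channels[, , 3] <- ch3
  structure(list(channels = channels, slice_index = k, case_id = case_id),
            class = "model_input")
}

#' @export
print.model_input <- function(x, ...) {
  cat(sprintf("model input '%s': %d x %d x 3, slice %d, mask fraction %.3f\n",
              x$case_id, dim(x$channels)[1], dim(x$channels)[2],
              x$slice_index, mean(x$channels[, , 3])))
  invisible(x)
}
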