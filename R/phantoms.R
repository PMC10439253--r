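#' Specification of a synthetic CT phantom cohort
#'
#' Phantoms are soft-tissue-range HU volumes containing one ellipsoidal
#' tumor whose intratumoral texture (a smoothed Gaussian random field) and
#' mean attenuation depend on a binary class label, emulating the
#' high/low tumor-microenvironment contrast the classifier must recover.
#' The class signal lives in texture statistics so that both the radiomics
#' bank and the convolutional branch can see it.
#'
#' @param volume_shape integer length-3, voxel grid size.
#' @param spacing numeric length-3, voxel spacing in mm.
#' @param background_hu c(mean, sd) of the background in HU.
#' @param radius_range tumor equatorial semi-axis range in mm.
#' @param axis_ratio_range range of the ratios applied to the other two
#'   semi-axes.
#' @param mean_hu_shift additive HU shift of class-1 tumors relative to
#'   class 0.
#' @param texture_grain c(class0, class1) texture correlation length in mm
#'   (Gaussian smoothing sigma); finer grain = busier texture.
#' @param texture_sd c(class0, class1) intratumoral texture standard
#'   deviation in HU.
#' @param prevalence probability of class 1.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(volume_shape = c(56L, 56L, 14L),
                         spacing = c(1, 1, 2.5),
                         background_hu = c(40, 12),
                         radius_range = c(6, 14),
                         axis_ratio_range = c(0.6, 1),
                         mean_hu_shift = 20,
                         texture_grain = c(4, 1.5),
                         texture_sd = c(12, 35),
                         prevalence = 0.5) {
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0,1)")
  if (any(radius_range <= 0)) stop("radii must be positive")
  if (any(texture_sd < 0)) stop("texture sd must be >= 0")
  structure(list(volume_shape = as.integer(volume_shape),
                 spacing = as.numeric(spacing),
                 background_hu = background_hu,
                 radius_range = radius_range,
                 axis_ratio_range = axis_ratio_range,
                 mean_hu_shift = mean_hu_shift,
                 texture_grain = texture_grain,
                 texture_sd = texture_sd,
                 prevalence = prevalence),
            class = "phantom_spec")
}

## Separable Gaussian smoothing of a 3D array; sigma per axis in voxels.
## Kernel rows renormalised so constants are preserved at the borders.
gauss_smooth3 <- function(a, sigma) {
  smooth_axis <- function(a, axis, s) {
    if (s <= 1e-8) return(a)
    n <- dim(a)[axis]
    r <- min(n - 1L, as.integer(ceiling(3 * s)))
    x <- (-r):r
    k <- exp(-x^2 / (2 * s^2))
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- pmin(pmax(i + x, 1L), n)  # clamp taps at the border
      for (t in seq_along(j)) K[i, j[t]] <- K[i, j[t]] + k[t]
    }
    K <- K / rowSums(K)
    d <- dim(a)
    if (axis == 1L) {
      array(K %*% matrix(a, d[1]), d)
    } else if (axis == 2L) {
      b <- aperm(a, c(2, 1, 3))
      aperm(array(K %*% matrix(b, d[2]), dim(b)), c(2, 1, 3))
    } else {
      b <- aperm(a, c(3, 1, 2))
      aperm(array(K %*% matrix(b, d[3]), dim(b)), c(2, 3, 1))
    }
  }
  for (ax in 1:3) a <- smooth_axis(a, ax, sigma[ax])
  a
}

#' Generate one synthetic phantom case
#'
#' Draws the class label from `Bernoulli(prevalence)`, places one random
#' ellipsoidal tumor fully inside the volume, plants class-dependent
#' texture (smoothed Gaussian random field rescaled to the class texture
#' sd) plus the class mean shift inside the tumor, and clips all HU values
#' to (-200, 300). Consumes the current R random stream.
#'
#' @param spec a [phantom_spec].
#' @param case_id identifier recorded in the outputs.
#' @return An object of class `phantom_case`: list with `volume`
#'   ([ct_volume]), `mask` ([roi_mask]), `label` (0/1) and `provenance`
#'   (realized parameters).
#' @export
generate_case <- function(spec, case_id = "case") {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$volume_shape; sp <- spec$spacing
  label <- stats::rbinom(1, 1, spec$prevalence)
  r_eq <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
  semi <- c(r_eq,
            r_eq * stats::runif(1, spec$axis_ratio_range[1], spec$axis_ratio_range[2]),
            r_eq * stats::runif(1, spec$axis_ratio_range[1], spec$axis_ratio_range[2]))
  extent <- (d - 1) * sp
  if (any(2 * semi > extent))
    stop("infeasible geometry: tumor cannot fit inside the volume")
  lo <- semi; hi <- extent - semi
  centre <- stats::runif(3, lo, hi)
  xs <- (seq_len(d[1]) - 1) * sp[1]
  ys <- (seq_len(d[2]) - 1) * sp[2]
  zs <- (seq_len(d[3]) - 1) * sp[3]
  q <- outer(((xs - centre[1]) / semi[1])^2,
             ((ys - centre[2]) / semi[2])^2, "+")
  q <- outer(q, ((zs - centre[3]) / semi[3])^2, "+")
  msk <- (q <= 1) * 1L
  if (sum(msk) < 8L)
    stop("infeasible geometry: tumor too small for the voxel grid")
  ## scanner-like noise everywhere; the class-dependent texture field is
  ## added on top inside the tumor, so its sd is planted relative to a
  ## fixed absolute noise floor
  vox <- array(spec$background_hu[1] +
                 stats::rnorm(prod(d), 0, spec$background_hu[2]), d)
  cls <- label + 1L
  grain_vox <- spec$texture_grain[cls] / sp
  field <- gauss_smooth3(array(stats::rnorm(prod(d)), d), grain_vox)
  fs <- stats::sd(field[msk == 1L])
  if (fs > 0) field <- field / fs * spec$texture_sd[cls]
  shift <- if (label == 1L) spec$mean_hu_shift else 0
  inside <- msk == 1L
  vox[inside] <- vox[inside] + shift + field[inside]
  vox <- pmin(pmax(vox, -200), 300)
  structure(list(volume = ct_volume(vox, sp),
                 mask = roi_mask(msk, sp),
                 label = label,
                 provenance = list(case_id = case_id, label = label,
                                   centre_mm = centre, semi_axes_mm = semi,
                                   texture_grain_mm = spec$texture_grain[cls],
                                   texture_sd_hu = spec$texture_sd[cls])),
            class = "phantom_case")
}

#' Generate a phantom cohort in memory
#'
#' @param spec a [phantom_spec].
#' @param n number of cases (>= 2).
#' @param seed integer seed; the cohort is a pure function of
#'   `(spec, n, seed)`.
#' @return list of [generate_case()] results with names `case_0001`, ...
#' @export
generate_cohort <- function(spec, n, seed = 1L) {
  if (n < 2) stop("need at least 2 cases")
  set.seed(seed)
  ids <- sprintf("case_%04d", seq_len(n))
  stats::setNames(lapply(ids, function(id) generate_case(spec, id)), ids)
}

#' Write a phantom cohort as NIfTI files plus a manifest CSV
#'
#' The manifest has columns `case_id,image_path,mask_path,label`, the same
#' schema used to ingest real cohorts.
#'
#' @inheritParams generate_cohort
#' @param dir output directory (created if needed).
#' @return Path to the manifest CSV, invisibly; the manifest data frame is
#'   attached as attribute `manifest`.
#' @export
write_phantom_cohort <- function(spec, n, dir, seed = 1L) {
  cohort <- generate_cohort(spec, n, seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(names(cohort), function(id) {
    ip <- file.path(dir, paste0(id, "_image.nii.gz"))
    mp <- file.path(dir, paste0(id, "_mask.nii.gz"))
    write_nifti_volume(cohort[[id]]$volume, ip)
    write_nifti_volume(cohort[[id]]$mask, mp)
    data.frame(case_id = id, image_path = ip, mask_path = mp,
               label = cohort[[id]]$label, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(structure(path, manifest = manifest))
}
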