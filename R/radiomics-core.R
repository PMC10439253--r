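#' Discretize in-mask intensities into gray levels
#'
#' Equal-width binning of the in-mask intensity range into `n_bins` levels.
#' A constant in-mask region maps entirely to level 1.
#'
#' @param slice 2D numeric matrix of intensities (HU or window-normalized).
#' @param mask 2D binary matrix of the same shape.
#' @param n_bins number of gray levels (>= 2).
#' @return An object of class `label_image`: list with `labels` (integer
#'   matrix, `NA` outside the mask), `mask`, `n_bins` and `raw` (the input
#'   intensities).
#' @export
discretize <- function(slice, mask, n_bins) {
  slice <- as.matrix(slice); mask <- as.matrix(mask)
  if (!identical(dim(slice), dim(mask))) stop("slice/mask shape mismatch")
  if (n_bins < 2) stop("n_bins must be >= 2")
  inm <- mask > 0.5
  if (sum(inm) < 2L) stop("too few in-mask pixels (need >= 2)")
  x <- slice[inm]
  lo <- min(x); rng <- max(x) - lo
  lab <- matrix(NA_integer_, nrow(slice), ncol(slice))
  if (rng == 0) {
    lab[inm] <- 1L
  } else {
    width <- rng / n_bins
    lab[inm] <- pmin(as.integer(floor((x - lo) / width)) + 1L, as.integer(n_bins))
  }
  structure(list(labels = lab, mask = inm * 1L, n_bins = as.integer(n_bins),
                 raw = slice),
            class = "label_image")
}

## Histogram probabilities over the realized gray levels 1..n_bins.
.label_hist <- function(li) {
  cnt <- tabulate(li$labels[li$mask == 1L], nbins = li$n_bins)
  cnt / sum(cnt)
}

#' First-order intensity statistics (18 features)
#'
#' Order statistics and moments are computed on the raw in-mask
#' intensities; `entropy` and `uniformity` on the discretized histogram, so
#' only those two depend on the discretization setting. Moments use the
#' population (denominator n) convention; skewness and kurtosis of a
#' constant region are reported as 0. `total_energy` scales energy by the
#' physical pixel area.
#'
#' @param li a [discretize()] result.
#' @param spacing in-plane pixel spacing (dx, dy) in mm.
#' @return Named numeric vector of 18 features.
#' @export
firstorder_features <- function(li, spacing = c(1, 1)) {
  stopifnot(inherits(li, "label_image"))
  x <- li$raw[li$mask == 1L]
  n <- length(x)
  if (n < 2L) stop("too few in-mask pixels")
  p <- .label_hist(li)
  pe <- p[p > 0]
  q <- stats::quantile(x, c(.10, .25, .50, .75, .90), names = FALSE, type = 7)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  sub <- x[x >= q[1] & x <= q[5]]
  c(energy = sum(x^2),
    total_energy = prod(spacing[1:2]) * sum(x^2),
    entropy = -sum(pe * log2(pe)),
    minimum = min(x),
    p10 = q[1],
    p90 = q[5],
    maximum = max(x),
    mean = m,
    median = q[3],
    iqr = q[4] - q[2],
    range = max(x) - min(x),
    mad = mean(abs(x - m)),
    rmad = mean(abs(sub - mean(sub))),
    rms = sqrt(mean(x^2)),
    skewness = if (m2 > 0) mean((x - m)^3) / m2^1.5 else 0,
    kurtosis = if (m2 > 0) mean((x - m)^4) / m2^2 else 0,
    variance = m2,
    uniformity = sum(pe^2))
}

#' Two-dimensional shape features of a binary mask (9 features)
#'
#' Computed in physical units on the largest-tumor slice. The mesh surface
#' and perimeter come from the half-level isocontour (marching squares with
#' linear interpolation) of the lightly smoothed mask, which is accurate
#' for smooth tumor outlines; `pixel_surface` is the foreground count times
#' the pixel area. Sphericity is `2*sqrt(pi*A)/P` (1 for a circle) and
#' spherical disproportion its reciprocal. The maximum 2D diameter is the
#' largest pairwise distance between boundary pixel centres; the major axis
#' length is `4*sqrt(lambda1)` from the PCA of foreground pixel coordinates
#' and elongation is `sqrt(lambda2/lambda1)`.
#'
#' @param mask 2D binary matrix.
#' @param spacing pixel spacing (dx, dy) in mm.
#' @return Named numeric vector of 9 features.
#' @export
shape2d_features <- function(mask, spacing = c(1, 1)) {
  mask <- (as.matrix(mask) > 0.5) * 1L
  dx <- spacing[1]; dy <- spacing[2]
  n <- sum(mask)
  if (n < 2L) stop("too few in-mask pixels for shape analysis")
  ms <- .mask_contour(mask, dx, dy)
  if (ms$area <= 0) stop("too few in-mask pixels for shape analysis")
  ## boundary pixels: foreground with a 4-neighbour outside the mask
  inm <- mask == 1L
  shift_sum <- function(m) {
    s <- matrix(0L, nrow(m), ncol(m))
    s[-1, ] <- s[-1, ] + m[-nrow(m), ]
    s[-nrow(m), ] <- s[-nrow(m), ] + m[-1, ]
    s[, -1] <- s[, -1] + m[, -ncol(m)]
    s[, -ncol(m)] <- s[, -ncol(m)] + m[, -1]
    s
  }
  interior <- shift_sum(mask) == 4L
  interior[!inm] <- FALSE
  interior[c(1, nrow(mask)), ] <- FALSE
  interior[, c(1, ncol(mask))] <- FALSE
  bidx <- which(inm & !interior, arr.ind = TRUE)
  bx <- (bidx[, 1] - 1) * dx; by <- (bidx[, 2] - 1) * dy
  dmax <- if (nrow(bidx) > 1)
    sqrt(max(outer(bx, bx, "-")^2 + outer(by, by, "-")^2)) else 0
  idx <- which(inm, arr.ind = TRUE)
  px <- (idx[, 1] - 1) * dx; py <- (idx[, 2] - 1) * dy
  cv <- stats::cov(cbind(px, py)) * (n - 1) / n
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  if (ev[1] <= 0) stop("too few in-mask pixels for shape analysis")
  spher <- 2 * sqrt(pi * ms$area) / ms$perimeter
  c(mesh_surface = ms$area,
    pixel_surface = n * dx * dy,
    perimeter = ms$perimeter,
    perimeter_surface_ratio = ms$perimeter / ms$area,
    sphericity = spher,
    spherical_disproportion = 1 / spher,
    max_diameter = dmax,
    major_axis_length = 4 * sqrt(ev[1]),
    elongation = sqrt(max(ev[2], 0) / ev[1]))
}

## Half-level isocontour of the mask by marching squares with linear
## interpolation on a [1,2,1]/4-smoothed copy (subpixel boundary placement;
## unbiased perimeters for smooth outlines). Oriented segments keep the
## foreground on the left, so summing cross products over the closed loops
## yields the enclosed area.
.mask_contour <- function(mask, dx, dy) {
  nr <- nrow(mask); nc <- ncol(mask)
  pm <- matrix(0, nr + 4L, nc + 4L)
  pm[3:(nr + 2L), 3:(nc + 2L)] <- mask
  k <- c(0.25, 0.5, 0.25)
  sm <- apply(pm, 2, function(v) stats::filter(v, k, sides = 2))
  sm <- t(apply(sm, 1, function(v) stats::filter(v, k, sides = 2)))
  sm[is.na(sm)] <- 0
  L <- 0.5
  a <- sm[-nrow(sm), -ncol(sm)]; b <- sm[-1, -ncol(sm)]
  cc <- sm[-nrow(sm), -1];       d <- sm[-1, -1]
  caseid <- (a >= L) + 2L * (b >= L) + 4L * (cc >= L) + 8L * (d >= L)
  cells <- which(caseid != 0L & caseid != 15L, arr.ind = TRUE)
  per <- 0; area2 <- 0
  cross <- function(p, q) p[1] * q[2] - p[2] * q[1]
  for (kk in seq_len(nrow(cells))) {
    i <- as.integer(cells[kk, 1]); j <- as.integer(cells[kk, 2])
    av <- a[i, j]; bv <- b[i, j]; cv <- cc[i, j]; dv <- d[i, j]
    p_ab <- c(i + (L - av) / (bv - av), j)
    p_cd <- c(i + (L - cv) / (dv - cv), j + 1)
    p_ac <- c(i, j + (L - av) / (cv - av))
    p_bd <- c(i + 1, j + (L - bv) / (dv - bv))
    segs <- switch(caseid[i, j],
      list(list(p_ab, p_ac)),                       # 1: A
      list(list(p_bd, p_ab)),                       # 2: B
      list(list(p_bd, p_ac)),                       # 3: A+B
      list(list(p_ac, p_cd)),                       # 4: C
      list(list(p_ab, p_cd)),                       # 5: A+C
      list(list(p_bd, p_ab), list(p_ac, p_cd)),     # 6: B+C (disconnected)
      list(list(p_bd, p_cd)),                       # 7: A+B+C
      list(list(p_cd, p_bd)),                       # 8: D
      list(list(p_ab, p_ac), list(p_cd, p_bd)),     # 9: A+D (disconnected)
      list(list(p_cd, p_ab)),                       # 10: B+D
      list(list(p_cd, p_ac)),                       # 11: A+B+D
      list(list(p_ac, p_bd)),                       # 12: C+D
      list(list(p_ab, p_bd)),                       # 13: A+C+D
      list(list(p_ac, p_ab)))                       # 14: B+C+D
    for (sg in segs) {
      p1 <- c(sg[[1]][1] * dx, sg[[1]][2] * dy)
      p2 <- c(sg[[2]][1] * dx, sg[[2]][2] * dy)
      per <- per + sqrt(sum((p1 - p2)^2))
      area2 <- area2 + cross(p1, p2)
    }
  }
  list(perimeter = unname(per), area = unname(abs(area2)) / 2)
}
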