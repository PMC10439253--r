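## Texture matrix families over a discretized label image.
##
## All four families follow the IBSI 2D conventions: distance-1 pixel pairs
## in the four directions 0/45/90/135 degrees for GLCM and GLRLM (features
## computed per direction, then direction-averaged), 8-connected zones for
## GLSZM and 8-neighbourhoods with exact-equality dependence for GLDM.
## Entropy-type sums run over strictly positive probabilities.

.tex_dirs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))

## pairs of in-mask labels at offset (dr, dc); returns two integer vectors
.offset_pairs <- function(lab, dr, dc) {
  nr <- nrow(lab); nc <- ncol(lab)
  r1 <- max(1L, 1L - dr):min(nr, nr - dr)
  c1 <- max(1L, 1L - dc):min(nc, nc - dc)
  a <- lab[r1, c1, drop = FALSE]
  b <- lab[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  list(a = a[ok], b = b[ok])
}

## symmetric normalized GLCM for one direction, or NULL if no valid pair
.glcm_matrix <- function(li, dir) {
  ng <- li$n_bins
  pr <- .offset_pairs(li$labels, dir[1], dir[2])
  if (length(pr$a) == 0L) return(NULL)
  cnt <- tabulate((pr$a - 1L) * ng + pr$b, nbins = ng * ng)
  P <- matrix(cnt, ng, ng, byrow = TRUE)
  P <- P + t(P)
  P / sum(P)
}

.glcm_from_P <- function(P) {
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P)
  mu <- sum(i * P)
  sigma2 <- sum((i - mu)^2 * P)
  k_d <- 0:(ng - 1)
  pxmy <- as.vector(rowsum(as.vector(P), as.vector(abs(i - j))))
  k_s <- 2:(2 * ng)
  pxpy <- as.vector(rowsum(as.vector(P), as.vector(i + j)))
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  da <- sum(k_d * pxmy)
  hx <- ent(px)
  hxy <- ent(P)
  pp <- outer(px, px)
  pos <- P > 0 & pp > 0
  hxy1 <- -sum(P[pos] * log2(pp[pos]))
  pos2 <- pp > 0
  hxy2 <- -sum(pp[pos2] * log2(pp[pos2]))
  corr <- if (sigma2 > 0) (sum(i * j * P) - mu^2) / sigma2 else 1
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))
  ## maximal correlation coefficient
  lv <- which(px > 0)
  mcc <- if (length(lv) < 2) 1 else {
    Ps <- P[lv, lv, drop = FALSE]
    pxs <- px[lv]
    ## Q(i,j) = sum_k P(i,k) P(j,k) / (px(i) px(k))
    Q <- matrix(0, length(lv), length(lv))
    for (kk in seq_along(lv))
      Q <- Q + outer(Ps[, kk] / pxs, Ps[, kk] / pxs[kk])
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(min(ev[2], 1), 0))
  }
  c(autocorrelation = sum(i * j * P),
    cluster_prominence = sum((i + j - 2 * mu)^4 * P),
    cluster_shade = sum((i + j - 2 * mu)^3 * P),
    cluster_tendency = sum((i + j - 2 * mu)^2 * P),
    contrast = sum((i - j)^2 * P),
    correlation = corr,
    difference_average = da,
    difference_entropy = ent(pxmy),
    difference_variance = sum((k_d - da)^2 * pxmy),
    id = sum(P / (1 + abs(i - j))),
    idm = sum(P / (1 + (i - j)^2)),
    idmn = sum(P / (1 + ((i - j) / ng)^2)),
    idn = sum(P / (1 + abs(i - j) / ng)),
    imc1 = imc1,
    imc2 = imc2,
    inverse_variance = sum(P[i != j] / (i - j)[i != j]^2),
    joint_average = mu,
    joint_energy = sum(P^2),
    joint_entropy = hxy,
    maximum_probability = max(P),
    mcc = mcc,
    sum_average = sum(k_s * pxpy),
    sum_entropy = ent(pxpy),
    sum_squares = sigma2)
}

#' Gray-level co-occurrence matrix features (24, direction-averaged)
#'
#' Symmetric distance-1 co-occurrence matrices in the requested directions;
#' each of the 24 features is computed per direction and the direction
#' average is reported.
#'
#' @param li a [discretize()] result.
#' @param directions list of integer (dr, dc) offsets; default the four
#'   2D directions 0, 45, 90, 135 degrees.
#' @return Named numeric vector of 24 features.
#' @export
glcm_features <- function(li, directions = .tex_dirs) {
  stopifnot(inherits(li, "label_image"))
  per <- lapply(directions, function(d) {
    P <- .glcm_matrix(li, d)
    if (is.null(P)) NULL else .glcm_from_P(P)
  })
  per <- per[!vapply(per, is.null, TRUE)]
  if (length(per) == 0L) stop("too few in-mask pixels: no valid pixel pair")
  Reduce(`+`, per) / length(per)
}

## run-length matrix (ng x max run length) for one direction
.glrlm_matrix <- function(li, dir) {
  lab <- li$labels
  nr <- nrow(lab); nc <- ncol(lab)
  dr <- dir[1]; dc <- dir[2]
  ## arrange every scan line as a row of an NA-padded matrix, then extract
  ## all runs with a single rle pass over the NA-separated vector
  if (dr == 0L && abs(dc) == 1L) {
    M <- lab
  } else if (dc == 0L && abs(dr) == 1L) {
    M <- t(lab)
  } else {
    r <- as.vector(row(lab)); cc <- as.vector(col(lab))
    key <- if (dr * dc == 1L) r - cc + nc else r + cc - 1L
    pos <- if (dr * dc == 1L) cc else r
    M <- matrix(NA_integer_, nr + nc - 1L, max(nr, nc))
    M[cbind(key, pos)] <- lab[cbind(r, cc)]
  }
  vec <- as.vector(t(cbind(M, NA_integer_)))
  rr <- rle(vec)
  keep <- !is.na(rr$values)
  gl <- rr$values[keep]; rl <- rr$lengths[keep]
  if (length(gl) == 0L) return(NULL)
  ng <- li$n_bins
  maxlen <- max(rl)
  cnt <- tabulate((gl - 1L) * maxlen + rl, nbins = ng * maxlen)
  matrix(cnt, ng, maxlen, byrow = TRUE)
}

.rlm_features <- function(P, np, kind = c("run", "zone")) {
  kind <- match.arg(kind)
  ns <- sum(P)
  i <- row(P); j <- col(P)
  p <- P / ns
  pg <- rowSums(P); pr <- colSums(P)
  mu_i <- sum(row(p) * p); mu_j <- sum(col(p) * p)
  pe <- p[p > 0]
  jj <- col(P)
  v <- c(sum(P / jj^2) / ns,            # short emphasis
         sum(P * jj^2) / ns,            # long/large emphasis
         sum(pg^2) / ns,                # gray-level non-uniformity
         sum(pg^2) / ns^2,              # GLN normalized
         sum(pr^2) / ns,                # run/zone-size non-uniformity
         sum(pr^2) / ns^2,              # normalized
         ns / np,                       # run/zone percentage
         sum((i - mu_i)^2 * p),         # gray-level variance
         sum((j - mu_j)^2 * p),         # run/zone variance
         -sum(pe * log2(pe)),           # entropy
         sum(P / i^2) / ns,             # low gray-level emphasis
         sum(P * i^2) / ns,             # high gray-level emphasis
         sum(P / (i^2 * jj^2)) / ns,    # short+low
         sum(P * i^2 / jj^2) / ns,      # short+high
         sum(P * jj^2 / i^2) / ns,      # long+low
         sum(P * i^2 * jj^2) / ns)      # long+high
  nm <- if (kind == "run") {
    c("short_run_emphasis", "long_run_emphasis",
      "gray_level_nonuniformity", "gray_level_nonuniformity_normalized",
      "run_length_nonuniformity", "run_length_nonuniformity_normalized",
      "run_percentage", "gray_level_variance", "run_variance",
      "run_entropy", "low_gray_level_run_emphasis",
      "high_gray_level_run_emphasis", "short_run_low_gray_level_emphasis",
      "short_run_high_gray_level_emphasis",
      "long_run_low_gray_level_emphasis",
      "long_run_high_gray_level_emphasis")
  } else {
    c("small_area_emphasis", "large_area_emphasis",
      "gray_level_nonuniformity", "gray_level_nonuniformity_normalized",
      "size_zone_nonuniformity", "size_zone_nonuniformity_normalized",
      "zone_percentage", "gray_level_variance", "zone_variance",
      "zone_entropy", "low_gray_level_zone_emphasis",
      "high_gray_level_zone_emphasis", "small_area_low_gray_level_emphasis",
      "small_area_high_gray_level_emphasis",
      "large_area_low_gray_level_emphasis",
      "large_area_high_gray_level_emphasis")
  }
  stats::setNames(v, nm)
}

#' Gray-level run-length matrix features (16, direction-averaged)
#'
#' Runs of equal gray level along each direction (mask gaps break runs);
#' the 16 IBSI GLRLM features are computed per direction and averaged.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features.
#' @export
glrlm_features <- function(li, directions = .tex_dirs) {
  stopifnot(inherits(li, "label_image"))
  np <- sum(li$mask)
  if (np < 2L) stop("too few in-mask pixels")
  per <- lapply(directions, function(d) {
    P <- .glrlm_matrix(li, d)
    if (is.null(P)) NULL else .rlm_features(P, np, "run")
  })
  per <- per[!vapply(per, is.null, TRUE)]
  if (length(per) == 0L) stop("too few in-mask pixels")
  Reduce(`+`, per) / length(per)
}

## 8-connected zones of equal gray level; returns data.frame(level, size)
.glszm_zones <- function(li) {
  lab <- li$labels
  nr <- nrow(lab); nc <- ncol(lab)
  inm <- !is.na(lab)
  np <- sum(inm)
  pixid <- matrix(0L, nr, nc)
  pixid[inm] <- seq_len(np)
  edges <- list()
  for (o in list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))) {
    dr <- o[1]; dc <- o[2]
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    a <- pixid[r1, c1, drop = FALSE]
    b <- pixid[r1 + dr, c1 + dc, drop = FALSE]
    la <- lab[r1, c1, drop = FALSE]
    lb <- lab[r1 + dr, c1 + dc, drop = FALSE]
    ok <- a > 0L & b > 0L & !is.na(la) & !is.na(lb) & la == lb
    if (any(ok)) edges[[length(edges) + 1L]] <- rbind(a[ok], b[ok])
  }
  membership <- if (length(edges)) {
    g <- igraph::make_graph(as.vector(do.call(cbind, edges)), n = np,
                            directed = FALSE)
    igraph::components(g)$membership
  } else seq_len(np)
  labs <- lab[inm]
  zone_size <- tabulate(membership, nbins = max(membership))
  zone_level <- labs[match(seq_along(zone_size), membership)]
  data.frame(level = as.integer(zone_level), size = as.integer(zone_size))
}

#' Gray-level size-zone matrix features (16)
#'
#' Zones are maximal 8-connected sets of equal gray level.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features.
#' @export
glszm_features <- function(li) {
  stopifnot(inherits(li, "label_image"))
  np <- sum(li$mask)
  if (np < 2L) stop("too few in-mask pixels")
  z <- .glszm_zones(li)
  smax <- max(z$size)
  cnt <- tabulate((z$level - 1L) * smax + z$size, nbins = li$n_bins * smax)
  P <- matrix(cnt, li$n_bins, smax, byrow = TRUE)
  .rlm_features(P, np, "zone")
}

#' Gray-level dependence matrix features (14)
#'
#' For each in-mask pixel the dependence is the number of its in-mask
#' 8-neighbours with exactly the same gray level (dependence tolerance 0).
#' The matrix is indexed by gray level and dependence count d in 0..8;
#' emphasis weights use the dependence size d+1 so the small/large
#' dependence formulas are finite for isolated pixels.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 14 features.
#' @export
gldm_features <- function(li) {
  stopifnot(inherits(li, "label_image"))
  lab <- li$labels
  np <- sum(li$mask)
  if (np < 2L) stop("too few in-mask pixels")
  nr <- nrow(lab); nc <- ncol(lab)
  dep <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    a <- lab[r1, c1, drop = FALSE]
    b <- lab[r1 + dr, c1 + dc, drop = FALSE]
    eq <- !is.na(a) & !is.na(b) & a == b
    dep[r1, c1] <- dep[r1, c1] + eq
  }
  inm <- !is.na(lab)
  g <- lab[inm]; d <- dep[inm]           # d in 0..8
  nd <- 9L
  cnt <- tabulate((g - 1L) * nd + d + 1L, nbins = li$n_bins * nd)
  P <- matrix(cnt, li$n_bins, nd, byrow = TRUE)
  ns <- sum(P)
  p <- P / ns
  i <- row(P); j <- col(P)               # j = d + 1 (dependence size)
  pg <- rowSums(P); pd <- colSums(P)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  pe <- p[p > 0]
  c(small_dependence_emphasis = sum(P / j^2) / ns,
    large_dependence_emphasis = sum(P * j^2) / ns,
    gray_level_nonuniformity = sum(pg^2) / ns,
    dependence_nonuniformity = sum(pd^2) / ns,
    dependence_nonuniformity_normalized = sum(pd^2) / ns^2,
    gray_level_variance = sum((i - mu_i)^2 * p),
    dependence_variance = sum((j - mu_j)^2 * p),
    dependence_entropy = -sum(pe * log2(pe)),
    low_gray_level_emphasis = sum(P / i^2) / ns,
    high_gray_level_emphasis = sum(P * i^2) / ns,
    small_dependence_low_gray_level_emphasis = sum(P / (i^2 * j^2)) / ns,
    small_dependence_high_gray_level_emphasis = sum(P * i^2 / j^2) / ns,
    large_dependence_low_gray_level_emphasis = sum(P * j^2 / i^2) / ns,
    large_dependence_high_gray_level_emphasis = sum(P * i^2 * j^2) / ns)
}
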