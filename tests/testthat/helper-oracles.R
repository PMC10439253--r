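## Independent brute-force oracles: explicit pixel/pair/run/zone/neighbour
## enumeration with plain double loops, kept deliberately naive so they
## share no code path with the package implementations.

oracle_dirs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))

## entropy helper (log2, positive entries only)
o_ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }

## ---- GLCM ----------------------------------------------------------------

oracle_glcm_matrix <- function(lab, ng, dir) {
  P <- matrix(0, ng, ng)
  nr <- nrow(lab); nc <- ncol(lab)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (is.na(lab[r, cc])) next
    for (sgn in c(1L, -1L)) {  # symmetric: count both orders
      r2 <- r + sgn * dir[1]; c2 <- cc + sgn * dir[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (is.na(lab[r2, c2])) next
      P[lab[r, cc], lab[r2, c2]] <- P[lab[r, cc], lab[r2, c2]] + 1
    }
  }
  if (sum(P) == 0) return(NULL)
  P / sum(P)
}

oracle_glcm_features <- function(P) {
  ng <- nrow(P)
  px <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) px[i] <- px[i] + P[i, j]
  mu <- 0
  for (i in 1:ng) mu <- mu + i * px[i]
  sig2 <- 0
  for (i in 1:ng) sig2 <- sig2 + (i - mu)^2 * px[i]
  pd <- numeric(ng)           # p_{x-y}(k), k = 0..ng-1
  ps <- numeric(2 * ng - 1)   # p_{x+y}(k), k = 2..2ng
  for (i in 1:ng) for (j in 1:ng) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
    ps[i + j - 1] <- ps[i + j - 1] + P[i, j]
  }
  da <- sum((0:(ng - 1)) * pd)
  acc <- cp <- cs <- ct <- con <- idv <- idmv <- idmn <- idn <- 0
  invvar <- je <- maxp <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    acc <- acc + i * j * p
    cp <- cp + (i + j - 2 * mu)^4 * p
    cs <- cs + (i + j - 2 * mu)^3 * p
    ct <- ct + (i + j - 2 * mu)^2 * p
    con <- con + (i - j)^2 * p
    idv <- idv + p / (1 + abs(i - j))
    idmv <- idmv + p / (1 + (i - j)^2)
    idmn <- idmn + p / (1 + ((i - j) / ng)^2)
    idn <- idn + p / (1 + abs(i - j) / ng)
    if (i != j) invvar <- invvar + p / (i - j)^2
    je <- je + p^2
    if (p > maxp) maxp <- p
  }
  hx <- o_ent(px); hxy <- o_ent(P)
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    if (px[i] * px[j] > 0) {
      if (P[i, j] > 0) hxy1 <- hxy1 - P[i, j] * log2(px[i] * px[j])
      hxy2 <- hxy2 - px[i] * px[j] * log2(px[i] * px[j])
    }
  }
  corr <- if (sig2 > 0) (acc - mu^2) / sig2 else 1
  lv <- which(px > 0)
  mcc <- if (length(lv) < 2) 1 else {
    Q <- matrix(0, length(lv), length(lv))
    for (a in seq_along(lv)) for (b in seq_along(lv)) {
      s <- 0
      for (k in seq_along(lv))
        s <- s + P[lv[a], lv[k]] * P[lv[b], lv[k]] / (px[lv[a]] * px[lv[k]])
      Q[a, b] <- s
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(min(ev[2], 1), 0))
  }
  dvar <- 0
  for (k in 0:(ng - 1)) dvar <- dvar + (k - da)^2 * pd[k + 1]
  c(autocorrelation = acc, cluster_prominence = cp, cluster_shade = cs,
    cluster_tendency = ct, contrast = con, correlation = corr,
    difference_average = da, difference_entropy = o_ent(pd),
    difference_variance = dvar, id = idv, idm = idmv, idmn = idmn,
    idn = idn,
    imc1 = if (hx > 0) (hxy - hxy1) / hx else 0,
    imc2 = sqrt(max(1 - exp(-2 * (hxy2 - hxy)), 0)),
    inverse_variance = invvar, joint_average = mu, joint_energy = je,
    joint_entropy = hxy, maximum_probability = maxp, mcc = mcc,
    sum_average = sum((2:(2 * ng)) * ps), sum_entropy = o_ent(ps),
    sum_squares = sig2)
}

oracle_glcm <- function(lab, ng, dirs = oracle_dirs) {
  fs <- list()
  for (d in dirs) {
    P <- oracle_glcm_matrix(lab, ng, d)
    if (!is.null(P)) fs[[length(fs) + 1]] <- oracle_glcm_features(P)
  }
  Reduce(`+`, fs) / length(fs)
}

## ---- GLRLM ---------------------------------------------------------------

oracle_glrlm_matrix <- function(lab, ng, dir) {
  nr <- nrow(lab); nc <- ncol(lab)
  runs_g <- integer(0); runs_l <- integer(0)
  visited <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    ## start of a run: predecessor out of grid, NA, or different label
    if (is.na(lab[r, cc])) next
    pr <- r - dir[1]; pc <- cc - dir[2]
    prev_same <- pr >= 1 && pr <= nr && pc >= 1 && pc <= nc &&
      !is.na(lab[pr, pc]) && lab[pr, pc] == lab[r, cc]
    if (prev_same) next
    len <- 0L; rr <- r; c2 <- cc
    while (rr >= 1 && rr <= nr && c2 >= 1 && c2 <= nc &&
           !is.na(lab[rr, c2]) && lab[rr, c2] == lab[r, cc]) {
      len <- len + 1L; rr <- rr + dir[1]; c2 <- c2 + dir[2]
    }
    runs_g <- c(runs_g, lab[r, cc]); runs_l <- c(runs_l, len)
  }
  if (length(runs_g) == 0) return(NULL)
  P <- matrix(0, ng, max(runs_l))
  for (k in seq_along(runs_g))
    P[runs_g[k], runs_l[k]] <- P[runs_g[k], runs_l[k]] + 1
  P
}

oracle_rlm_features <- function(P, np) {
  ng <- nrow(P); nl <- ncol(P)
  ns <- sum(P)
  sre <- lre <- gln <- rln <- lgl <- hgl <- srl <- srh <- lrl <- lrh <- 0
  for (i in 1:ng) for (j in 1:nl) {
    p <- P[i, j]
    sre <- sre + p / j^2; lre <- lre + p * j^2
    lgl <- lgl + p / i^2; hgl <- hgl + p * i^2
    srl <- srl + p / (i^2 * j^2); srh <- srh + p * i^2 / j^2
    lrl <- lrl + p * j^2 / i^2; lrh <- lrh + p * i^2 * j^2
  }
  for (i in 1:ng) gln <- gln + sum(P[i, ])^2
  for (j in 1:nl) rln <- rln + sum(P[, j])^2
  mi <- mj <- 0
  for (i in 1:ng) for (j in 1:nl) { mi <- mi + i * P[i, j] / ns; mj <- mj + j * P[i, j] / ns }
  gv <- rv <- 0
  for (i in 1:ng) for (j in 1:nl) {
    gv <- gv + (i - mi)^2 * P[i, j] / ns
    rv <- rv + (j - mj)^2 * P[i, j] / ns
  }
  c(sre / ns, lre / ns, gln / ns, gln / ns^2, rln / ns, rln / ns^2,
    ns / np, gv, rv, o_ent(P / ns), lgl / ns, hgl / ns, srl / ns,
    srh / ns, lrl / ns, lrh / ns)
}

oracle_glrlm <- function(lab, ng, dirs = oracle_dirs) {
  np <- sum(!is.na(lab))
  fs <- list()
  for (d in dirs) {
    P <- oracle_glrlm_matrix(lab, ng, d)
    if (!is.null(P)) fs[[length(fs) + 1]] <- oracle_rlm_features(P, np)
  }
  v <- Reduce(`+`, fs) / length(fs)
  names(v) <- c("short_run_emphasis", "long_run_emphasis",
                "gray_level_nonuniformity", "gray_level_nonuniformity_normalized",
                "run_length_nonuniformity", "run_length_nonuniformity_normalized",
                "run_percentage", "gray_level_variance", "run_variance",
                "run_entropy", "low_gray_level_run_emphasis",
                "high_gray_level_run_emphasis", "short_run_low_gray_level_emphasis",
                "short_run_high_gray_level_emphasis",
                "long_run_low_gray_level_emphasis",
                "long_run_high_gray_level_emphasis")
  v
}

## ---- GLSZM ---------------------------------------------------------------

## zones by breadth-first flood fill over the 8-neighbourhood
oracle_glszm <- function(lab, ng) {
  nr <- nrow(lab); nc <- ncol(lab)
  seen <- matrix(FALSE, nr, nc)
  lev <- integer(0); siz <- integer(0)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (is.na(lab[r, cc]) || seen[r, cc]) next
    queue <- list(c(r, cc)); seen[r, cc] <- TRUE; n <- 0L
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]; n <- n + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- q[1] + dr; c2 <- q[2] + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (seen[r2, c2] || is.na(lab[r2, c2])) next
        if (lab[r2, c2] == lab[r, cc]) {
          seen[r2, c2] <- TRUE
          queue[[length(queue) + 1]] <- c(r2, c2)
        }
      }
    }
    lev <- c(lev, lab[r, cc]); siz <- c(siz, n)
  }
  P <- matrix(0, ng, max(siz))
  for (k in seq_along(lev)) P[lev[k], siz[k]] <- P[lev[k], siz[k]] + 1
  v <- oracle_rlm_features(P, sum(!is.na(lab)))
  names(v) <- c("small_area_emphasis", "large_area_emphasis",
                "gray_level_nonuniformity", "gray_level_nonuniformity_normalized",
                "size_zone_nonuniformity", "size_zone_nonuniformity_normalized",
                "zone_percentage", "gray_level_variance", "zone_variance",
                "zone_entropy", "low_gray_level_zone_emphasis",
                "high_gray_level_zone_emphasis", "small_area_low_gray_level_emphasis",
                "small_area_high_gray_level_emphasis",
                "large_area_low_gray_level_emphasis",
                "large_area_high_gray_level_emphasis")
  v
}

## ---- GLDM ----------------------------------------------------------------

oracle_gldm <- function(lab, ng) {
  nr <- nrow(lab); nc <- ncol(lab)
  glev <- integer(0); dep <- integer(0)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (is.na(lab[r, cc])) next
    d <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- cc + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!is.na(lab[r2, c2]) && lab[r2, c2] == lab[r, cc]) d <- d + 1L
    }
    glev <- c(glev, lab[r, cc]); dep <- c(dep, d)
  }
  P <- matrix(0, ng, 9)  # dependence d in 0..8 -> column d + 1
  for (k in seq_along(glev)) P[glev[k], dep[k] + 1] <- P[glev[k], dep[k] + 1] + 1
  ns <- sum(P)
  sde <- lde <- gln <- dn <- lgl <- hgl <- sdl <- sdh <- ldl <- ldh <- 0
  for (i in 1:ng) for (j in 1:9) {
    p <- P[i, j]
    sde <- sde + p / j^2; lde <- lde + p * j^2
    lgl <- lgl + p / i^2; hgl <- hgl + p * i^2
    sdl <- sdl + p / (i^2 * j^2); sdh <- sdh + p * i^2 / j^2
    ldl <- ldl + p * j^2 / i^2; ldh <- ldh + p * i^2 * j^2
  }
  for (i in 1:ng) gln <- gln + sum(P[i, ])^2
  for (j in 1:9) dn <- dn + sum(P[, j])^2
  mi <- mj <- 0
  for (i in 1:ng) for (j in 1:9) { mi <- mi + i * P[i, j] / ns; mj <- mj + j * P[i, j] / ns }
  gv <- dv <- 0
  for (i in 1:ng) for (j in 1:9) {
    gv <- gv + (i - mi)^2 * P[i, j] / ns
    dv <- dv + (j - mj)^2 * P[i, j] / ns
  }
  c(small_dependence_emphasis = sde / ns, large_dependence_emphasis = lde / ns,
    gray_level_nonuniformity = gln / ns, dependence_nonuniformity = dn / ns,
    dependence_nonuniformity_normalized = dn / ns^2,
    gray_level_variance = gv, dependence_variance = dv,
    dependence_entropy = o_ent(P / ns),
    low_gray_level_emphasis = lgl / ns, high_gray_level_emphasis = hgl / ns,
    small_dependence_low_gray_level_emphasis = sdl / ns,
    small_dependence_high_gray_level_emphasis = sdh / ns,
    large_dependence_low_gray_level_emphasis = ldl / ns,
    large_dependence_high_gray_level_emphasis = ldh / ns)
}

## random label image on an irregular mask, as a ready label_image object
random_label_image <- function(seed, nr = 8L, nc = 8L, ng = 4L,
                               mask_frac = 0.85) {
  set.seed(seed)
  lab <- matrix(sample.int(ng, nr * nc, replace = TRUE), nr, nc)
  drop <- runif(nr * nc) > mask_frac
  lab[drop] <- NA_integer_
  if (sum(!is.na(lab)) < 4) lab[1:4] <- sample.int(ng, 4, replace = TRUE)
  structure(list(labels = lab, mask = (!is.na(lab)) * 1L,
                 n_bins = as.integer(ng), raw = matrix(0, nr, nc)),
            class = "label_image")
}

## ---- misc oracles --------------------------------------------------------

## Youden threshold by enumerating ROC vertices (fpr/tpr at each distinct
## score, descending), independent of the package's exhaustive search
oracle_youden_vertex <- function(scores, labels) {
  th <- sort(unique(scores))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  j <- vapply(th, function(t)
    sum(scores >= t & labels == 1) / n1 -
      sum(scores >= t & labels == 0) / n0, 0)
  min(th[j >= max(j) - 1e-12])
}
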