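test_that("discretization bins the in-mask range and handles degenerate input", {
  m <- matrix(1, 2, 2)
  li <- discretize(matrix(c(0, 1, 2, 3), 2), m, 4)
  expect_identical(sort(as.vector(li$labels)), 1:4)
  const <- discretize(matrix(5, 3, 3), matrix(1, 3, 3), 8)
  expect_true(all(const$labels == 1L))
  expect_error(discretize(matrix(1:4, 2), m, 1), "n_bins")
  expect_error(discretize(matrix(1:4, 2), matrix(c(1, 0, 0, 0), 2), 4),
               "too few")
})

test_that("first-order statistics match hand computation", {
  li <- discretize(matrix(c(1, 2, 3, 4), 2), matrix(1, 2, 2), 4)
  f <- firstorder_features(li)
  expect_equal(unname(f["mean"]), 2.5)
  expect_equal(unname(f["range"]), 3)
  expect_equal(unname(f["energy"]), 1 + 4 + 9 + 16)
  expect_equal(unname(f["variance"]), mean((1:4 - 2.5)^2))
  ## uniform histogram over 4 bins -> entropy log2(4)
  expect_equal(unname(f["entropy"]), 2)
  const <- discretize(matrix(7, 3, 3), matrix(1, 3, 3), 8)
  fc <- firstorder_features(const)
  expect_equal(unname(fc[c("entropy", "uniformity", "variance",
                           "skewness", "kurtosis")]), c(0, 1, 0, 0, 0))
})

test_that("shape features recover geometry of squares and disks", {
  sq <- matrix(0L, 14, 14); sq[3:12, 3:12] <- 1L
  f <- shape2d_features(sq, c(1, 1))
  expect_equal(unname(f["pixel_surface"]), 100)
  expect_equal(unname(f["max_diameter"]), sqrt(2) * 9, tolerance = 1e-9)
  expect_true(f["elongation"] > 0 && f["elongation"] <= 1)
  expect_equal(unname(f["elongation"]), 1, tolerance = 1e-9)  # square: isotropic
  ## large disk: sphericity -> 1 within 5%
  disk <- make_disk_mask(71, 30)
  fd <- shape2d_features(disk, c(1, 1))
  expect_equal(unname(fd["sphericity"]), 1, tolerance = 0.05)
  expect_equal(unname(fd["mesh_surface"]), pi * 30^2, tolerance = 0.05)
  expect_equal(unname(fd["spherical_disproportion"]),
               1 / fd[["sphericity"]], tolerance = 1e-12)
  ## physical units: doubling spacing scales area by 4, perimeter by 2
  f2 <- shape2d_features(sq, c(2, 2))
  expect_equal(unname(f2["pixel_surface"]), 400)
  expect_equal(unname(f2["perimeter"]), 2 * unname(f["perimeter"]))
  expect_error(shape2d_features(matrix(c(1, rep(0, 8)), 3), c(1, 1)),
               "too few")
})

test_that("texture features on canonical images match enumeration by hand", {
  mkli <- function(lab, ng) structure(
    list(labels = lab, mask = (!is.na(lab)) * 1L, n_bins = as.integer(ng),
         raw = matrix(0, nrow(lab), ncol(lab))), class = "label_image")
  ## constant region: degenerate texture
  const <- mkli(matrix(1L, 4, 4), 2)
  g <- glcm_features(const)
  expect_equal(unname(g[c("contrast", "joint_entropy", "maximum_probability")]),
               c(0, 0, 1))
  expect_equal(unname(glrlm_features(const)["gray_level_nonuniformity_normalized"]), 1)
  z <- glszm_features(const)
  expect_equal(unname(z["zone_entropy"]), 0)  # one zone of size 16
  ## horizontal pair structure: [[1,1],[2,2]] by rows
  li2 <- mkli(matrix(c(1L, 2L, 1L, 2L), 2), 2)
  g2 <- glcm_features(li2, directions = list(c(0L, 1L)))
  expect_equal(unname(g2["contrast"]), 0)
  expect_equal(unname(g2["joint_energy"]), 0.5)   # P(1,1) = P(2,2) = 0.5
  ## checkerboard: horizontal neighbours always differ by 1
  cb <- mkli(outer(1:4, 1:4, function(i, j) ((i + j) %% 2) + 1L), 2)
  expect_equal(unname(glcm_features(cb, directions = list(c(0L, 1L)))["contrast"]), 1)
  ## all zones of size 1 in a checkerboard (8-connectivity joins diagonals
  ## of the same colour, so use a 4-level tiling instead)
  t4 <- mkli(matrix(c(1L, 3L, 2L, 4L), 2, 2)[rep(1:2, 3), rep(1:2, 3)], 4)
  fz <- glszm_features(t4)
  expect_equal(unname(fz["large_area_emphasis"]), 1)
  ## single run of length 5
  run <- mkli(matrix(1L, 1, 5), 2)
  fr <- glrlm_features(run, directions = list(c(0L, 1L)))
  expect_equal(unname(fr["short_run_emphasis"]), 1 / 25)
  ## alternating labels: run-length non-uniformity equals the run count
  alt <- mkli(matrix(rep(c(1L, 2L), 4), 1), 2)
  fa <- glrlm_features(alt, directions = list(c(0L, 1L)))
  expect_equal(unname(fa["run_length_nonuniformity"]), 8)
  ## two disjoint same-level patches of sizes 3 and 5
  zm <- matrix(NA_integer_, 7, 7)
  zm[2, 2:4] <- 1L; zm[5:6, 6:7] <- 1L; zm[5, 5] <- 1L
  f5 <- glszm_features(mkli(zm, 1))
  expect_equal(unname(f5["small_area_emphasis"]), (1 / 9 + 1 / 25) / 2)
  ## GLDM: constant 3x3 has one pixel with all 8 neighbours dependent
  f6 <- gldm_features(mkli(matrix(1L, 3, 3), 2))
  expect_equal(unname(f6["large_dependence_emphasis"]),
               (4 * 4^2 + 4 * 6^2 + 9^2) / 9)
  ## all-distinct labels: every dependence 0, DNU = pixel count
  f7 <- gldm_features(mkli(matrix(1:9, 3, 3), 9))
  expect_equal(unname(f7["dependence_nonuniformity"]), 9)
  expect_equal(unname(f7["small_dependence_emphasis"]), 1)  # all size 1
})

test_that("texture families agree with brute-force enumeration on random images", {
  for (seed in 1:25) {
    li <- random_label_image(seed, ng = 3L + seed %% 3)
    expect_equal(glcm_features(li), oracle_glcm(li$labels, li$n_bins),
                 tolerance = 1e-9)
    expect_equal(glrlm_features(li), oracle_glrlm(li$labels, li$n_bins),
                 tolerance = 1e-9)
    expect_equal(glszm_features(li), oracle_glszm(li$labels, li$n_bins),
                 tolerance = 1e-9)
    expect_equal(gldm_features(li), oracle_gldm(li$labels, li$n_bins),
                 tolerance = 1e-9)
  }
})

test_that("direction-averaged texture features are invariant to 90-degree rotation", {
  for (seed in 1:10) {
    li <- random_label_image(seed, nr = 7L, nc = 9L)
    rot <- li
    rot$labels <- t(li$labels)[ncol(li$labels):1, , drop = FALSE]
    rot$mask <- t(li$mask)[ncol(li$mask):1, , drop = FALSE]
    expect_equal(glcm_features(li), glcm_features(rot), tolerance = 1e-9)
    expect_equal(glrlm_features(li), glrlm_features(rot), tolerance = 1e-9)
    expect_equal(glszm_features(li), glszm_features(rot), tolerance = 1e-9)
    expect_equal(gldm_features(li), gldm_features(rot), tolerance = 1e-9)
  }
})

test_that("intensity-shift invariance: discretized features fixed, mean shifts exactly", {
  tc <- make_toy_case(20, 20, 5)
  set.seed(9)
  tc$volume$voxels <- tc$volume$voxels + rnorm(length(tc$volume$voxels), 0, 5)
  f1 <- extract_radiomics(tc$volume, tc$mask)
  tc2 <- tc
  tc2$volume$voxels <- tc$volume$voxels + 25
  f2 <- extract_radiomics(tc2$volume, tc2$mask)
  tex <- grep("^(glcm|glrlm|glszm|gldm)_|entropy|uniformity", names(f1))
  expect_equal(f1[tex], f2[tex], tolerance = 1e-9)
  means <- grep("^firstorder_mean_", names(f1))
  expect_equal(unname(f2[means] - f1[means]), rep(25, 4), tolerance = 1e-9)
})

test_that("the default bank has exactly 361 features with the printed family counts", {
  tc <- make_toy_case()
  set.seed(2)
  tc$volume$voxels <- tc$volume$voxels + rnorm(length(tc$volume$voxels), 0, 8)
  f <- extract_radiomics(tc$volume, tc$mask)
  expect_length(f, 361)
  fd <- feature_dictionary()
  expect_identical(names(f), fd$name)
  expect_equal(as.vector(table(fd$family)[c("shape", "firstorder", "glcm",
                                            "glrlm", "glszm", "gldm")]),
               c(9L, 72L, 96L, 64L, 64L, 56L))
  ## one discretization setting: 9 shape + 88
  expect_length(extract_radiomics(tc$volume, tc$mask, bins = 16L), 97)
  ## deterministic
  expect_identical(f, extract_radiomics(tc$volume, tc$mask))
})

test_that("z-score standardization follows the population convention", {
  x <- matrix(c(1, 3, 5, 5), 2, 2,
              dimnames = list(NULL, c("a", "b")))
  expect_warning(st <- zscore_fit(x), "constant")
  expect_equal(unname(st$mean), c(2, 5))
  expect_equal(unname(st$sd), c(1, 0))
  z <- zscore_apply(x, st)
  expect_equal(unname(z[, 1]), c(-1, 1))
  expect_equal(unname(z[, 2]), c(0, 0))     # constant feature -> 0
  expect_equal(unname(zscore_apply(c(a = 3, b = 9), st)[1]), 1)
  ## applying fit-set statistics to the fit set centres every column
  set.seed(3)
  y <- matrix(rnorm(50), 10, 5)
  stz <- zscore_fit(y)
  expect_true(all(abs(colMeans(zscore_apply(y, stz))) < 1e-9))
  expect_error(zscore_fit(y[1, , drop = FALSE]), "insufficient")
})
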