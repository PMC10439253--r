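## Canonical composition of the 361-feature radiomics bank:
## 9 shape-2D features computed once on the largest-tumor slice, plus, for
## each of the four gray-level discretizations (8, 16, 32, 64 bins),
## 18 first-order + 24 GLCM + 16 GLRLM + 16 GLSZM + 14 GLDM features:
## 9 + 4 * 88 = 361.

.default_bins <- c(8L, 16L, 32L, 64L)
.feature_dict_version <- "1.0"

.family_feature_names <- function() {
  li <- discretize(matrix(c(0, 1, 2, 3), 2), matrix(1, 2, 2), 4)
  list(shape = names(shape2d_features(matrix(c(0,1,1,1,1,1,1,1,1), 3))),
       firstorder = names(firstorder_features(li)),
       glcm = names(glcm_features(li)),
       glrlm = names(glrlm_features(li)),
       glszm = names(glszm_features(li)),
       gldm = names(gldm_features(li)))
}

#' The frozen radiomics feature dictionary
#'
#' Enumerates the 361 feature identifiers in canonical order:
#' `shape_<name>` once, then `<family>_<name>_<bins>` for each
#' discretization setting. The dictionary version is recorded in model
#' checkpoints so feature tables and models cannot be mixed across schema
#' changes.
#'
#' @param bins integer vector of gray-level counts (default 8, 16, 32, 64).
#' @return data.frame with columns `name`, `family`, `feature`, `bins`
#'   (`NA` for shape), and attribute `version`.
#' @export
feature_dictionary <- function(bins = .default_bins) {
  fam <- .family_feature_names()
  rows <- data.frame(name = paste0("shape_", fam$shape), family = "shape",
                     feature = fam$shape, bins = NA_integer_,
                     stringsAsFactors = FALSE)
  for (b in bins) {
    for (f in c("firstorder", "glcm", "glrlm", "glszm", "gldm")) {
      rows <- rbind(rows, data.frame(
        name = paste0(f, "_", fam[[f]], "_", b), family = f,
        feature = fam[[f]], bins = as.integer(b), stringsAsFactors = FALSE))
    }
  }
  structure(rows, version = .feature_dict_version)
}

#' Write the feature dictionary as JSON
#'
#' @param path output path.
#' @inheritParams feature_dictionary
#' @export
write_feature_dictionary <- function(path, bins = .default_bins) {
  fd <- feature_dictionary(bins)
  jsonlite::write_json(list(version = attr(fd, "version"), features = fd),
                       path, dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}

#' Extract the radiomics vector for one case
#'
#' Selects the largest-tumor axial slice, computes the 9 shape features
#' once, then the first-order and four texture families at each
#' discretization setting, and assembles the named feature vector in
#' canonical dictionary order (361 features for the default settings).
#' Inputs are expected to be preprocessed (resampled and window
#' normalized).
#'
#' @param vol a [ct_volume] (typically window-normalized).
#' @param mask the aligned [roi_mask].
#' @param bins integer vector of gray-level counts (default 8, 16, 32, 64).
#' @param case_id identifier used in error messages.
#' @return Named numeric vector (length 361 for the defaults).
#' @export
extract_radiomics <- function(vol, mask, bins = .default_bins,
                              case_id = "case") {
  stopifnot(inherits(vol, "ct_volume"), inherits(mask, "roi_mask"))
  if (!identical(dim(vol$voxels), dim(mask$voxels)))
    stop("grid mismatch for case ", case_id)
  out <- tryCatch({
    k <- select_largest_slice(mask)
    sl <- vol$voxels[, , k]
    ms <- mask$voxels[, , k]
    sp <- vol$spacing[1:2]
    shp <- shape2d_features(ms, sp)
    vals <- list(stats::setNames(shp, paste0("shape_", names(shp))))
    for (b in bins) {
      li <- discretize(sl, ms, b)
      for (f in c("firstorder", "glcm", "glrlm", "glszm", "gldm")) {
        v <- switch(f,
                    firstorder = firstorder_features(li, sp),
                    glcm = glcm_features(li),
                    glrlm = glrlm_features(li),
                    glszm = glszm_features(li),
                    gldm = gldm_features(li))
        vals[[length(vals) + 1L]] <- stats::setNames(
          v, paste0(f, "_", names(v), "_", b))
      }
    }
    unlist(vals)
  }, error = function(e) stop("radiomics extraction failed for case '",
                              case_id, "': ", conditionMessage(e),
                              call. = FALSE))
  out
}

#' Radiomics feature table for a cohort
#'
#' @param cases named list; each element has `volume`, `mask` (e.g.
#'   [generate_case()] output or [read_case()] output), already
#'   preprocessed.
#' @inheritParams extract_radiomics
#' @return data.frame: first column `case_id`, then one column per feature.
#' @export
radiomics_table <- function(cases, bins = .default_bins) {
  rows <- lapply(names(cases), function(id)
    extract_radiomics(cases[[id]]$volume, cases[[id]]$mask, bins, id))
  m <- do.call(rbind, rows)
  data.frame(case_id = names(cases), m, stringsAsFactors = FALSE,
             row.names = NULL, check.names = FALSE)
}

#' Fit per-feature z-score standardization statistics
#'
#' Means and standard deviations use the population (denominator n)
#' convention. Zero-variance features are flagged and mapped to 0 by
#' [zscore_apply()].
#'
#' @param x numeric matrix or feature data.frame (cases in rows; a
#'   `case_id` column is dropped), from the training set only.
#' @return An object of class `zscore_stats`.
#' @export
zscore_fit <- function(x) {
  x <- .as_feature_matrix(x)
  if (nrow(x) < 2L) stop("insufficient data: need >= 2 training vectors")
  mu <- colMeans(x)
  sd <- sqrt(colMeans(sweep(x, 2, mu)^2))
  if (any(sd == 0))
    warning(sum(sd == 0), " constant feature(s); standardized values set to 0")
  structure(list(mean = mu, sd = sd, constant = sd == 0),
            class = "zscore_stats")
}

#' Apply z-score standardization
#'
#' @param x matrix/data.frame/vector of raw feature values.
#' @param stats a [zscore_fit()] result.
#' @return Standardized values, same shape as `x`; zero-variance features
#'   map to 0.
#' @export
zscore_apply <- function(x, stats) {
  stopifnot(inherits(stats, "zscore_stats"))
  vec <- is.null(dim(x)) && !is.data.frame(x)
  x <- .as_feature_matrix(x)
  if (ncol(x) != length(stats$mean)) stop("feature dimension mismatch")
  sd <- ifelse(stats$constant, 1, stats$sd)
  z <- sweep(sweep(x, 2, stats$mean), 2, sd, "/")
  z[, stats$constant] <- 0
  if (vec) drop(z) else z
}

.as_feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    if ("case_id" %in% names(x)) x <- x[setdiff(names(x), "case_id")]
    x <- as.matrix(x)
  } else if (is.null(dim(x))) {
    x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  }
  storage.mode(x) <- "double"
  x
}
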