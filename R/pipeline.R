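#' Configuration for an end-to-end pipeline run
#'
#' @param out_dir output directory.
#' @param n number of phantom cases to simulate.
#' @param phantom a [phantom_spec()].
#' @param split either fractions `c(train =, val =, test =)` summing to 1,
#'   or a list of explicit, disjoint case-id character vectors with those
#'   names. Splits by case id emulate by-time cohort splits
#'   deterministically.
#' @param target_spacing analysis voxel spacing in mm.
#' @param window a [window_spec()].
#' @param input_size model input side length.
#' @param bins radiomics discretization settings.
#' @param model an [hrr_config()].
#' @param control a [train_control()].
#' @param seed global seed; every stage derives from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, n = 200L, phantom = phantom_spec(),
                       split = c(train = 0.6, val = 0.15, test = 0.25),
                       target_spacing = c(0.75, 0.75, 2.5),
                       window = window_spec(), input_size = 64L,
                       bins = c(8L, 16L, 32L, 64L),
                       model = hrr_tiny_config(),
                       control = train_control(), seed = 1L) {
  if (is.numeric(split) && abs(sum(split) - 1) > 1e-8)
    stop("split fractions must sum to 1")
  structure(list(out_dir = out_dir, n = as.integer(n), phantom = phantom,
                 split = split, target_spacing = target_spacing,
                 window = window, input_size = as.integer(input_size),
                 bins = as.integer(bins), model = model, control = control,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Preprocess one case to analysis space
#'
#' Resample to the target spacing (trilinear image / nearest mask), window
#' normalize, and build the 3-channel model input.
#'
#' @param volume a [ct_volume]; `mask` the aligned [roi_mask].
#' @param mask a [roi_mask].
#' @param target_spacing analysis spacing in mm.
#' @param window a [window_spec()].
#' @param size model input side length.
#' @param case_id identifier.
#' @return list with `volume` (windowed), `mask`, `input`.
#' @export
preprocess_case <- function(volume, mask, target_spacing = c(0.75, 0.75, 2.5),
                            window = window_spec(), size = 64L,
                            case_id = NA_character_) {
  v <- resample_volume(volume, target_spacing)
  m <- resample_mask(mask, target_spacing)
  inp <- build_input(v, m, window, size, case_id = case_id)
  list(volume = window_normalize(v, window), mask = m, input = inp)
}

## md5 of an R object via its serialization (provenance hashing)
.obj_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

#' Run the full pipeline: simulate, preprocess, extract, train, predict,
#' evaluate, explain
#'
#' Writes, under `config$out_dir`: the phantom cohort (NIfTI + manifest),
#' the radiomics feature table (`features.csv`), per-case scores
#' (`scores.csv`), the evaluation report (`report.json`; the operating
#' threshold is estimated on the training split and applied to the test
#' split), a Grad-CAM heatmap of the first test case (`heatmap.csv`), the
#' trained checkpoint (`checkpoint.rds`) and a run manifest
#' (`manifest.json`) with config/checkpoint hashes from which every
#' reported number can be reproduced. Re-running the same config
#' reproduces the manifest.
#'
#' @param config a [run_config()].
#' @return The manifest, invisibly; elements include `report` and paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  ## simulate
  cohort_dir <- file.path(config$out_dir, "cohort")
  manifest_csv <- stage("simulate",
    write_phantom_cohort(config$phantom, config$n, cohort_dir,
                         seed = config$seed))
  cases <- utils::read.csv(manifest_csv, stringsAsFactors = FALSE)
  ## split
  ids <- cases$case_id
  split <- config$split
  if (is.numeric(split)) {
    set.seed(config$seed + 1L)
    ord <- sample(ids)
    ntr <- round(split[["train"]] * length(ids))
    nva <- round(split[["val"]] * length(ids))
    split <- list(train = sort(ord[seq_len(ntr)]),
                  val = sort(ord[ntr + seq_len(nva)]),
                  test = sort(ord[(ntr + nva + 1L):length(ids)]))
  }
  if (anyDuplicated(c(split$train, split$val, split$test)))
    stop("validation leakage: train/val/test case ids overlap")
  ## preprocess + extract
  pre <- stage("preprocess", {
    out <- lapply(seq_len(nrow(cases)), function(i) {
      rc <- read_case(cases$image_path[i], cases$mask_path[i])
      preprocess_case(rc$volume, rc$mask, config$target_spacing,
                      config$window, config$input_size, cases$case_id[i])
    })
    names(out) <- cases$case_id
    out
  })
  features <- stage("extract", radiomics_table(pre, config$bins))
  utils::write.csv(features, file.path(config$out_dir, "features.csv"),
                   row.names = FALSE)
  ## train on train+val (val used for checkpoint selection)
  fit_ids <- c(split$train, split$val)
  fm <- .as_feature_matrix(features)
  rownames(fm) <- features$case_id
  labels <- stats::setNames(cases$label, cases$case_id)
  fit <- stage("train", hrradnet(
    inputs = lapply(pre[fit_ids], `[[`, "input"),
    radiomics = fm[fit_ids, , drop = FALSE],
    labels = labels[fit_ids],
    config = config$model, control = config$control,
    val_ids = match(split$val, fit_ids), seed = config$seed))
  saveRDS(fit, file.path(config$out_dir, "checkpoint.rds"))
  ## predict all cases
  scores <- stage("predict", predict(
    fit, lapply(pre[ids], `[[`, "input"), fm[ids, , drop = FALSE]))
  sc <- data.frame(case_id = ids, dlrs = scores,
                   label = labels[ids], row.names = NULL)
  utils::write.csv(sc, file.path(config$out_dir, "scores.csv"),
                   row.names = FALSE)
  ## evaluate: cutoff from the training split, report on the test split
  report <- stage("evaluate", {
    tr <- sc[sc$case_id %in% c(split$train, split$val), ]
    te <- sc[sc$case_id %in% split$test, ]
    cut <- youden_cutoff(tr$dlrs, tr$label)
    eval_report(te$dlrs, te$label, threshold = cut$threshold,
                n_boot = 500L, seed = config$seed)
  })
  rep_json <- list(
    auc = report$auc, auc_ci = report$auc_ci,
    threshold = report$cutoff$threshold,
    sensitivity = report$confusion$sensitivity,
    specificity = report$confusion$specificity,
    accuracy = report$confusion$accuracy,
    confusion = report$confusion[c("tp", "fp", "tn", "fn")],
    n_test = report$n)
  jsonlite::write_json(rep_json, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  ## explain the first test case
  stage("explain", {
    id1 <- split$test[1]
    hm <- grad_cam(fit, pre[[id1]]$input, fm[id1, , drop = FALSE])
    utils::write.csv(hm$values, file.path(config$out_dir, "heatmap.csv"),
                     row.names = FALSE)
  })
  manifest <- list(
    config_hash = .obj_hash(config),
    seed = config$seed,
    n_cases = length(ids),
    split = lapply(split, as.character),
    feature_dictionary_version = .feature_dict_version,
    checkpoint_hash = .obj_hash(fit$model$params),
    best_epoch = fit$best_epoch,
    report = rep_json)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$report_object <- report
  manifest$fit <- fit
  invisible(manifest)
}

#' Score a cohort from a saved checkpoint
#'
#' Refuses to run when the checkpoint's feature dictionary version or
#' feature names do not match the feature table.
#'
#' @param checkpoint path to a `checkpoint.rds` written by
#'   [run_pipeline()], or an [hrradnet()] fit.
#' @param inputs named list of `model_input` objects.
#' @param features radiomics feature data.frame (with `case_id` column)
#'   or matrix aligned with `inputs`.
#' @param dict_version feature dictionary version of `features`.
#' @return data.frame with `case_id` and `dlrs`.
#' @export
predict_scores <- function(checkpoint, inputs, features,
                           dict_version = .feature_dict_version) {
  fit <- if (is.character(checkpoint)) readRDS(checkpoint) else checkpoint
  stopifnot(inherits(fit, "hrradnet"))
  if (!identical(fit$dict_version, dict_version))
    stop("feature dictionary version mismatch: model ", fit$dict_version,
         " vs features ", dict_version)
  ids <- if (is.data.frame(features) && "case_id" %in% names(features))
    features$case_id else names(inputs)
  p <- predict(fit, inputs, features)
  data.frame(case_id = ids, dlrs = p, row.names = NULL)
}
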