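## Shared fixtures, built in code. The small trained fit is expensive
## (phantom cohort + a short training run), so it is created lazily once
## per test session and reused across test files.

## internal layer primitives exercised directly by the model tests
se_init <- dlrs:::se_init
se_fwd <- dlrs:::se_fwd
hrr_forward <- dlrs:::hrr_forward
hrr_backward <- dlrs:::hrr_backward

make_disk_mask <- function(n, r, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  d2 <- outer((seq_len(n) - cx)^2, (seq_len(n) - cy)^2, "+")
  (d2 <= r^2) * 1L
}

## tiny aligned volume/mask pair with a bright box tumor
make_toy_case <- function(nx = 12L, ny = 12L, nz = 5L,
                          spacing = c(1, 1, 2.5)) {
  vox <- array(10, c(nx, ny, nz))
  msk <- array(0L, c(nx, ny, nz))
  msk[4:9, 4:9, 2:4] <- 1L
  vox[msk == 1L] <- 80
  list(volume = ct_volume(vox, spacing), mask = roi_mask(msk, spacing))
}

.fixture_env <- new.env(parent = emptyenv())

## phantom cohort of n cases, preprocessed, with features; memoised
fixture_cohort <- function(n = 60L, seed = 101L) {
  key <- paste0("cohort_", n, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    coh <- generate_cohort(phantom_spec(), n, seed = seed)
    pre <- lapply(coh, function(cs)
      preprocess_case(cs$volume, cs$mask, case_id = cs$provenance$case_id))
    feats <- radiomics_table(pre)
    .fixture_env[[key]] <- list(
      cohort = coh, pre = pre, features = feats,
      inputs = lapply(pre, `[[`, "input"),
      fm = dlrs:::.as_feature_matrix(feats),
      labels = vapply(coh, `[[`, 0L, "label"))
  }
  .fixture_env[[key]]
}

## small trained fit on the fixture cohort (8 epochs, tiny preset)
fixture_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    fx <- fixture_cohort()
    .fixture_env$fit <- hrradnet(
      fx$inputs, fx$fm, fx$labels,
      control = train_control(n_epochs = 8L), val_frac = 0.2, seed = 5L)
  }
  .fixture_env$fit
}
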