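#' Focal loss
#'
#' `FL(p) = -alpha * (1 - p)^gamma * log(p)` where `p` is the predicted
#' probability of the case's true class (the network output for label 1,
#' one minus it for label 0). With `gamma = 0`, `alpha = 1` this reduces to
#' cross-entropy. `p` is clamped at `1e-7` for numerical stability of the
#' logarithm; the batch loss used in training is the mean over cases.
#'
#' @param p numeric vector of true-class probabilities in `[0, 1]`.
#' @param alpha balancing weight (> 0), default 1.
#' @param gamma focusing exponent (>= 0), default 2.
#' @return Numeric vector of per-case losses.
#' @export
focal_loss <- function(p, alpha = 1, gamma = 2) {
  if (alpha <= 0 || gamma < 0) stop("need alpha > 0 and gamma >= 0")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("probabilities must lie in [0, 1]")
  pc <- pmax(p, 1e-7)
  -alpha * (1 - pc)^gamma * log(pc)
}

## d(mean focal loss)/dp, elementwise (0 where the clamp is active)
.focal_grad <- function(p, alpha = 1, gamma = 2) {
  pc <- pmax(p, 1e-7)
  g <- alpha * gamma * (1 - pc)^(pmax(gamma - 1, 0)) * log(pc) -
    alpha * (1 - pc)^gamma / pc
  if (gamma == 0) g <- -alpha / pc
  g * (p >= 1e-7) / length(p)
}

#' Training control parameters
#'
#' Defaults follow the published recipe: batch size 16, Adam with initial
#' learning rate 1e-3 halved every 10 epochs, random left/right and
#' anterior/posterior reflections and rotation with angle uniform in
#' (-30, 30) degrees.
#'
#' @param batch_size cases per gradient step.
#' @param initial_lr initial learning rate.
#' @param lr_halving_period epochs between learning-rate halvings.
#' @param n_epochs number of training epochs.
#' @param reflect_lr,reflect_ap enable the two reflections (each applied
#'   independently with probability 0.5).
#' @param rotation_range rotation angle range in degrees.
#' @param alpha,gamma focal-loss parameters.
#' @return An object of class `train_control`.
#' @export
train_control <- function(batch_size = 16L, initial_lr = 1e-3,
                          lr_halving_period = 10L, n_epochs = 30L,
                          reflect_lr = TRUE, reflect_ap = TRUE,
                          rotation_range = c(-30, 30),
                          alpha = 1, gamma = 2) {
  stopifnot(batch_size >= 1, initial_lr > 0, lr_halving_period >= 1,
            n_epochs >= 0, alpha > 0, gamma >= 0)
  if (any(abs(rotation_range) >= 180) || rotation_range[1] > rotation_range[2])
    stop("rotation range must be an ordered pair within (-180, 180)")
  structure(list(batch_size = as.integer(batch_size),
                 initial_lr = initial_lr,
                 lr_halving_period = as.integer(lr_halving_period),
                 n_epochs = as.integer(n_epochs),
                 reflect_lr = isTRUE(reflect_lr),
                 reflect_ap = isTRUE(reflect_ap),
                 rotation_range = rotation_range,
                 alpha = alpha, gamma = gamma),
            class = "train_control")
}

#' Learning rate at a (0-based) epoch
#'
#' `initial_lr * 0.5 ^ floor(e / lr_halving_period)`.
#'
#' @param e epoch index, 0-based.
#' @param control a [train_control()].
#' @export
lr_at_epoch <- function(e, control = train_control()) {
  stopifnot(all(e >= 0))
  control$initial_lr * 0.5^floor(e / control$lr_halving_period)
}

## rotate a 2D matrix by theta degrees about its centre (inverse mapping),
## bilinear or nearest sampling, zero fill outside the source
rotate_image <- function(img, theta_deg, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  h <- nrow(img); w <- ncol(img)
  th <- theta_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  cx <- (h + 1) / 2; cy <- (w + 1) / 2
  gx <- matrix(seq_len(h) - cx, h, w)
  gy <- matrix(rep(seq_len(w) - cy, each = h), h, w)
  sx <- ct * gx + st * gy + cx
  sy <- -st * gx + ct * gy + cy
  ok <- sx >= 1 & sx <= h & sy >= 1 & sy <= w
  out <- matrix(0, h, w)
  if (!any(ok)) return(out)
  if (method == "nearest") {
    i <- pmin(pmax(round(sx[ok]), 1), h)
    j <- pmin(pmax(round(sy[ok]), 1), w)
    out[ok] <- img[cbind(i, j)]
  } else {
    x <- pmin(pmax(sx[ok], 1), h); y <- pmin(pmax(sy[ok], 1), w)
    i0 <- pmin(floor(x), h - 1); j0 <- pmin(floor(y), w - 1)
    fx <- x - i0; fy <- y - j0
    out[ok] <- img[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
      img[cbind(i0 + 1, j0)] * fx * (1 - fy) +
      img[cbind(i0, j0 + 1)] * (1 - fx) * fy +
      img[cbind(i0 + 1, j0 + 1)] * fx * fy
  }
  out
}

#' Randomly augment a model input
#'
#' Applies each enabled reflection independently with probability 0.5 and
#' one rotation with angle uniform in the configured range, consuming the
#' current R random stream. The image channel is rotated with bilinear
#' sampling, the mask channel with nearest-neighbour (staying binary), and
#' the masked channel is recomputed as image x mask so the channel
#' invariants hold.
#'
#' @param input a `model_input`.
#' @param control a [train_control()].
#' @return An augmented `model_input`.
#' @export
augment_input <- function(input, control = train_control()) {
  stopifnot(inherits(input, "model_input"))
  ch1 <- input$channels[, , 1]; ch3 <- input$channels[, , 3]
  if (control$reflect_lr && stats::runif(1) < 0.5) {
    ch1 <- ch1[nrow(ch1):1, , drop = FALSE]
    ch3 <- ch3[nrow(ch3):1, , drop = FALSE]
  }
  if (control$reflect_ap && stats::runif(1) < 0.5) {
    ch1 <- ch1[, ncol(ch1):1, drop = FALSE]
    ch3 <- ch3[, ncol(ch3):1, drop = FALSE]
  }
  th <- stats::runif(1, control$rotation_range[1], control$rotation_range[2])
  if (th != 0) {
    ch1 <- rotate_image(ch1, th, "bilinear")
    ch3 <- rotate_image(ch3, th, "nearest")
  }
  ch1 <- pmin(pmax(ch1, 0), 1)
  out <- input
  out$channels[, , 1] <- ch1
  out$channels[, , 2] <- ch1 * ch3
  out$channels[, , 3] <- ch3
  out
}

## elementwise map over two parallel parameter trees
.tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    for (nm in seq_along(a)) a[[nm]] <- .tree_map2(f, a[[nm]], b[[nm]])
    a
  } else f(a, b)
}

.adam_new <- function(params)
  list(m = rapply(params, function(x) x * 0, how = "replace"),
       v = rapply(params, function(x) x * 0, how = "replace"),
       t = 0L)

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- .tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                        state$v, grads)
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  upd <- .tree_map2(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps),
                    state$m, state$v)
  params <- .tree_map2(`-`, params, upd)
  list(params = params, state = state)
}

#' Fit HR-Rad-Net on a labelled cohort
#'
#' The single model-fitting entry point. Radiomics standardization
#' statistics are fitted on the training split only (never on validation
#' cases), training cases are augmented on the fly, the focal loss is
#' minimised with Adam under the halving learning-rate schedule, and the
#' checkpoint with the best validation AUC is returned. The whole run is a
#' deterministic function of its arguments: one seeded stream drives
#' initialization, shuffling and augmentation.
#'
#' @param inputs list of `model_input` objects (see [build_input()]).
#' @param radiomics matrix or data.frame of raw (unstandardized) radiomics
#'   features, rows aligned with `inputs`.
#' @param labels binary vector (0/1) aligned with `inputs`.
#' @param config an [hrr_config()]; `radiomics_dim` is taken from the data.
#' @param control a [train_control()].
#' @param val_frac fraction of cases held out for checkpoint selection
#'   (ignored when `val_ids` given).
#' @param val_ids explicit indices of validation cases.
#' @param seed integer seed for the run.
#' @return An object of class `hrradnet` with components `model`, `zstats`,
#'   `history` (epoch, loss, lr, val_auc), `best_epoch`, `fitted.values`,
#'   `labels`, `val_ids`, `dict_version`.
#' @export
hrradnet <- function(inputs, radiomics, labels,
                     config = hrr_tiny_config(),
                     control = train_control(),
                     val_frac = 0.2, val_ids = NULL, seed = 1L) {
  stopifnot(inherits(config, "hrr_config"), inherits(control, "train_control"))
  radiomics <- .as_feature_matrix(radiomics)
  n <- length(inputs)
  if (n == 0L || nrow(radiomics) != n || length(labels) != n)
    stop("inputs, radiomics and labels must describe the same cases")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  config$radiomics_dim <- ncol(radiomics)
  model <- hrr_model(config, seed)       # seeds the stream; it continues below
  if (is.null(val_ids)) {
    val_ids <- sort(sample.int(n, max(1L, round(val_frac * n))))
  }
  train_ids <- setdiff(seq_len(n), val_ids)
  if (length(train_ids) < 2L) stop("empty split: too few training cases")
  if (length(unique(labels[train_ids])) < 2L)
    stop("single-class split: training set needs both classes")
  zstats <- zscore_fit(radiomics[train_ids, , drop = FALSE])
  z <- zscore_apply(radiomics, zstats)
  x_val <- stack_inputs(inputs[val_ids])
  z_val <- z[val_ids, , drop = FALSE]
  y_val <- labels[val_ids]
  state <- .adam_new(model$params)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        lr = numeric(0), val_auc = numeric(0))
  best <- list(auc = -Inf, params = model$params, epoch = 0L)
  val_degenerate <- length(unique(y_val)) < 2L
  for (e in seq_len(control$n_epochs)) {
    lr <- lr_at_epoch(e - 1L, control)
    ord <- sample(train_ids)
    ep_loss <- 0; nb <- 0L
    for (b in seq(1L, length(ord), by = control$batch_size)) {
      ids <- ord[b:min(b + control$batch_size - 1L, length(ord))]
      xb <- stack_inputs(lapply(inputs[ids], augment_input, control = control))
      fw <- hrr_forward(model, xb, z[ids, , drop = FALSE], keep_cache = TRUE)
      y <- labels[ids]
      pt <- ifelse(y == 1L, fw$p, 1 - fw$p)
      ep_loss <- ep_loss + mean(focal_loss(pt, control$alpha, control$gamma))
      nb <- nb + 1L
      dz <- .focal_grad(pt, control$alpha, control$gamma) *
        (2 * y - 1) * fw$p * (1 - fw$p)
      bk <- hrr_backward(model, fw$cache, dz)
      st <- .adam_step(model$params, bk$grads, state, lr)
      model$params <- st$params; state <- st$state
    }
    val_auc <- if (val_degenerate) NA_real_ else
      roc_auc(hrr_forward(model, x_val, z_val)$p, y_val)
    history <- rbind(history, data.frame(epoch = e, loss = ep_loss / nb,
                                         lr = lr, val_auc = val_auc))
    if (!val_degenerate && val_auc > best$auc)
      best <- list(auc = val_auc, params = model$params, epoch = e)
  }
  if (control$n_epochs > 0L) {
    if (val_degenerate) {
      warning("validation split has a single class: AUC undefined, ",
              "falling back to the last-epoch checkpoint")
      best <- list(auc = NA_real_, params = model$params,
                   epoch = control$n_epochs)
    }
    model$params <- best$params
  }
  fitted <- hrr_forward(model, stack_inputs(inputs), z)$p
  structure(list(model = model, config = model$config, control = control,
                 zstats = zstats, history = history,
                 best_epoch = best$epoch, best_val_auc = best$auc,
                 fitted.values = fitted, labels = labels,
                 val_ids = val_ids, seed = seed,
                 feature_names = colnames(radiomics),
                 dict_version = .feature_dict_version,
                 call = match.call()),
            class = "hrradnet")
}
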