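#' Network architecture configuration
#'
#' The backbone is a multi-resolution design: a strided convolutional stem,
#' one single-branch stage at the working resolution, then `n_stages - 1`
#' two-branch stages holding a high-resolution stream of `base_width`
#' channels and a half-resolution stream of `2 * base_width` channels, with
#' cross-resolution exchange (1x1 convolution + nearest upsampling upward,
#' strided convolution downward) after every stage. A squeeze-and-excitation
#' gate sits at the end of each resolution branch. Pooled image embeddings
#' are fused with a dense embedding of the standardized radiomics vector in
#' a fully connected head that emits one probability.
#'
#' @param n_stages number of stages (>= 2; stage 1 is single-branch).
#' @param base_width channels of the highest-resolution stream.
#' @param se_reduction squeeze-and-excitation reduction ratio (clamped so
#'   the bottleneck has at least one unit).
#' @param radiomics_dim length of the radiomics vector (361 for the default
#'   feature bank).
#' @param embed_dim width of the radiomics embedding layer.
#' @param hidden_dim width of the fused hidden layer.
#' @param input_size input side length in pixels.
#' @param use_radiomics,use_se ablation switches (see [ablate()]).
#' @return An object of class `hrr_config`.
#' @export
hrr_config <- function(n_stages = 2L, base_width = 8L, se_reduction = 16L,
                       radiomics_dim = 361L, embed_dim = 64L,
                       hidden_dim = 128L, input_size = 64L,
                       use_radiomics = TRUE, use_se = TRUE) {
  stopifnot(n_stages >= 2L, base_width >= 1L, se_reduction >= 1L,
            radiomics_dim >= 1L, embed_dim >= 1L, hidden_dim >= 1L)
  if (input_size %% 8L != 0L)
    stop("input_size must be a multiple of 8 (two stem strides + one branch stride)")
  structure(list(n_stages = as.integer(n_stages),
                 base_width = as.integer(base_width),
                 se_reduction = as.integer(se_reduction),
                 radiomics_dim = as.integer(radiomics_dim),
                 embed_dim = as.integer(embed_dim),
                 hidden_dim = as.integer(hidden_dim),
                 input_size = as.integer(input_size),
                 use_radiomics = isTRUE(use_radiomics),
                 use_se = isTRUE(use_se)),
            class = "hrr_config")
}

#' The tiny CPU preset (2 stages, width 8)
#' @export
hrr_tiny_config <- function(...) hrr_config(n_stages = 2L, base_width = 8L, ...)

#' Initialize network weights deterministically
#'
#' Fan-in-scaled (He) random initialization under an explicit seed; the
#' same seed always yields bitwise-identical weights.
#'
#' @param config an [hrr_config()].
#' @param seed integer seed.
#' @return An object of class `hrr_model`: list with `params`, `config`.
#' @export
hrr_model <- function(config = hrr_tiny_config(), seed = 1L) {
  stopifnot(inherits(config, "hrr_config"))
  set.seed(seed)
  w <- config$base_width; r <- config$se_reduction
  p <- list(
    stem1 = conv_init(3L, 3L, w),
    stem2 = conv_init(3L, w, w),
    stage1 = conv_init(3L, w, w),
    stage1_se = se_init(w, r))
  p$trans <- conv_init(3L, w, 2L * w)
  p$blocks <- lapply(seq_len(config$n_stages - 1L), function(i) list(
    hi = conv_init(3L, w, w), hi_se = se_init(w, r),
    lo = conv_init(3L, 2L * w, 2L * w), lo_se = se_init(2L * w, r),
    up = conv_init(1L, 2L * w, w),
    down = conv_init(3L, w, 2L * w)))
  img_dim <- 3L * w
  fused <- img_dim + if (config$use_radiomics) config$embed_dim else 0L
  p$rad <- dense_init(config$radiomics_dim, config$embed_dim)
  p$hid <- dense_init(img_dim + config$embed_dim, config$hidden_dim)
  p$out <- dense_init(config$hidden_dim, 1L)
  structure(list(params = p, config = config, seed = seed),
            class = "hrr_model")
}

#' Number of trainable parameters
#' @param model an `hrr_model` or `hrradnet` fit.
#' @export
n_parameters <- function(model) {
  cnt <- 0L
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else cnt <<- cnt + length(x)
    invisible(NULL)
  }
  walk(model$params)
  cnt
}

## Forward pass. x_img: (B, S, S, 3); x_rad: (B, radiomics_dim) already
## standardized. Returns list(p = probabilities, cache) when keep_cache.
hrr_forward <- function(model, x_img, x_rad, keep_cache = FALSE) {
  cfg <- model$config; p <- model$params
  B <- dim(x_img)[1]
  if (cfg$use_radiomics) {
    if (is.null(x_rad) || ncol(x_rad) != cfg$radiomics_dim)
      stop("dimension mismatch: radiomics vector must have length ",
           cfg$radiomics_dim)
  }
  se_do <- function(X, par) {
    if (cfg$use_se) se_fwd(X, par)
    else list(Y = X, identity = TRUE, X = X)
  }
  cc <- list()
  cc$c_stem1 <- conv_fwd(x_img, p$stem1, 3L, 2L)
  cc$r_stem1 <- relu_fwd(cc$c_stem1$Y)
  cc$c_stem2 <- conv_fwd(cc$r_stem1$Y, p$stem2, 3L, 2L)
  cc$r_stem2 <- relu_fwd(cc$c_stem2$Y)
  cc$c_s1 <- conv_fwd(cc$r_stem2$Y, p$stage1, 3L, 1L)
  cc$r_s1 <- relu_fwd(cc$c_s1$Y)
  cc$se_s1 <- se_do(cc$r_s1$Y, p$stage1_se)
  h <- cc$se_s1$Y
  cc$c_trans <- conv_fwd(h, p$trans, 3L, 2L)
  cc$r_trans <- relu_fwd(cc$c_trans$Y)
  l <- cc$r_trans$Y
  cc$blocks <- list()
  for (i in seq_along(p$blocks)) {
    bp <- p$blocks[[i]]; bc <- list()
    bc$c_hi <- conv_fwd(h, bp$hi, 3L, 1L)
    bc$r_hi <- relu_fwd(bc$c_hi$Y)
    bc$se_hi <- se_do(bc$r_hi$Y, bp$hi_se)
    bc$c_lo <- conv_fwd(l, bp$lo, 3L, 1L)
    bc$r_lo <- relu_fwd(bc$c_lo$Y)
    bc$se_lo <- se_do(bc$r_lo$Y, bp$lo_se)
    h1 <- bc$se_hi$Y; l1 <- bc$se_lo$Y
    bc$c_up <- conv_fwd(l1, bp$up, 1L, 1L, pad = 0L)
    bc$u_up <- up2_fwd(bc$c_up$Y)
    bc$r_hout <- relu_fwd(h1 + bc$u_up$Y)
    bc$c_down <- conv_fwd(h1, bp$down, 3L, 2L)
    bc$r_lout <- relu_fwd(l1 + bc$c_down$Y)
    h <- bc$r_hout$Y; l <- bc$r_lout$Y
    cc$blocks[[i]] <- bc
  }
  cc$gap_h <- gap_fwd(h)
  cc$gap_l <- gap_fwd(l)
  img_emb <- cbind(cc$gap_h$Y, cc$gap_l$Y)
  if (cfg$use_radiomics) {
    cc$d_rad <- dense_fwd(x_rad, p$rad)
    cc$r_rad <- relu_fwd(cc$d_rad$Y)
    rad_emb <- cc$r_rad$Y
  } else {
    rad_emb <- matrix(0, B, cfg$embed_dim)
  }
  fused <- cbind(img_emb, rad_emb)
  cc$d_hid <- dense_fwd(fused, p$hid)
  cc$r_hid <- relu_fwd(cc$d_hid$Y)
  cc$d_out <- dense_fwd(cc$r_hid$Y, p$out)
  z <- drop(cc$d_out$Y)
  prob <- 1 / (1 + exp(-z))
  cc$z <- z; cc$prob <- prob
  cc$h_final <- h                       # last high-resolution activation
  cc$l_final <- l
  if (keep_cache) list(p = prob, cache = cc) else list(p = prob)
}

## Backward pass from dL/dz (gradient at the pre-sigmoid logit).
## Returns list(grads = same structure as params, d_input, d_hfinal).
hrr_backward <- function(model, cache, dz, guided = FALSE) {
  cfg <- model$config; p <- model$params
  g <- rapply(p, function(x) x * 0, how = "replace")
  se_back <- function(cache_se, par, dY) {
    if (cfg$use_se) se_bwd(cache_se, par, dY, guided)
    else list(dX = dY, dW1 = par$W1 * 0, db1 = par$b1 * 0,
              dW2 = par$W2 * 0, db2 = par$b2 * 0)
  }
  dzm <- matrix(dz, ncol = 1)
  bo <- dense_bwd(cache$d_out, p$out, dzm)
  g$out$W <- bo$dW; g$out$b <- bo$db
  dr_hid <- relu_bwd(cache$r_hid, bo$dX, guided)
  bh <- dense_bwd(cache$d_hid, p$hid, dr_hid)
  g$hid$W <- bh$dW; g$hid$b <- bh$db
  w3 <- 3L * cfg$base_width
  d_img <- bh$dX[, seq_len(w3), drop = FALSE]
  d_rad_emb <- bh$dX[, w3 + seq_len(cfg$embed_dim), drop = FALSE]
  if (cfg$use_radiomics) {
    dr_rad <- relu_bwd(cache$r_rad, d_rad_emb, guided)
    br <- dense_bwd(cache$d_rad, p$rad, dr_rad)
    g$rad$W <- br$dW; g$rad$b <- br$db
  }
  wh <- cfg$base_width
  dh <- gap_bwd(cache$gap_h, d_img[, seq_len(wh), drop = FALSE])
  dl <- gap_bwd(cache$gap_l, d_img[, wh + seq_len(2L * wh), drop = FALSE])
  d_hfinal <- dh                        # grad at the last high-res activation
  d_lfinal <- dl
  for (i in rev(seq_along(p$blocks))) {
    bp <- p$blocks[[i]]; bc <- cache$blocks[[i]]
    dsum_h <- relu_bwd(bc$r_hout, dh, guided)
    dsum_l <- relu_bwd(bc$r_lout, dl, guided)
    ## h_out = relu(h1 + up(conv1x1(l1))); l_out = relu(l1 + conv_down(h1))
    d_h1 <- dsum_h
    d_up_out <- up2_bwd(bc$u_up, dsum_h)
    b_up <- conv_bwd(bc$c_up, bp$up, d_up_out)
    g$blocks[[i]]$up$W <- b_up$dW; g$blocks[[i]]$up$b <- b_up$db
    d_l1 <- dsum_l + b_up$dX
    b_down <- conv_bwd(bc$c_down, bp$down, dsum_l)
    g$blocks[[i]]$down$W <- b_down$dW; g$blocks[[i]]$down$b <- b_down$db
    d_h1 <- d_h1 + b_down$dX
    bs_hi <- se_back(bc$se_hi, bp$hi_se, d_h1)
    g$blocks[[i]]$hi_se <- list(W1 = bs_hi$dW1, b1 = bs_hi$db1,
                                W2 = bs_hi$dW2, b2 = bs_hi$db2)
    dr <- relu_bwd(bc$r_hi, bs_hi$dX, guided)
    b_hi <- conv_bwd(bc$c_hi, bp$hi, dr)
    g$blocks[[i]]$hi$W <- b_hi$dW; g$blocks[[i]]$hi$b <- b_hi$db
    bs_lo <- se_back(bc$se_lo, bp$lo_se, d_l1)
    g$blocks[[i]]$lo_se <- list(W1 = bs_lo$dW1, b1 = bs_lo$db1,
                                W2 = bs_lo$dW2, b2 = bs_lo$db2)
    dr <- relu_bwd(bc$r_lo, bs_lo$dX, guided)
    b_lo <- conv_bwd(bc$c_lo, bp$lo, dr)
    g$blocks[[i]]$lo$W <- b_lo$dW; g$blocks[[i]]$lo$b <- b_lo$db
    dh <- b_hi$dX
    dl <- b_lo$dX
  }
  dr_trans <- relu_bwd(cache$r_trans, dl, guided)
  b_trans <- conv_bwd(cache$c_trans, p$trans, dr_trans)
  g$trans$W <- b_trans$dW; g$trans$b <- b_trans$db
  dh <- dh + b_trans$dX
  bs1 <- se_back(cache$se_s1, p$stage1_se, dh)
  g$stage1_se <- list(W1 = bs1$dW1, b1 = bs1$db1, W2 = bs1$dW2, b2 = bs1$db2)
  dr <- relu_bwd(cache$r_s1, bs1$dX, guided)
  b_s1 <- conv_bwd(cache$c_s1, p$stage1, dr)
  g$stage1$W <- b_s1$dW; g$stage1$b <- b_s1$db
  dr <- relu_bwd(cache$r_stem2, b_s1$dX, guided)
  b_st2 <- conv_bwd(cache$c_stem2, p$stem2, dr)
  g$stem2$W <- b_st2$dW; g$stem2$b <- b_st2$db
  dr <- relu_bwd(cache$r_stem1, b_st2$dX, guided)
  b_st1 <- conv_bwd(cache$c_stem1, p$stem1, dr)
  g$stem1$W <- b_st1$dW; g$stem1$b <- b_st1$db
  list(grads = g, d_input = b_st1$dX, d_hfinal = d_hfinal,
       d_lfinal = d_lfinal)
}

#' Forward scores for a batch
#'
#' @param model an `hrr_model` (or the `model` element of a fit).
#' @param inputs list of `model_input` objects, or a (B, S, S, 3) array.
#' @param radiomics matrix (B x radiomics_dim) of standardized features.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
hrr_score <- function(model, inputs, radiomics = NULL) {
  x <- stack_inputs(inputs)
  if (!is.null(radiomics) && is.null(dim(radiomics)))
    radiomics <- matrix(radiomics, nrow = 1)
  hrr_forward(model, x, radiomics)$p
}

## list of model_input -> (B, S, S, 3) array
stack_inputs <- function(inputs) {
  if (is.array(inputs) && length(dim(inputs)) == 4L) return(inputs)
  if (inherits(inputs, "model_input")) inputs <- list(inputs)
  s <- dim(inputs[[1]]$channels)
  x <- array(0, c(length(inputs), s))
  for (i in seq_along(inputs)) x[i, , , ] <- inputs[[i]]$channels
  x
}

#' Ablated model variants
#'
#' `no_radiomics` removes the radiomics branch (the head sees a zero
#' embedding, so the output depends only on the image); `no_se` fixes all
#' squeeze-and-excitation gates to identity.
#'
#' @param model an `hrr_model` or `hrradnet` fit.
#' @param mode `"no_radiomics"` or `"no_se"`.
#' @return A model of the same class with the ablation applied.
#' @export
ablate <- function(model, mode) {
  if (!mode %in% c("no_radiomics", "no_se"))
    stop("unknown ablation mode: ", mode)
  if (mode == "no_radiomics") model$config$use_radiomics <- FALSE
  else model$config$use_se <- FALSE
  model
}

#' @export
print.hrr_model <- function(x, ...) {
  cat(sprintf("HR-Rad-Net model: %d stages, width %d, %s radiomics, %s SE, %d parameters\n",
              x$config$n_stages, x$config$base_width,
              if (x$config$use_radiomics) "with" else "without",
              if (x$config$use_se) "with" else "without",
              n_parameters(x)))
  invisible(x)
}
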