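#' Grad-CAM heatmap for one case
#'
#' Gradient-weighted class activation mapping: the spatial average of the
#' score gradient per channel of the target convolutional layer weights
#' that channel's activation map; the rectified weighted sum is bilinearly
#' upsampled to the input resolution and max-normalized to `[0, 1]`.
#'
#' @param model an `hrr_model` or [hrradnet()] fit.
#' @param input a `model_input`.
#' @param radiomics standardized radiomics vector (raw if `model` is an
#'   `hrradnet` fit, in which case the stored standardization is applied).
#' @param target_layer `"hi_final"` (last highest-resolution block, the
#'   default) or `"lo_final"`.
#' @return An object of class `heatmap`: list with `values` (input-size
#'   matrix in `[0, 1]`), `raw` (unnormalized map at layer resolution),
#'   `target_layer`, `case_id`.
#' @export
grad_cam <- function(model, input, radiomics = NULL,
                     target_layer = "hi_final") {
  if (inherits(model, "hrradnet")) {
    if (!is.null(radiomics))
      radiomics <- zscore_apply(.as_feature_matrix(radiomics), model$zstats)
    model <- model$model
  }
  if (!target_layer %in% c("hi_final", "lo_final"))
    stop("unknown layer: ", target_layer)
  stopifnot(inherits(input, "model_input"))
  x <- stack_inputs(input)
  if (!is.null(radiomics) && is.null(dim(radiomics)))
    radiomics <- matrix(radiomics, nrow = 1)
  fw <- hrr_forward(model, x, radiomics, keep_cache = TRUE)
  p <- fw$p
  bk <- hrr_backward(model, fw$cache, p * (1 - p))  # d(score)/d(logit)
  A <- if (target_layer == "hi_final") fw$cache$h_final else fw$cache$l_final
  G <- if (target_layer == "hi_final") bk$d_hfinal else bk$d_lfinal
  d <- dim(A)                            # (1, H, W, C)
  w <- apply(G[1, , , , drop = FALSE], 4, mean)
  cam <- matrix(0, d[2], d[3])
  for (cidx in seq_len(d[4])) cam <- cam + w[cidx] * A[1, , , cidx]
  cam <- pmax(cam, 0)
  s <- dim(input$channels)[1]
  up <- bilinear_resize(cam, s, s)
  up <- pmax(up, 0)
  if (max(up) > 0) up <- up / max(up)
  structure(list(values = up, raw = cam, score = p,
                 target_layer = target_layer, case_id = input$case_id),
            class = "heatmap")
}

#' Guided Grad-CAM overlay
#'
#' Backpropagates the score to the input with the guided rule (negative
#' gradients suppressed at every rectifier) and multiplies the resulting
#' fine-grained gradient map on the CT channel elementwise with the
#' upsampled Grad-CAM heatmap.
#'
#' @inheritParams grad_cam
#' @param heatmap optionally a precomputed [grad_cam()] result.
#' @return An object of class `heatmap` whose `values` carry the signed
#'   fine-grained overlay (zero wherever the coarse heatmap is zero).
#' @export
guided_gradcam <- function(model, input, radiomics = NULL,
                           target_layer = "hi_final", heatmap = NULL) {
  if (is.null(heatmap))
    heatmap <- grad_cam(model, input, radiomics, target_layer)
  if (inherits(model, "hrradnet")) {
    if (!is.null(radiomics))
      radiomics <- zscore_apply(.as_feature_matrix(radiomics), model$zstats)
    model <- model$model
  }
  x <- stack_inputs(input)
  if (!is.null(radiomics) && is.null(dim(radiomics)))
    radiomics <- matrix(radiomics, nrow = 1)
  fw <- hrr_forward(model, x, radiomics, keep_cache = TRUE)
  p <- fw$p
  bk <- hrr_backward(model, fw$cache, p * (1 - p), guided = TRUE)
  gbp <- bk$d_input[1, , , 1]            # gradient map on the CT channel
  out <- heatmap
  out$values <- gbp * heatmap$values
  out$raw <- gbp
  out
}

#' @export
print.heatmap <- function(x, ...) {
  cat(sprintf("heatmap '%s' (%s): %d x %d, score %.3f\n",
              x$case_id, x$target_layer, nrow(x$values), ncol(x$values),
              x$score))
  invisible(x)
}

#' Render a heatmap over its CT channel
#'
#' @param x a [grad_cam()] result.
#' @param input the `model_input` the map was computed from (optional;
#'   shown underneath when given).
#' @param ... unused.
#' @export
plot.heatmap <- function(x, input = NULL, ...) {
  v <- x$values
  if (!is.null(input))
    graphics::image(input$channels[, , 1], col = grDevices::gray.colors(64),
                    axes = FALSE, main = sprintf("Grad-CAM (%s)", x$case_id))
  add <- !is.null(input)
  cols <- grDevices::hcl.colors(32, "YlOrRd", rev = TRUE, alpha = 0.5)
  graphics::image(v, col = cols, axes = FALSE, add = add,
                  main = if (add) NULL else sprintf("Grad-CAM (%s)", x$case_id))
  invisible(x)
}
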