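#' @export
print.hrradnet <- function(x, ...) {
  cat("HR-Rad-Net fit\n")
  cat(sprintf("  %d cases (%d train / %d validation), %d epochs, seed %d\n",
              length(x$labels), length(x$labels) - length(x$val_ids),
              length(x$val_ids), x$control$n_epochs, x$seed))
  print(x$model)
  if (is.finite(x$best_val_auc))
    cat(sprintf("  best validation AUC %.3f at epoch %d\n",
                x$best_val_auc, x$best_epoch))
  invisible(x)
}

#' @export
summary.hrradnet <- function(object, ...) {
  val <- object$val_ids
  out <- list(fit = object,
              n = length(object$labels),
              history = object$history,
              val_report = if (length(unique(object$labels[val])) == 2L)
                eval_report(object$fitted.values[val], object$labels[val],
                            n_boot = 500L, seed = object$seed)
              else NULL)
  class(out) <- "summary.hrradnet"
  out
}

#' @export
print.summary.hrradnet <- function(x, ...) {
  print(x$fit)
  if (nrow(x$history) > 0) {
    cat(sprintf("  final training loss %.4f (epoch 1: %.4f)\n",
                x$history$loss[nrow(x$history)], x$history$loss[1]))
  }
  if (!is.null(x$val_report)) {
    cat("Validation-split diagnostics:\n")
    print(x$val_report)
  }
  invisible(x)
}

#' Predict tumor-microenvironment scores for new cases
#'
#' Applies the stored radiomics standardization (fitted on the training
#' split) and runs the network in inference mode.
#'
#' @param object an [hrradnet()] fit.
#' @param inputs list of `model_input` objects (or one `model_input`).
#' @param radiomics raw radiomics matrix/data.frame aligned with `inputs`.
#' @param type `"response"` for probabilities (the deep-learning radiomics
#'   score), `"class"` for 0/1 at `threshold`.
#' @param threshold classification threshold used for `type = "class"`.
#' @param ... unused.
#' @return Numeric score vector, or integer class vector.
#' @export
predict.hrradnet <- function(object, inputs, radiomics,
                             type = c("response", "class"),
                             threshold = 0.5, ...) {
  type <- match.arg(type)
  radiomics <- .as_feature_matrix(radiomics)
  if (!is.null(object$feature_names) && !is.null(colnames(radiomics)) &&
      !identical(colnames(radiomics), object$feature_names))
    stop("feature name mismatch: radiomics columns do not match the ",
         "features the model was trained on")
  z <- zscore_apply(radiomics, object$zstats)
  p <- hrr_score(object$model, inputs, z)
  if (type == "class") as.integer(p >= threshold) else p
}

#' @export
fitted.hrradnet <- function(object, ...) object$fitted.values

#' @export
residuals.hrradnet <- function(object, ...)
  object$labels - object$fitted.values

#' @export
coef.hrradnet <- function(object, ...) {
  unlist(object$model$params)
}

#' Plot the training history of a fit
#'
#' Training loss, learning-rate schedule and validation AUC per epoch.
#'
#' @param x an [hrradnet()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.hrradnet <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0) {
    warning("no training history to plot")
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$loss, type = "b", xlab = "epoch",
                 ylab = "mean focal loss", main = "Training loss", ...)
  graphics::plot(h$epoch, h$val_auc, type = "b", xlab = "epoch",
                 ylab = "validation AUC", main = "Validation AUC",
                 ylim = c(0, 1), ...)
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}
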