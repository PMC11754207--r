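#' Foreground (vegetation) mask
#'
#' A per-pixel logical mask (`TRUE` = foreground) together with the exact
#' foreground pixel fraction.
#'
#' @param mask Logical matrix.
#' @return Object of class `foreground_mask` with elements `mask` and
#'   `fg_fraction` (= true-pixel count / pixel count, exact).
#' @export
foreground_mask <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("`mask` must be a logical matrix")
  structure(list(mask = mask, fg_fraction = sum(mask) / length(mask)),
            class = "foreground_mask")
}

#' @export
print.foreground_mask <- function(x, ...) {
  cat(sprintf("<foreground_mask> %dx%d, %.1f%% foreground\n",
              nrow(x$mask), ncol(x$mask), 100 * x$fg_fraction))
  invisible(x)
}

# Color Index of Vegetation Extraction coefficients (Kataoka et al.)
CIVE_COEF <- c(r = 0.441, g = -0.811, b = 0.385, intercept = 18.78745)

#' Color Index of Vegetation Extraction (CIVE)
#'
#' Per-pixel vegetation index
#' \eqn{CIVE = 0.441 R - 0.811 G + 0.385 B + 18.78745}
#' on 8-bit channel values; lower values indicate more vegetation.
#' Thresholding the index separates soil background from plants in
#' field imagery.
#'
#' @param rgb Numeric array `(U, V, 3)`, channel values in `[0, 255]`.
#' @return Numeric `U x V` matrix of index values.
#' @export
cive_index <- function(rgb) {
  if (!is.array(rgb) || length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stop("`rgb` must be a (U, V, 3) array")
  v <- CIVE_COEF[["r"]] * as.vector(rgb[, , 1]) +
    CIVE_COEF[["g"]] * as.vector(rgb[, , 2]) +
    CIVE_COEF[["b"]] * as.vector(rgb[, , 3]) + CIVE_COEF[["intercept"]]
  matrix(v, nrow = dim(rgb)[1], ncol = dim(rgb)[2])
}

#' Foreground mask from a CIVE map
#'
#' Pixels with CIVE strictly below the threshold are foreground
#' (vegetation).  With `threshold = "otsu"` the cut is chosen by Otsu's
#' method on the index histogram (256 levels over the observed range).
#'
#' @param cive Numeric matrix from [cive_index].
#' @param threshold Numeric cutoff, or `"otsu"`.
#' @return A [foreground_mask].
#' @export
mask_from_cive <- function(cive, threshold = "otsu") {
  if (!is.matrix(cive)) stop("`cive` must be a matrix")
  if (identical(threshold, "otsu")) {
    rng <- range(cive)
    if (rng[1] == rng[2]) {
      threshold <- rng[1]  # constant map: nothing below => empty mask
    } else {
      scaled <- (cive - rng[1]) / (rng[2] - rng[1])
      t01 <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
      threshold <- rng[1] + t01 * (rng[2] - rng[1])
    }
  } else if (!is.numeric(threshold) || length(threshold) != 1L) {
    stop('`threshold` must be a scalar or "otsu"')
  }
  foreground_mask(cive < threshold)
}

#' Foreground mask from the model's background prediction
#'
#' A pixel is foreground when its argmax class differs from the
#' background class.  Argmax ties are broken toward the lowest class id
#' for determinism.
#'
#' @param mean_probs Numeric array `(C, U, V)` of per-pixel class
#'   probabilities (for example the sample mean of a [prob_stack]).
#' @param background_class Background class id in `0..C-1`.
#' @return A [foreground_mask].
#' @export
mask_from_prediction <- function(mean_probs, background_class) {
  if (!is.array(mean_probs) || length(dim(mean_probs)) != 3L)
    stop("`mean_probs` must be a (C, U, V) array")
  Cn <- dim(mean_probs)[1]
  if (!is.numeric(background_class) || length(background_class) != 1L ||
      background_class < 0 || background_class > Cn - 1)
    stop(sprintf("`background_class` must be in 0..%d", Cn - 1))
  pm <- matrix(mean_probs, nrow = Cn)            # (C, U*V)
  argmax <- max.col(t(pm), ties.method = "first") - 1L  # 0-based class ids
  fg <- matrix(argmax != background_class,
               nrow = dim(mean_probs)[2], ncol = dim(mean_probs)[3])
  foreground_mask(fg)
}

#' Mean predictive probabilities of a sample stack
#'
#' Averages a [prob_stack] over its T samples, yielding the `(C, U, V)`
#' mean class-probability array used for background prediction.
#'
#' @param stack A [prob_stack].
#' @return Numeric array `(C, U, V)`.
#' @export
mean_probs <- function(stack) {
  stopifnot(inherits(stack, "prob_stack"))
  s <- stack$samples
  array(colMeans(array(s, dim = c(stack$T, stack$C * stack$U * stack$V))),
        dim = c(stack$C, stack$U, stack$V))
}
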