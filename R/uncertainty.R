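#' Monte-Carlo probability sample stack
#'
#' Container for T stochastic per-pixel class-probability samples of one
#' image, as produced by a learner with stochastic forward passes (for
#' example MC-Dropout).  The tensor is indexed `[t, c, u, v]` where `t` is
#' the sample, `c` the class, and `(u, v)` the pixel (row, column; 0 origin
#' top-left, stored 1-based as usual in R).
#'
#' Every per-pixel, per-sample class distribution must be a valid
#' probability vector: entries non-negative and summing to 1 within `1e-6`.
#'
#' @param samples Numeric 4-d array with dimensions `c(T, C, U, V)`,
#'   `T >= 1` samples, `C >= 2` classes.
#' @return An object of class `prob_stack` with elements `samples`, `T`,
#'   `C`, `U`, `V`.
#' @examples
#' s <- array(1 / 3, dim = c(2, 3, 4, 4))
#' st <- prob_stack(s)
#' st$T; st$C
#' @export
prob_stack <- function(samples) {
  if (!is.array(samples) || length(dim(samples)) != 4L)
    stop("`samples` must be a 4-d array with dims (T, C, U, V)")
  d <- dim(samples)
  if (d[1] < 1L) stop("empty stack: T must be >= 1")
  if (d[2] < 2L) stop("C must be >= 2")
  if (d[3] < 1L || d[4] < 1L) stop("U and V must be >= 1")
  if (any(samples < 0))
    stop("invalid distribution: negative probability entries")
  # sums over the class dimension, per (t, u, v)
  sums <- colSums(aperm(samples, c(2L, 1L, 3L, 4L)),
                  dims = 1L)
  if (max(abs(sums - 1)) > 1e-6)
    stop("invalid distribution: class probabilities must sum to 1 (tol 1e-6)")
  structure(
    list(samples = samples, T = d[1], C = d[2], U = d[3], V = d[4]),
    class = "prob_stack"
  )
}

#' @export
print.prob_stack <- function(x, ...) {
  cat(sprintf("<prob_stack> T=%d samples, C=%d classes, %dx%d pixels\n",
              x$T, x$C, x$U, x$V))
  invisible(x)
}

# x * log(x) with the continuity convention 0 * log 0 = 0
xlogx <- function(x) {
  out <- x * log(x)
  out[x == 0] <- 0
  out
}

#' Shannon entropy of a class-probability vector
#'
#' Computes \eqn{E(P) = -\sum_c P_c \log P_c} in nats, with the convention
#' \eqn{0 \log 0 = 0}.  The result lies in `[0, log(C)]`.
#'
#' @param p Numeric vector of class probabilities (non-negative, summing to
#'   1 within `1e-6`).
#' @return Scalar entropy in nats.
#' @examples
#' class_entropy(rep(1 / 3, 3))   # log(3)
#' class_entropy(c(1, 0, 0))      # 0
#' @export
class_entropy <- function(p) {
  if (!is.numeric(p) || length(p) < 1L)
    stop("`p` must be a non-empty numeric vector")
  if (any(p < 0))
    stop("invalid distribution: negative probability entries")
  if (abs(sum(p) - 1) > 1e-6)
    stop("invalid distribution: probabilities must sum to 1 (tol 1e-6)")
  -sum(xlogx(p))
}

#' Per-pixel BALD uncertainty map
#'
#' Computes the pixel-wise Bayesian Active Learning by Disagreement (BALD)
#' acquisition score from a Monte-Carlo probability sample stack.  With
#' `mode = "sum"` (the default) the score at a pixel is
#' \deqn{U(u,v) = \frac1T \sum_t E(P_{t,\cdot}(u,v)) +
#'   E\Big(\frac1T \sum_t P_{t,\cdot}(u,v)\Big),}
#' the sum of the mean sample-wise entropy and the entropy of the mean
#' sample.  `mode = "mutual_information"` instead returns their difference
#' (entropy of the mean minus mean entropy), the classical BALD mutual
#' information; it is clamped at 0 against roundoff.
#'
#' Entropies are in nats, so `"sum"` values lie in `[0, 2 log C]` and
#' `"mutual_information"` values in `[0, log C]`.
#'
#' @param stack A [prob_stack].
#' @param mode `"sum"` or `"mutual_information"`.
#' @return Numeric `U x V` matrix of non-negative uncertainties.
#' @examples
#' s <- array(0, dim = c(2, 2, 1, 1))
#' s[1, , 1, 1] <- c(1, 0); s[2, , 1, 1] <- c(0, 1)
#' bald_map(prob_stack(s))  # log(2): disagreement with zero sample entropy
#' @export
bald_map <- function(stack, mode = c("sum", "mutual_information")) {
  mode <- match.arg(mode)
  if (!inherits(stack, "prob_stack")) stack <- prob_stack(stack$samples)
  s <- stack$samples
  Tn <- stack$T; Cn <- stack$C; Un <- stack$U; Vn <- stack$V

  # mean over t of per-sample entropies: sum over c, then mean over t
  byc <- aperm(s, c(2L, 1L, 3L, 4L))           # (C, T, U, V)
  ent_tuv <- -colSums(xlogx(byc), dims = 1L)   # (T, U, V)
  mean_ent <- colMeans(array(ent_tuv, dim = c(Tn, Un * Vn)))

  # entropy of the mean sample
  pbar <- colMeans(array(s, dim = c(Tn, Cn * Un * Vn)))  # (C*U*V)
  pbar <- array(pbar, dim = c(Cn, Un * Vn))
  ent_mean <- -colSums(xlogx(pbar))

  vals <- if (mode == "sum") mean_ent + ent_mean
          else pmax(ent_mean - mean_ent, 0)
  matrix(vals, nrow = Un, ncol = Vn)
}

#' Aggregate a pixel uncertainty map to one image score
#'
#' The image score is the mean of the per-pixel uncertainties, optionally
#' restricted to a foreground mask.  A mask covering zero pixels yields a
#' score of 0 (with a warning): an image with no eligible foreground should
#' never outrank one that has some.
#'
#' @param map Numeric matrix of per-pixel uncertainties (from [bald_map]).
#' @param mask Optional logical matrix of the same shape; when given, the
#'   mean is taken over `TRUE` pixels only.
#' @return Scalar image uncertainty.
#' @export
image_uncertainty <- function(map, mask = NULL) {
  if (!is.matrix(map) || !is.numeric(map))
    stop("`map` must be a numeric matrix")
  if (is.null(mask)) return(mean(map))
  if (inherits(mask, "foreground_mask")) mask <- mask$mask
  if (!identical(dim(mask), dim(map)))
    stop("`mask` shape must match `map`")
  n <- sum(mask)
  if (n == 0L) {
    warning("mask covers zero pixels; image uncertainty set to 0")
    return(0)
  }
  sum(map[mask]) / n
}

#' Scale an image uncertainty score by its foreground fraction
#'
#' Multiplies the per-image uncertainty by the fraction of foreground
#' pixels, so that vegetation-sparse images are de-prioritized in ranking
#' even when their few foreground pixels are individually uncertain.
#'
#' @param u_image Scalar image uncertainty (non-negative).
#' @param fg_fraction Foreground pixel fraction in `[0, 1]`.
#' @return `u_image * fg_fraction`.
#' @export
scale_by_foreground <- function(u_image, fg_fraction) {
  if (!is.numeric(fg_fraction) || length(fg_fraction) != 1L ||
      is.na(fg_fraction) || fg_fraction < 0 || fg_fraction > 1)
    stop("`fg_fraction` must be a scalar in [0, 1]")
  u_image * fg_fraction
}
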