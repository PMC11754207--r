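# Synthetic background-dominant field scenes and planted-uncertainty
# probability stacks.  Everything here is a pure function of its
# arguments including the seed, so every downstream module is testable
# without external data.

# class ids used by the synthetic field scenes
SYN_BACKGROUND <- 0L  # soil
SYN_CROP <- 1L
SYN_WEED <- 2L

# mean RGB of each synthetic class.  Soil is far from both plant
# classes; crop and weed are close in hue (as in real field imagery,
# where separating the two vegetation classes is the hard part of
# labeling).  Crop blobs are a uniform cultivar (narrow per-blob
# brightness range) while weed blobs are heterogeneous (wide per-blob
# brightness range), so a classifier must see many labeled weed blobs
# before its decision boundary settles — giving the learning curve the
# sample-size dependence the under-represented class has in real data.
SYN_COLORS <- rbind(background = c(102, 82, 62),
                    crop = c(60, 140, 65),
                    weed = c(112, 148, 58))
SYN_PIXEL_SD <- 15
SYN_IMAGE_SD <- 6                      # per-image illumination shift
SYN_BLOB_RANGE <- rbind(crop = c(0.92, 1.08),  # per-blob brightness factor
                        weed = c(0.65, 1.45))

# paint one elliptical blob of class `cls` onto label (background pixels
# only), stopping exactly at `budget` newly painted pixels; returns the
# painted linear indices
paint_ellipse <- function(label, cls, budget) {
  U <- nrow(label); V <- ncol(label)
  cy <- runif(1, 1, U); cx <- runif(1, 1, V)
  # weed plants are fewer and larger than crop plants
  ax_rng <- if (cls == SYN_WEED) c(4, 11) else c(2.5, 8)
  ax <- runif(1, ax_rng[1], ax_rng[2]); bx <- runif(1, ax_rng[1], ax_rng[2])
  th <- runif(1, 0, pi)
  r0 <- max(1, floor(cy - 12)); r1 <- min(U, ceiling(cy + 12))
  c0 <- max(1, floor(cx - 12)); c1 <- min(V, ceiling(cx + 12))
  rr <- rep(r0:r1, times = c1 - c0 + 1L)
  cc <- rep(c0:c1, each = r1 - r0 + 1L)
  dy <- rr - cy; dx <- cc - cx
  xr <- dx * cos(th) + dy * sin(th)
  yr <- -dx * sin(th) + dy * cos(th)
  d <- (xr / ax)^2 + (yr / bx)^2
  inside <- d <= 1
  idx <- (cc[inside] - 1L) * U + rr[inside]
  dd <- d[inside]
  bg <- label[idx] == SYN_BACKGROUND
  idx <- idx[bg]; dd <- dd[bg]
  if (length(idx) > budget)  # trim farthest pixels so the blob stays compact
    idx <- idx[order(dd)][seq_len(budget)]
  idx
}

make_scene <- function(size, crop_target, weed_target) {
  N <- size * size
  label <- matrix(SYN_BACKGROUND, size, size)
  base <- matrix(rep(SYN_COLORS[1, ], each = N), N, 3L)  # soil everywhere
  for (spec in list(list(SYN_CROP, crop_target),
                    list(SYN_WEED, weed_target))) {
    cls <- spec[[1]]; target <- spec[[2]]
    rng <- SYN_BLOB_RANGE[cls, ]
    painted <- 0L; tries <- 0L
    while (painted < target && tries < 400L) {
      idx <- paint_ellipse(label, cls, target - painted)
      label[idx] <- cls
      f <- runif(1, rng[1], rng[2])    # per-blob brightness
      base[idx, ] <- rep(SYN_COLORS[cls + 1L, ] * f, each = length(idx))
      painted <- painted + length(idx)
      tries <- tries + 1L
    }
  }
  # render RGB: per-pixel gaussian noise + per-image illumination shift
  img <- array(0, dim = c(size, size, 3L))
  for (ch in 1:3) {
    img[, , ch] <- pmin(pmax(matrix(base[, ch] + rnorm(N, 0, SYN_PIXEL_SD) +
                                      rnorm(1, 0, SYN_IMAGE_SD),
                                    size, size), 0), 255)
  }
  fr <- tabulate(as.vector(label) + 1L, nbins = 3L) / N
  structure(list(image = img, label = label,
                 class_fractions = c(background = fr[1], crop = fr[2],
                                     weed = fr[3])),
            class = "synthetic_scene")
}

#' Generate a synthetic background-dominant field dataset
#'
#' Produces seeded RGB tiles with integer class labels emulating the
#' statistics of UAV field imagery: soil background dominates (~85% of
#' pixels), crop blobs cover ~13% of pixels and appear in most images,
#' weed blobs cover ~2% of pixels and appear in few, and some tiles are
#' entirely vegetation-free.  Plants are elliptical blobs in
#' distinguishable (but noisy, overlapping) colors; classes are
#' background = 0, crop = 1, weed = 2.
#'
#' Per image, a class is present with probability `1 - p_empty_*`; given
#' presence its pixel-count target is drawn around the conditional mean
#' so the global class fractions land within a few percentage points of
#' the requested ones.
#'
#' @param n_images Number of tiles.
#' @param size Tile side in pixels (square tiles; default 64).
#' @param bg_fraction,crop_fraction,weed_fraction Target global pixel
#'   fractions (must sum to 1).
#' @param p_empty_weed Probability a tile has no weed (default 0.78,
#'   i.e. weed present in 22% of tiles).
#' @param p_empty_crop Probability a tile has no crop (default 0.13).
#' @param seed Integer seed; same seed gives bit-identical output.
#' @return List of `synthetic_scene` objects, each with `image`
#'   (`size x size x 3`, values in `[0, 255]`), `label` (integer matrix)
#'   and `class_fractions`.
#' @export
make_field_dataset <- function(n_images, size = 64L, bg_fraction = 0.85,
                               crop_fraction = 0.13, weed_fraction = 0.02,
                               p_empty_weed = 0.78, p_empty_crop = 0.13,
                               seed = 1L) {
  fr <- c(bg_fraction, crop_fraction, weed_fraction)
  if (any(fr < 0) || any(fr > 1) || abs(sum(fr) - 1) > 1e-9)
    stop("class fractions must lie in [0, 1] and sum to 1")
  if (p_empty_weed < 0 || p_empty_weed > 1 || p_empty_crop < 0 ||
      p_empty_crop > 1)
    stop("p_empty_* must lie in [0, 1]")
  if (weed_fraction > 0 && p_empty_weed == 1)
    stop("weed_fraction > 0 is infeasible when every tile is weed-free")
  if (crop_fraction > 0 && p_empty_crop == 1)
    stop("crop_fraction > 0 is infeasible when every tile is crop-free")
  N <- size * size
  crop_mean <- if (p_empty_crop < 1) crop_fraction / (1 - p_empty_crop) else 0
  weed_mean <- if (p_empty_weed < 1) weed_fraction / (1 - p_empty_weed) else 0
  if (crop_mean + weed_mean > 0.9)
    stop("infeasible fractions: conditional plant cover would exceed 90%")
  withr::with_seed(seed, {
    lapply(seq_len(n_images), function(i) {
      has_crop <- crop_fraction > 0 && runif(1) >= p_empty_crop
      has_weed <- weed_fraction > 0 && runif(1) >= p_empty_weed
      ct <- if (has_crop) round(N * crop_mean * runif(1, 0.5, 1.5)) else 0L
      wt <- if (has_weed) round(N * weed_mean * runif(1, 0.5, 1.5)) else 0L
      make_scene(size, ct, wt)
    })
  })
}

#' Synthetic Monte-Carlo probability stack with planted uncertainty
#'
#' Builds a [prob_stack] for a scene in which the samples are
#' near-deterministic (peaked on the true class, with `low_noise`
#' jitter) everywhere except inside the planted superpixels, where each
#' Monte-Carlo sample commits to a randomly drawn class
#' (`high_noise` = mixing weight of the disagreement component), so the
#' BALD map is provably higher inside planted regions.  With
#' `high_noise = 0` the planted regions are indistinguishable from the
#' rest.
#'
#' @param scene A `synthetic_scene` from [make_field_dataset].
#' @param spmap [superpixel_map] of the scene (defines region geometry).
#' @param planted_ids Segment ids to plant high uncertainty in.
#' @param T Number of Monte-Carlo samples (>= 2).
#' @param high_noise Disagreement weight in `[0, 1]` for planted regions.
#' @param low_noise Jitter amplitude outside (and inside) regions.
#' @param n_classes Number of classes (default 3).
#' @param seed Integer seed.
#' @return A [prob_stack].
#' @export
make_prob_stack <- function(scene, spmap, planted_ids, T = 8L,
                            high_noise = 1, low_noise = 0.01,
                            n_classes = 3L, seed = 1L) {
  stopifnot(inherits(spmap, "superpixel_map"))
  if (T < 2L) stop("`T` must be >= 2")
  if (high_noise < 0 || high_noise > 1 || low_noise < 0)
    stop("noise parameters out of range")
  planted_ids <- as.integer(planted_ids)
  if (length(planted_ids) &&
      (any(planted_ids < 1L) || any(planted_ids > spmap$m)))
    stop("unknown planted segment id")
  U <- nrow(scene$label); V <- ncol(scene$label); N <- U * V
  Cn <- as.integer(n_classes)
  truev <- as.vector(scene$label)
  oneh <- matrix(0, Cn, N)
  oneh[cbind(truev + 1L, seq_len(N))] <- 1
  a <- high_noise
  withr::with_seed(seed, {
    arr <- low_noise * array(runif(T * Cn * N), dim = c(T, Cn, N))
    arr <- arr + aperm(array(oneh, dim = c(Cn, N, T)), c(3L, 1L, 2L))
    labv <- as.vector(spmap$labels)
    for (s in planted_ids) {
      pix <- which(labv == s)
      if (a > 0) {
        d <- sample.int(Cn, T, replace = TRUE)  # per-sample committed class
        for (t in seq_len(T)) {
          m <- (1 - a) * oneh[, pix, drop = FALSE] +
            low_noise * matrix(runif(Cn * length(pix)), Cn)
          m[d[t], ] <- m[d[t], ] + a
          arr[t, , pix] <- m
        }
      }
    }
    # normalize each (t, pixel) distribution
    flat <- matrix(aperm(arr, c(2L, 1L, 3L)), nrow = Cn)
    flat <- sweep(flat, 2L, colSums(flat), "/")
    arr <- aperm(array(flat, dim = c(Cn, T, N)), c(2L, 1L, 3L))
    prob_stack(array(arr, dim = c(T, Cn, U, V)))
  })
}

# 3x3 box mean with replicated borders
box3 <- function(m) {
  U <- nrow(m); V <- ncol(m)
  p <- m[c(1, 1:U, U), c(1, 1:V, V)]
  acc <- matrix(0, U, V)
  for (dr in 0:2) for (dc in 0:2)
    acc <- acc + p[dr + 1:U, dc + 1:V]
  acc / 9
}

learner_features <- function(image) {
  f <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
             as.vector(image[, , 3]),
             as.vector(box3(image[, , 1])), as.vector(box3(image[, , 2])),
             as.vector(box3(image[, , 3]))) / 255
  colnames(f) <- c("r", "g", "b", "mr", "mg", "mb")
  f
}

softmax_rows <- function(L) {
  L <- L - apply(L, 1L, max)
  E <- exp(L)
  E / rowSums(E)
}

# logits from a multinomial-logistic coefficient matrix W ((k-1) x (p+1));
# first observed class is the reference with logit 0
mlogit_probs <- function(W, X) {
  L <- cbind(0, cbind(1, X) %*% t(W))
  softmax_rows(L)
}

#' Tiny per-pixel learner for CPU-scale active learning experiments
#'
#' A learner-contract object: multinomial logistic regression over six
#' local color features (RGB and their 3x3 neighborhood means), trained
#' on a seeded subsample of the non-ignored labeled pixels.  Monte-Carlo
#' probability samples are drawn by input-feature dropout (each sample
#' randomly silences half the features, inverted-dropout scaled), the
#' same mechanism MC-Dropout uses to expose model disagreement: pixels
#' whose class is pinned down by any feature subset stay certain, pixels
#' whose evidence lives in few features disagree across samples.
#'
#' The contract (shared by any learner usable with [al_step]):
#' \describe{
#'   \item{`fit(images, labels, prev, ignore_value, seed)`}{trains on
#'     partial labels, skipping `ignore_value` pixels; `prev` is the
#'     previous step's model for warm-starting; returns a model object.}
#'   \item{`predict_probs(model, image)`}{`(C, U, V)` mean class
#'     probabilities; near-uniform when `model` is `NULL` (untrained).}
#'   \item{`predict_classes(model, image)`}{argmax class-id matrix
#'     (0-based, ties toward the lowest id).}
#'   \item{`sample_probabilities(model, image, T, seed)`}{a
#'     [prob_stack] of T stochastic samples.}
#' }
#'
#' @param n_classes Number of classes (default 3).
#' @param max_pixels Training subsample cap per fit (default 20000).
#' @param dropout Feature dropout rate for sampling (default 0.5).
#' @return A learner-contract list of class `al_learner`.
#' @export
tiny_learner <- function(n_classes = 3L, max_pixels = 20000L,
                         dropout = 0.5) {
  n_classes <- as.integer(n_classes)

  fit <- function(images, labels, prev = NULL, ignore_value = 255L,
                  seed = 1L) {
    xs <- list(); ys <- list()
    for (i in seq_along(images)) {
      keep <- as.vector(labels[[i]]) != ignore_value
      if (!any(keep)) next
      xs[[length(xs) + 1L]] <- learner_features(images[[i]])[keep, ,
                                                             drop = FALSE]
      ys[[length(ys) + 1L]] <- as.vector(labels[[i]])[keep]
    }
    if (!length(xs)) stop("no labeled pixels to train on")
    X <- do.call(rbind, xs); y <- unlist(ys)
    withr::with_seed(seed, {
      if (nrow(X) > max_pixels) {
        pick <- sample.int(nrow(X), max_pixels)
        X <- X[pick, , drop = FALSE]; y <- y[pick]
      }
      classes <- sort(unique(y))
      if (length(classes) == 1L)
        return(list(kind = "constant", classes = classes,
                    n_classes = n_classes))
      d <- data.frame(y = factor(y, levels = classes), X)
      fit0 <- nnet::multinom(y ~ ., data = d, trace = FALSE,
                             maxit = 200, decay = 1e-4)
      W <- coef(fit0)
      if (is.null(dim(W))) W <- matrix(W, nrow = 1L,
                                       dimnames = list(NULL, names(W)))
      list(kind = "mlogit", W = W, classes = classes,
           n_classes = n_classes)
    })
  }

  embed_probs <- function(P, classes) {
    # observed-class probabilities -> full C columns with a tiny floor
    full <- matrix(1e-6, nrow(P), n_classes)
    full[, classes + 1L] <- full[, classes + 1L] + P
    full / rowSums(full)
  }

  probs_matrix <- function(model, X) {
    if (is.null(model))
      return(matrix(1 / n_classes, nrow(X), n_classes))
    if (model$kind == "constant") {
      P <- matrix(1, nrow(X), 1L)
      return(embed_probs(P, model$classes))
    }
    embed_probs(mlogit_probs(model$W, X), model$classes)
  }

  predict_probs <- function(model, image) {
    X <- learner_features(image)
    P <- probs_matrix(model, X)
    array(t(P), dim = c(n_classes, nrow(image), ncol(image)))
  }

  predict_classes <- function(model, image) {
    P <- probs_matrix(model, learner_features(image))
    matrix(max.col(P, ties.method = "first") - 1L,
           nrow(image), ncol(image))
  }

  sample_probabilities <- function(model, image, T, seed = 1L) {
    X <- learner_features(image)
    N <- nrow(X); p <- ncol(X)
    withr::with_seed(seed, {
      samples <- array(0, dim = c(T, n_classes, N))
      for (t in seq_len(T)) {
        if (is.null(model) || model$kind == "constant") {
          P <- probs_matrix(model, X)
          eps <- matrix(runif(N * n_classes, 0, 0.02), N)
          P <- (P + eps) / rowSums(P + eps)
        } else {
          keep <- runif(p) >= dropout
          if (!any(keep)) keep[sample.int(p, 1L)] <- TRUE
          Xd <- X
          Xd[, !keep] <- 0
          Xd[, keep] <- Xd[, keep] / (1 - dropout)
          P <- embed_probs(mlogit_probs(model$W, Xd), model$classes)
        }
        samples[t, , ] <- t(P)
      }
      prob_stack(array(samples,
                       dim = c(T, n_classes, nrow(image), ncol(image))))
    })
  }

  structure(list(fit = fit, predict_probs = predict_probs,
                 predict_classes = predict_classes,
                 sample_probabilities = sample_probabilities,
                 n_classes = n_classes),
            class = "al_learner")
}
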