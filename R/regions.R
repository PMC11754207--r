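#' Superpixel segmentation map
#'
#' Integer segment label per pixel plus the realized segment count `m`.
#' Ids form the contiguous range `1..m` and every id is occupied by at
#' least one pixel.
#'
#' @param labels Integer matrix of segment ids.
#' @return Object of class `superpixel_map` with elements `labels` and `m`.
#' @export
superpixel_map <- function(labels) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  storage.mode(labels) <- "integer"
  ids <- sort(unique(as.vector(labels)))
  m <- length(ids)
  if (!identical(ids, seq_len(m)))
    labels <- matrix(match(labels, ids), nrow = nrow(labels))
  structure(list(labels = labels, m = m), class = "superpixel_map")
}

#' @export
print.superpixel_map <- function(x, ...) {
  cat(sprintf("<superpixel_map> %d segments over %dx%d pixels\n",
              x$m, nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

# sRGB [0,255] image array (U, V, 3) -> CIELab matrix (U*V, 3)
rgb_to_lab <- function(image) {
  grDevices::convertColor(matrix(as.vector(image) / 255, ncol = 3L),
                          from = "sRGB", to = "Lab")
}

#' SLIC superpixel segmentation
#'
#' Segments an RGB image into approximately `n_segments` compact
#' superpixels with the SLIC algorithm: k-means-style clustering in the
#' joint CIELab color + pixel coordinate space, with each cluster center
#' only competing for pixels within a `2S x 2S` window (`S` the grid
#' step), so complexity is linear in the pixel count.  The `compactness`
#' parameter trades color homogeneity against spatial regularity exactly
#' as in the original formulation: the combined distance is
#' \eqn{\sqrt{d_{lab}^2 + (d_{xy}/S)^2 m^2}} with `m = compactness`.
#'
#' The realized segment count can differ slightly from `n_segments`
#' (centers are seeded on a regular grid and empty clusters are dropped);
#' labels are always relabeled to the contiguous range `1..m`.  The
#' procedure is deterministic for fixed inputs.
#'
#' @param image Numeric array `(U, V, 3)`, channel values in `[0, 255]`.
#' @param n_segments Target number of superpixels (>= 1, <= pixel count).
#' @param compactness Spatial regularity weight; default 10.
#' @param max_iter Number of assignment/update sweeps; default 10.
#' @return A [superpixel_map].
#' @export
slic_segment <- function(image, n_segments, compactness = 10, max_iter = 10L) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("`image` must be a (U, V, 3) RGB array")
  U <- dim(image)[1]; V <- dim(image)[2]; N <- U * V
  if (n_segments < 1L) stop("`n_segments` must be >= 1")
  if (n_segments > N)
    stop(sprintf("`n_segments` (%d) exceeds pixel count (%d)", n_segments, N))
  if (n_segments == 1L)
    return(superpixel_map(matrix(1L, U, V)))

  lab <- rgb_to_lab(image)                      # (N, 3), column-major over (u, v)
  S <- sqrt(N / n_segments)
  # seed centers on an ny x nx grid with ny * nx ~ n_segments
  ny <- max(1L, as.integer(round(sqrt(n_segments * U / V))))
  nx <- max(1L, as.integer(ceiling(n_segments / ny)))
  gr <- (seq_len(ny) - 0.5) * U / ny
  gc <- (seq_len(nx) - 0.5) * V / nx
  cy <- rep(gr, times = nx)
  cx <- rep(gc, each = ny)
  k <- length(cy)
  idx0 <- (pmin(round(cx), V) - 1) * U + pmin(round(cy), U)  # linear index
  centers <- cbind(lab[idx0, , drop = FALSE], cy, cx)        # (k, 5)

  rowv <- rep(seq_len(U), times = V)
  colv <- rep(seq_len(V), each = U)
  w2 <- (compactness / S)^2

  labels <- integer(N)
  for (iter in seq_len(max_iter)) {
    best <- rep(Inf, N)
    labels[] <- 0L
    for (j in seq_len(k)) {
      r0 <- max(1L, floor(centers[j, 4] - 2 * S))
      r1 <- min(U, ceiling(centers[j, 4] + 2 * S))
      c0 <- max(1L, floor(centers[j, 5] - 2 * S))
      c1 <- min(V, ceiling(centers[j, 5] + 2 * S))
      rr <- r0:r1; cc <- c0:c1
      win <- as.vector(outer(rr, (cc - 1L) * U, `+`))
      d <- (lab[win, 1] - centers[j, 1])^2 +
           (lab[win, 2] - centers[j, 2])^2 +
           (lab[win, 3] - centers[j, 3])^2 +
           ((rowv[win] - centers[j, 4])^2 +
            (colv[win] - centers[j, 5])^2) * w2
      upd <- d < best[win]
      if (any(upd)) {
        wupd <- win[upd]
        best[wupd] <- d[upd]
        labels[wupd] <- j
      }
    }
    # pixels outside every window (possible on extreme aspect ratios):
    # assign to nearest center by position
    orphan <- labels == 0L
    if (any(orphan)) {
      oi <- which(orphan)
      dpos <- outer(rowv[oi], centers[, 4], `-`)^2 +
              outer(colv[oi], centers[, 5], `-`)^2
      labels[oi] <- max.col(-dpos, ties.method = "first")
    }
    # update centers as the mean Lab + position of member pixels
    cnt <- tabulate(labels, nbins = k)
    keep <- cnt > 0L
    for (col in 1:3)
      centers[keep, col] <- rowsum(lab[, col], labels)[, 1] / cnt[keep]
    centers[keep, 4] <- rowsum(rowv, labels)[, 1] / cnt[keep]
    centers[keep, 5] <- rowsum(colv, labels)[, 1] / cnt[keep]
  }
  superpixel_map(matrix(labels, nrow = U, ncol = V))
}

#' Per-superpixel mean uncertainty scores
#'
#' Aggregates a pixel uncertainty map over a superpixel map: each
#' segment's score is the mean uncertainty of its member pixels.  When a
#' foreground mask is supplied, only foreground member pixels enter the
#' mean; a segment with no foreground pixel scores 0 and is flagged
#' background (it is excluded from querying and from budget totals in
#' foreground mode).
#'
#' @param map Numeric uncertainty matrix (same shape as the segmentation).
#' @param spmap A [superpixel_map].
#' @param fg_mask Optional logical matrix or [foreground_mask].
#' @return A `superpixel_scores` data.frame with columns `id`, `score`,
#'   `n_pixels`, and `foreground` (logical; `FALSE` only for segments with
#'   zero foreground pixels under `fg_mask`).
#' @export
aggregate_scores <- function(map, spmap, fg_mask = NULL) {
  stopifnot(inherits(spmap, "superpixel_map"))
  if (!identical(dim(map), dim(spmap$labels)))
    stop("uncertainty map shape must match segmentation shape")
  m <- spmap$m
  lab <- as.vector(spmap$labels)
  if (is.null(fg_mask)) {
    sel <- rep(TRUE, length(lab))
  } else {
    if (inherits(fg_mask, "foreground_mask")) fg_mask <- fg_mask$mask
    if (!identical(dim(fg_mask), dim(map)))
      stop("`fg_mask` shape must match `map`")
    sel <- as.vector(fg_mask)
  }
  cnt <- tabulate(lab[sel], nbins = m)
  sums <- numeric(m)
  if (any(sel)) {
    rs <- rowsum(as.vector(map)[sel], lab[sel])
    sums[as.integer(rownames(rs))] <- rs[, 1]
  }
  score <- ifelse(cnt > 0L, sums / pmax(cnt, 1L), 0)
  out <- data.frame(id = seq_len(m), score = score,
                    n_pixels = tabulate(lab, nbins = m),
                    foreground = cnt > 0L)
  class(out) <- c("superpixel_scores", class(out))
  out
}

#' Two-class Jenks natural breaks split
#'
#' Splits a set of scalar values into a high and a low class at the
#' contiguous split of the sorted values that minimizes the total
#' within-class sum of squared deviations — the two-class case of Jenks
#' natural breaks, solved exactly by scanning all `n - 1` split points
#' with prefix sums.
#'
#' Conventions for degenerate input: a single value is classed high (an
#' image selected for querying yields at least one region); all-equal
#' values yield an empty high class (equal uncertainty carries no
#' ranking signal, so nothing is queried).  Values exactly equal to the
#' break (the low class maximum) stay low.
#'
#' @param values Numeric vector (length >= 1).
#' @return List with `high_ids` and `low_ids` (integer indices into
#'   `values`) and `break_value` (the low-class maximum; high values are
#'   strictly above it).
#' @examples
#' jenks_split_2(c(1, 1, 1, 10, 10))$high_ids   # 4 5
#' @export
jenks_split_2 <- function(values) {
  n <- length(values)
  if (n == 0L) stop("`values` must be non-empty")
  if (!is.numeric(values) || anyNA(values)) stop("`values` must be numeric, no NA")
  if (n == 1L)
    return(list(high_ids = 1L, low_ids = integer(0), break_value = -Inf))
  ord <- order(values)
  x <- values[ord]
  if (x[1] == x[n])  # zero variance: no informative break
    return(list(high_ids = integer(0), low_ids = seq_len(n),
                break_value = x[n]))
  cs <- cumsum(x); cs2 <- cumsum(x^2); tot <- cs[n]; tot2 <- cs2[n]
  ks <- which(x[-n] < x[-1])       # only split between distinct values
  ssd_low  <- cs2[ks] - cs[ks]^2 / ks
  ssd_high <- (tot2 - cs2[ks]) - (tot - cs[ks])^2 / (n - ks)
  k <- ks[which.min(ssd_low + ssd_high)]
  brk <- x[k]
  high <- ord[(k + 1L):n]
  list(high_ids = sort(high),
       low_ids = sort(ord[1:k]),
       break_value = brk)
}
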