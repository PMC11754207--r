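# Independent brute-force oracles.  These deliberately use naive
# term-by-term loops (no shared code with the package internals) so that
# agreement is meaningful.

oracle_entropy <- function(p) {
  acc <- 0
  for (pc in p) if (pc > 0) acc <- acc - pc * log(pc)
  acc
}

# per-pixel double loop over samples and classes, Eq.-style sum form
oracle_bald <- function(samples, mode = "sum") {
  d <- dim(samples)
  out <- matrix(0, d[3], d[4])
  for (u in seq_len(d[3])) for (v in seq_len(d[4])) {
    ents <- numeric(d[1])
    pbar <- numeric(d[2])
    for (t in seq_len(d[1])) {
      ents[t] <- oracle_entropy(samples[t, , u, v])
      pbar <- pbar + samples[t, , u, v] / d[1]
    }
    out[u, v] <- if (mode == "sum") mean(ents) + oracle_entropy(pbar)
                 else oracle_entropy(pbar) - mean(ents)
  }
  out
}

oracle_masked_mean <- function(map, mask) {
  tot <- 0; n <- 0L
  for (i in seq_along(map)) if (mask[i]) { tot <- tot + map[i]; n <- n + 1L }
  if (n == 0L) 0 else tot / n
}

# explicit per-segment loop mean (optionally within a foreground mask)
oracle_aggregate <- function(map, labels, m, fg = NULL) {
  score <- numeric(m)
  for (s in seq_len(m)) {
    sel <- labels == s
    if (!is.null(fg)) sel <- sel & fg
    score[s] <- if (any(sel)) mean(map[sel]) else 0
  }
  score
}

# exhaustive two-class split of the sorted values: all n-1 split points,
# within-class SSD computed directly per side
oracle_jenks <- function(values) {
  x <- sort(values)
  n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  tot <- vapply(seq_len(n - 1L), function(k)
    ssd(x[1:k]) + ssd(x[(k + 1L):n]), numeric(1))
  k <- which.min(tot)
  list(low = x[1:k], high = x[(k + 1L):n], ssd = tot[k],
       break_value = x[k])
}

oracle_miou <- function(pred, truth, n_classes, ignore_value = 255L) {
  ious <- rep(NA_real_, n_classes)
  for (c in 0:(n_classes - 1L)) {
    tp <- fp <- fn <- 0L
    for (i in seq_along(truth)) {
      t <- truth[i]; p <- pred[i]
      if (t == ignore_value) next
      if (t == c && p == c) tp <- tp + 1L
      else if (t != c && p == c) fp <- fp + 1L
      else if (t == c && p != c) fn <- fn + 1L
    }
    if (tp + fp + fn > 0L) ious[c + 1L] <- tp / (tp + fp + fn)
  }
  list(miou = mean(ious, na.rm = TRUE), per_class = ious)
}

oracle_argmax_fg <- function(probs, background_class) {
  Cn <- dim(probs)[1]
  out <- matrix(FALSE, dim(probs)[2], dim(probs)[3])
  for (u in seq_len(dim(probs)[2])) for (v in seq_len(dim(probs)[3])) {
    best <- 1L
    for (c in 2:Cn) if (probs[c, u, v] > probs[best, u, v]) best <- c
    out[u, v] <- (best - 1L) != background_class
  }
  out
}

# random valid probability stack
random_stack <- function(T, C, U, V, seed) {
  withr::with_seed(seed, {
    a <- array(runif(T * C * U * V), dim = c(T, C, U, V))
    for (t in seq_len(T)) for (u in seq_len(U)) for (v in seq_len(V))
      a[t, , u, v] <- a[t, , u, v] / sum(a[t, , u, v])
    prob_stack(a)
  })
}

# random segmentation with every id occupied
random_spmap <- function(U, V, m, seed) {
  withr::with_seed(seed, {
    lab <- matrix(sample.int(m, U * V, replace = TRUE), U, V)
    lab[seq_len(m)] <- seq_len(m)   # guarantee occupancy
    superpixel_map(lab)
  })
}
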