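# ---- ranking-cost instrumentation -------------------------------------

.instr <- new.env(parent = emptyenv())
.instr$active <- FALSE
.instr$comparisons <- 0
.instr$scores_touched <- 0

# exact comparison count of a bottom-up two-way mergesort on `x`
mergesort_comparisons <- function(x) {
  n <- length(x)
  if (n < 2L) return(0)
  comps <- 0
  w <- 1L
  while (w < n) {
    i <- 1L
    while (i + w <= n) {
      la <- w
      lb <- min(w, n - (i + w) + 1L)
      a <- x[i:(i + la - 1L)]
      b <- x[(i + la):(i + la + lb - 1L)]
      idx <- order(c(a, b))                 # stable: ties keep a before b
      side <- c(rep(0L, la), rep(1L, lb))[idx]
      tail_run <- rle(rev(side))$lengths[1]
      comps <- comps + la + lb - tail_run
      x[i:(i + la + lb - 1L)] <- c(a, b)[idx]
      i <- i + 2L * w
    }
    w <- 2L * w
  }
  comps
}

#' Count the comparison cost of sorting a score vector
#'
#' Runs an instrumented bottom-up mergesort over `values` and returns the
#' exact number of key comparisons performed.  Used to audit the ranking
#' cost contract of the two-stage querying scheme (rank n images, then m
#' regions in each of the b selected images) against a hypothetical joint
#' sort of all n*m region scores.
#'
#' @param values Numeric vector.
#' @return Number of comparisons (scalar).
#' @export
sort_comparison_cost <- function(values) mergesort_comparisons(values)

#' Ranking instrumentation counters
#'
#' Toggles and reads counters that record, across every ranking performed
#' while active, (a) how many scores were touched and (b) how many sort
#' comparisons they cost (measured by an instrumented mergesort over the
#' same keys).  With two-stage querying a step touches exactly `n + b*m`
#' scores — never the `n*m` a joint region sort would.
#'
#' @param action `"start"` resets and enables the counters, `"report"`
#'   returns them, `"stop"` disables them.
#' @return For `"report"`, a list with `scores_touched` and
#'   `comparisons`; otherwise invisibly `NULL`.
#' @export
instrument_ranking <- function(action = c("report", "start", "stop")) {
  action <- match.arg(action)
  if (action == "start") {
    .instr$active <- TRUE
    .instr$comparisons <- 0
    .instr$scores_touched <- 0
    return(invisible(NULL))
  }
  if (action == "stop") {
    .instr$active <- FALSE
    return(invisible(NULL))
  }
  list(scores_touched = .instr$scores_touched,
       comparisons = .instr$comparisons)
}

count_ranking <- function(scores) {
  if (.instr$active) {
    .instr$scores_touched <- .instr$scores_touched + length(scores)
    .instr$comparisons <- .instr$comparisons + mergesort_comparisons(scores)
  }
  invisible(NULL)
}

# ---- pool and image ranking -------------------------------------------

#' Assemble an unlabeled-pool entry
#'
#' @param id Image identifier (integer or character).
#' @param score Aggregated image uncertainty (non-negative scalar).
#' @param fg_fraction Optional foreground fraction in `[0, 1]`.
#' @param m Optional realized superpixel count.
#' @return One-row data.frame usable with [rank_images].
#' @export
pool_entry <- function(id, score, fg_fraction = NA_real_, m = NA_integer_) {
  if (score < 0) stop("pool score must be >= 0")
  data.frame(id = id, score = score, fg_fraction = fg_fraction, m = m)
}

#' Rank the unlabeled pool and take the top b images
#'
#' Single descending sort of the n per-image uncertainty scores; returns
#' the ids of the `min(b, n)` highest entries.  Ties are broken by
#' ascending image id for determinism.  This is the first stage of the
#' two-stage ranking: region scores of unselected images are never
#' sorted, keeping the per-step cost at `n log n + b m log m` instead of
#' the `nm log(nm)` of a joint region sort.
#'
#' @param pool data.frame with columns `id` and `score` (one row per
#'   unlabeled image), e.g. built with [pool_entry] and `rbind`.
#' @param b Number of images to query (>= 1).
#' @return Vector of `min(b, nrow(pool))` image ids, descending score.
#' @export
rank_images <- function(pool, b) {
  if (!is.data.frame(pool) || nrow(pool) == 0L)
    stop("`pool` must be a non-empty data.frame")
  if (!is.numeric(b) || length(b) != 1L || b < 1)
    stop("`b` must be >= 1")
  count_ranking(pool$score)
  ord <- order(-pool$score, pool$id)
  pool$id[ord[seq_len(min(b, nrow(pool)))]]
}

# ---- superpixel selection ---------------------------------------------

eligible_scores <- function(scores) {
  stopifnot(inherits(scores, "superpixel_scores") || is.data.frame(scores))
  scores[scores$foreground, , drop = FALSE]
}

#' Dynamic-budget superpixel selection
#'
#' Selects exactly the high-uncertainty cluster of the two-class Jenks
#' natural-breaks split of the eligible (foreground) superpixel scores.
#' The number of queried regions therefore adapts to how many
#' high-uncertainty regions the image actually has: zero when all scores
#' are equal, up to many when uncertainty is widespread.
#'
#' @param scores A `superpixel_scores` data.frame from [aggregate_scores].
#' @return Integer vector of queried segment ids (possibly empty).
#' @export
select_dynamic <- function(scores) {
  el <- eligible_scores(scores)
  if (nrow(el) == 0L) {
    warning("no eligible (foreground) segments; nothing queried")
    return(integer(0))
  }
  count_ranking(el$score)
  sp <- jenks_split_2(el$score)
  sort(el$id[sp$high_ids])
}

#' Static-budget superpixel selection
#'
#' Queries the top `round(q_fraction * m_eligible)` superpixels by score
#' (minimum 1), the fixed-budget baseline the dynamic scheme is compared
#' against.  Ties at the cutoff are broken by ascending segment id.
#'
#' @param scores A `superpixel_scores` data.frame from [aggregate_scores].
#' @param q_fraction Fraction of eligible superpixels to query, in (0, 1].
#' @return Integer vector of queried segment ids.
#' @export
select_static <- function(scores, q_fraction) {
  if (!is.numeric(q_fraction) || length(q_fraction) != 1L ||
      q_fraction <= 0 || q_fraction > 1)
    stop("`q_fraction` must be in (0, 1]")
  el <- eligible_scores(scores)
  if (nrow(el) == 0L) {
    warning("no eligible (foreground) segments; nothing queried")
    return(integer(0))
  }
  count_ranking(el$score)
  k <- max(1L, as.integer(floor(q_fraction * nrow(el) + 0.5)))
  ord <- order(-el$score, el$id)
  sort(el$id[ord[seq_len(min(k, nrow(el)))]])
}

# ---- partial labels ----------------------------------------------------

#' Build a partial label from queried superpixels
#'
#' Simulates the oracle: pixels inside queried segments receive their
#' ground-truth class; everything else is set to the ignore value, which
#' the learner's loss and the IoU evaluation both skip.
#'
#' @param full_label Integer matrix of ground-truth class ids.
#' @param spmap A [superpixel_map] of the same shape.
#' @param queried Integer vector of queried segment ids (subset of
#'   `1..m`).
#' @param ignore_value Reserved integer not used as a class id
#'   (default 255).
#' @return Integer matrix: ground truth inside queried segments,
#'   `ignore_value` elsewhere.
#' @export
build_partial_label <- function(full_label, spmap, queried,
                                ignore_value = 255L) {
  stopifnot(inherits(spmap, "superpixel_map"))
  if (!identical(dim(full_label), dim(spmap$labels)))
    stop("label shape must match segmentation shape")
  queried <- as.integer(queried)
  if (length(queried) && (any(queried < 1L) || any(queried > spmap$m)))
    stop("queried segment id not present in the superpixel map")
  out <- matrix(as.integer(ignore_value),
                nrow = nrow(full_label), ncol = ncol(full_label))
  sel <- spmap$labels %in% queried
  out[sel] <- as.integer(full_label[sel])
  out
}

# ---- budget ledger -----------------------------------------------------

#' Running labeled-superpixel budget ledger
#'
#' Accumulates, per active learning step, how many superpixels were
#' labeled out of how many eligible superpixels over the queried images.
#' The running average labeled fraction is always recomputed from the raw
#' integer counts (`sum(labeled) / sum(total)`), never updated
#' incrementally, so it cannot drift.  In foreground mode, totals count
#' foreground segments only.
#'
#' @return An empty `budget_ledger`.
#' @export
budget_ledger <- function() {
  structure(list(labeled = integer(0), total = integer(0),
                 images = integer(0)),
            class = "budget_ledger")
}

#' Record one querying step in the budget ledger
#'
#' @param ledger A [budget_ledger].
#' @param queried_per_image Integer vector: labeled superpixels per
#'   queried image.
#' @param totals_per_image Integer vector: eligible superpixels per
#'   queried image (foreground segments only in foreground mode).
#' @return The updated ledger.
#' @export
record_step <- function(ledger, queried_per_image, totals_per_image) {
  stopifnot(inherits(ledger, "budget_ledger"))
  if (length(queried_per_image) != length(totals_per_image))
    stop("per-image count vectors must have equal length")
  if (any(queried_per_image > totals_per_image))
    stop("queried count exceeds total count for some image")
  if (any(queried_per_image < 0) || any(totals_per_image < 0))
    stop("counts must be non-negative")
  ledger$labeled <- c(ledger$labeled, as.integer(sum(queried_per_image)))
  ledger$total <- c(ledger$total, as.integer(sum(totals_per_image)))
  ledger$images <- c(ledger$images, length(queried_per_image))
  ledger
}

#' Average labeled-superpixel fraction of a ledger
#'
#' @param ledger A [budget_ledger].
#' @return `sum(labeled) / sum(total)` over all recorded steps (0 when
#'   nothing has been recorded).
#' @export
labeled_fraction <- function(ledger) {
  stopifnot(inherits(ledger, "budget_ledger"))
  tot <- sum(ledger$total)
  if (tot == 0L) return(0)
  sum(ledger$labeled) / tot
}

#' @export
print.budget_ledger <- function(x, ...) {
  cat(sprintf(
    "<budget_ledger> %d steps, %d/%d superpixels labeled (avg %.1f%%)\n",
    length(x$labeled), sum(x$labeled), sum(x$total),
    100 * labeled_fraction(x)))
  invisible(x)
}
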