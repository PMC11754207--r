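# deterministic sub-seed derivation; keeps values well below 2^31
subseed <- function(seed, a = 0L, b = 0L) {
  as.integer(((seed %% 100003) * 10007 + a * 101 + b * 7 + 12345) %% 2147483629)
}

#' Active learning run configuration
#'
#' Bundles every tunable of the querying loop.  Defaults follow the
#' low-budget field-imagery protocol: 50 fully labeled initialization
#' images, 50 images queried per step, 6 steps, fine superpixels.
#'
#' @param init_count Images fully labeled at initialization.
#' @param b Images queried per active learning step.
#' @param steps Number of active learning steps.
#' @param T Monte-Carlo samples per image (>= 2; the disagreement score
#'   is degenerate with a single sample).
#' @param n_segments Target superpixels per image (e.g. 2000 fine / 500
#'   coarse on 256x256 tiles).
#' @param mode `"dynamic"` (Jenks high cluster) or `"static"` (fixed
#'   top-q fraction).
#' @param q_fraction Static-mode query fraction in (0, 1]; ignored in
#'   dynamic mode.
#' @param foreground_mode Exclude background from ranking, selection and
#'   budget accounting, and scale image scores by foreground fraction.
#' @param background_class Background class id (foreground mode).
#' @param ignore_value Reserved label for unqueried pixels (default 255).
#' @param compactness SLIC compactness.
#' @param bald_mode `"sum"` (as-printed score) or `"mutual_information"`.
#' @param seed Integer seed governing every stochastic choice of the run.
#' @return A validated `al_config` list.
#' @export
al_config <- function(init_count = 50L, b = 50L, steps = 6L, T = 8L,
                      n_segments = 2000L, mode = c("dynamic", "static"),
                      q_fraction = NULL, foreground_mode = FALSE,
                      background_class = 0L, ignore_value = 255L,
                      compactness = 10, bald_mode = "sum", seed = 1L) {
  mode <- match.arg(mode)
  if (T < 2L) stop("`T` must be >= 2")
  if (init_count < 1L || b < 1L || steps < 0L)
    stop("`init_count`, `b` must be >= 1 and `steps` >= 0")
  if (mode == "static") {
    if (is.null(q_fraction) || q_fraction <= 0 || q_fraction > 1)
      stop("static mode requires `q_fraction` in (0, 1]")
  }
  structure(list(init_count = as.integer(init_count), b = as.integer(b),
                 steps = as.integer(steps), T = as.integer(T),
                 n_segments = as.integer(n_segments), mode = mode,
                 q_fraction = q_fraction, foreground_mode = foreground_mode,
                 background_class = as.integer(background_class),
                 ignore_value = as.integer(ignore_value),
                 compactness = compactness, bald_mode = bald_mode,
                 seed = as.integer(seed)),
            class = "al_config")
}

#' Mean intersection-over-union of a segmentation prediction
#'
#' Per class c, `IoU_c = TP / (TP + FP + FN)` accumulated over all
#' supplied image pairs, counting only pixels whose ground truth is not
#' the ignore value.  The mean is unweighted over classes present in
#' the (non-ignored) truth or prediction; classes absent from both are
#' excluded rather than scored 0 or 1.
#'
#' @param pred Integer matrix of predicted class ids, or list of them.
#' @param truth Matching ground-truth matrix or list.
#' @param n_classes Number of classes (ids `0..n_classes-1`).
#' @param ignore_value Ground-truth value to skip (default 255).
#' @return List with `miou` and `per_class` (named vector, `NA` for
#'   classes absent from truth and prediction).
#' @export
evaluate_miou <- function(pred, truth, n_classes, ignore_value = 255L) {
  if (!is.list(pred)) pred <- list(pred)
  if (!is.list(truth)) truth <- list(truth)
  if (length(pred) != length(truth))
    stop("`pred` and `truth` must pair up")
  lv <- 0:(n_classes - 1L)
  conf <- matrix(0, n_classes, n_classes)
  any_valid <- FALSE
  for (i in seq_along(pred)) {
    if (!identical(dim(pred[[i]]), dim(truth[[i]])))
      stop("prediction/truth shape mismatch")
    valid <- truth[[i]] != ignore_value
    if (!any(valid)) next
    any_valid <- TRUE
    tv <- truth[[i]][valid]; pv <- pred[[i]][valid]
    if (any(!(pv %in% lv)) || any(!(tv %in% lv)))
      stop("class id outside 0..n_classes-1")
    conf <- conf + table(factor(tv, levels = lv), factor(pv, levels = lv))
  }
  if (!any_valid) stop("no non-ignored pixels to evaluate")
  tp <- diag(conf)
  fp <- colSums(conf) - tp
  fn <- rowSums(conf) - tp
  denom <- tp + fp + fn
  iou <- ifelse(denom > 0, tp / denom, NA_real_)
  names(iou) <- as.character(lv)
  list(miou = mean(iou[denom > 0]), per_class = iou)
}

# per-image scoring shared by initialization-free querying and al_step:
# returns list(score, map, fg) for one pool image
score_pool_image <- function(model, image, cfg, learner, seed) {
  stack <- learner$sample_probabilities(model, image, cfg$T, seed)
  map <- bald_map(stack, mode = cfg$bald_mode)
  if (cfg$foreground_mode) {
    fg <- mask_from_prediction(mean_probs(stack), cfg$background_class)
    u <- if (fg$fg_fraction > 0) image_uncertainty(map, fg$mask) else 0
    list(score = scale_by_foreground(u, fg$fg_fraction), map = map, fg = fg)
  } else {
    list(score = image_uncertainty(map), map = map, fg = NULL)
  }
}

#' Initialize an active learning run
#'
#' Uniformly samples `init_count` images from the unlabeled pool (seeded,
#' without replacement), gives them whole-image labels, and trains the
#' learner on them.  These are the only images that ever receive
#' whole-image labels; all later labels are partial.
#'
#' @param images List of RGB arrays `(U, V, 3)` in `[0, 255]`.
#' @param labels List of matching integer class-id matrices.
#' @param cfg An [al_config].
#' @param learner A learner contract (see [tiny_learner]).
#' @return An `al_state` list: `pool_ids`, `train_ids`, `train_images`,
#'   `train_labels`, `model`, `ledger`, `step`, plus the inputs.
#' @export
initialize_al <- function(images, labels, cfg, learner) {
  n <- length(images)
  if (length(labels) != n) stop("`images` and `labels` must pair up")
  if (n < cfg$init_count)
    stop(sprintf("pool (%d) smaller than init_count (%d)", n, cfg$init_count))
  if (cfg$init_count + cfg$b * cfg$steps > n)
    stop("init_count + b * steps exceeds pool size")
  init_ids <- withr::with_seed(subseed(cfg$seed, 1L),
                               sort(sample.int(n, cfg$init_count)))
  model <- learner$fit(images[init_ids], labels[init_ids],
                       prev = NULL, ignore_value = cfg$ignore_value,
                       seed = subseed(cfg$seed, 2L))
  list(images = images, labels = labels,
       pool_ids = setdiff(seq_len(n), init_ids),
       train_ids = init_ids,
       train_images = images[init_ids],
       train_labels = labels[init_ids],
       model = model, ledger = budget_ledger(), step = 0L,
       spcache = vector("list", n))
}

#' Run one active learning step
#'
#' Scores every pool image with Monte-Carlo BALD (foreground-masked and
#' foreground-scaled in foreground mode), selects the top-b images,
#' over-segments each into superpixels, queries the dynamic (Jenks high
#' cluster) or static (top-q) superpixels, asks the simulated oracle for
#' their labels (rest ignored), retrains the learner warm-started from
#' the previous step's model, and appends the step to the budget ledger.
#' Queried images leave the pool.
#'
#' @param state State from [initialize_al] or a previous `al_step`.
#' @param cfg An [al_config].
#' @param learner Learner contract.
#' @param oracle Function `id -> full label matrix` (defaults to looking
#'   up `state$labels`).
#' @return Updated state; `state$record` holds the step's
#'   queried/total superpixel counts per image.
#' @export
al_step <- function(state, cfg, learner, oracle = NULL) {
  if (length(state$pool_ids) < cfg$b)
    stop(sprintf("pool (%d) smaller than b (%d)",
                 length(state$pool_ids), cfg$b))
  if (is.null(oracle)) oracle <- function(id) state$labels[[id]]
  step <- state$step + 1L

  scored <- lapply(seq_along(state$pool_ids), function(k) {
    id <- state$pool_ids[k]
    score_pool_image(state$model, state$images[[id]], cfg, learner,
                     seed = subseed(cfg$seed, step, id))
  })
  pool_df <- data.frame(id = state$pool_ids,
                        score = vapply(scored, `[[`, numeric(1), "score"))
  sel <- rank_images(pool_df, cfg$b)

  queried_counts <- integer(0); total_counts <- integer(0)
  for (id in sel) {
    k <- match(id, state$pool_ids)
    if (is.null(state$spcache[[id]]))
      state$spcache[[id]] <- slic_segment(state$images[[id]],
                                          cfg$n_segments, cfg$compactness)
    spmap <- state$spcache[[id]]
    sc <- aggregate_scores(scored[[k]]$map, spmap,
                           fg_mask = if (cfg$foreground_mode)
                             scored[[k]]$fg else NULL)
    queried <- if (cfg$mode == "dynamic") select_dynamic(sc)
               else select_static(sc, cfg$q_fraction)
    plab <- build_partial_label(oracle(id), spmap, queried,
                                cfg$ignore_value)
    state$train_ids <- c(state$train_ids, id)
    state$train_images <- c(state$train_images, list(state$images[[id]]))
    state$train_labels <- c(state$train_labels, list(plab))
    queried_counts <- c(queried_counts, length(queried))
    total_counts <- c(total_counts,
                      if (cfg$foreground_mode) sum(sc$foreground)
                      else spmap$m)
  }

  state$ledger <- record_step(state$ledger, queried_counts, total_counts)
  state$pool_ids <- setdiff(state$pool_ids, sel)
  state$model <- learner$fit(state$train_images, state$train_labels,
                             prev = state$model,
                             ignore_value = cfg$ignore_value,
                             seed = subseed(cfg$seed, step, 999L))
  state$step <- step
  state$record <- list(step = step, selected = sel,
                       queried = queried_counts, totals = total_counts)
  state
}

#' Run a full active learning experiment
#'
#' Initialization plus `cfg$steps` active learning steps, with optional
#' per-step mean-IoU evaluation on a held-out test set.
#'
#' @param images,labels Unlabeled pool (lists; labels revealed only as
#'   the simulated oracle queries them).
#' @param cfg An [al_config].
#' @param learner Learner contract (see [tiny_learner]).
#' @param test_images,test_labels Optional held-out set for per-step
#'   evaluation.
#' @param n_classes Number of classes (required when evaluating).
#' @param verbose Print a per-step summary line to stderr.
#' @return An `al_run` object: `records` data.frame (one row per step,
#'   including step 0 = initialization), `ledger`, `cfg`, final `model`,
#'   and `state`.
#' @export
run_active_learning <- function(images, labels, cfg, learner,
                                test_images = NULL, test_labels = NULL,
                                n_classes = NULL, verbose = FALSE) {
  eval_step <- function(model) {
    if (is.null(test_images)) return(list(miou = NA_real_, per_class = NULL))
    pred <- lapply(test_images, function(im)
      learner$predict_classes(model, im))
    evaluate_miou(pred, test_labels, n_classes, cfg$ignore_value)
  }
  state <- initialize_al(images, labels, cfg, learner)
  ev <- eval_step(state$model)
  rows <- list(data.frame(step = 0L,
                          labeled_images = cfg$init_count,
                          labeled_superpixels = 0L, total_superpixels = 0L,
                          avg_labeled_fraction = NA_real_,
                          miou = ev$miou))
  if (verbose)
    message(sprintf("step 0: %d images (init), mIoU %.3f",
                    cfg$init_count, ev$miou))
  for (s in seq_len(cfg$steps)) {
    state <- al_step(state, cfg, learner)
    ev <- eval_step(state$model)
    rows[[s + 1L]] <- data.frame(
      step = s,
      labeled_images = cfg$init_count + s * cfg$b,
      labeled_superpixels = sum(state$ledger$labeled),
      total_superpixels = sum(state$ledger$total),
      avg_labeled_fraction = labeled_fraction(state$ledger),
      miou = ev$miou)
    if (verbose)
      message(sprintf(
        "step %d: %d images, avg labeled %.1f%%, mIoU %.3f",
        s, cfg$init_count + s * cfg$b,
        100 * labeled_fraction(state$ledger), ev$miou))
  }
  structure(list(records = do.call(rbind, rows), ledger = state$ledger,
                 cfg = cfg, model = state$model, state = state),
            class = "al_run")
}

#' @export
print.al_run <- function(x, ...) {
  cat(sprintf("<al_run> mode=%s, %d steps\n", x$cfg$mode, x$cfg$steps))
  print(x$records, row.names = FALSE)
  invisible(x)
}
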