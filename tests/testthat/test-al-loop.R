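# a deterministic stub learner: constant predictive distribution
# everywhere, optionally with per-sample disagreement; lets the loop be
# tested with no training at all
stub_learner <- function(n_classes = 3L, disagree = FALSE) {
  structure(list(
    fit = function(images, labels, prev = NULL, ignore_value = 255L,
                   seed = 1L) list(kind = "stub"),
    predict_probs = function(model, image)
      array(1 / n_classes, dim = c(n_classes, nrow(image), ncol(image))),
    predict_classes = function(model, image)
      matrix(0L, nrow(image), ncol(image)),
    sample_probabilities = function(model, image, T, seed = 1L) {
      a <- array(0, dim = c(T, n_classes, nrow(image), ncol(image)))
      for (t in seq_len(T)) {
        cls <- if (disagree) ((t - 1L) %% n_classes) + 1L else 1L
        a[t, cls, , ] <- 1
      }
      prob_stack(a)
    },
    n_classes = n_classes), class = "al_learner")
}

tiny_pool <- function(n, size = 16L, seed = 1L) {
  scenes <- make_field_dataset(n, size = size, seed = seed)
  list(images = lapply(scenes, `[[`, "image"),
       labels = lapply(scenes, `[[`, "label"))
}

test_that("miou matches the confusion-matrix oracle and honors ignore", {
  p <- matrix(0:2, 3, 3); expect_equal(evaluate_miou(p, p, 3)$miou, 1)
  truth <- matrix(255L, 4, 4); truth[1, 1] <- 1L
  pred <- matrix(1L, 4, 4)
  ev <- evaluate_miou(pred, truth, 3)
  expect_equal(unname(ev$per_class["1"]), 1)
  expect_equal(ev$miou, 1)
  for (seed in 1:10) {
    withr::with_seed(seed, {
      truth <- matrix(sample(c(0:2, 255L), 60, replace = TRUE), 6, 10)
      pred <- matrix(sample(0:2, 60, replace = TRUE), 6, 10)
    })
    want <- oracle_miou(pred, truth, 3)
    got <- evaluate_miou(pred, truth, 3)
    expect_equal(got$miou, want$miou, tolerance = 1e-12)
    expect_equal(unname(got$per_class), want$per_class, tolerance = 1e-12)
  }
  expect_error(evaluate_miou(matrix(0L, 2, 2), matrix(255L, 2, 2), 3),
               "no non-ignored")
  expect_error(evaluate_miou(matrix(0L, 2, 2), matrix(0L, 3, 2), 3),
               "shape")
})

test_that("initialization samples reproducibly and shrinks the pool", {
  pool <- tiny_pool(12, seed = 4)
  L <- stub_learner()
  cfg <- al_config(init_count = 5, b = 2, steps = 2, T = 2,
                   n_segments = 8, seed = 42)
  s1 <- initialize_al(pool$images, pool$labels, cfg, L)
  s2 <- initialize_al(pool$images, pool$labels, cfg, L)
  expect_identical(s1$train_ids, s2$train_ids)
  expect_length(s1$train_ids, 5L)
  expect_length(s1$pool_ids, 7L)
  expect_identical(intersect(s1$train_ids, s1$pool_ids), integer(0))

  cfg_all <- al_config(init_count = 12, b = 1, steps = 0, T = 2, seed = 1)
  s3 <- initialize_al(pool$images, pool$labels, cfg_all, L)
  expect_length(s3$pool_ids, 0L)
  expect_error(initialize_al(pool$images[1:3], pool$labels[1:3], cfg, L),
               "smaller|exceeds")
})

test_that("initialization scales to a low-budget field pool", {
  # 50 whole-image labels out of a 1784-image pool, the low-budget
  # field-imagery protocol; images can be trivial since only the
  # sampling and bookkeeping are under test
  img <- array(128, dim = c(4, 4, 3))
  lab <- matrix(0L, 4, 4)
  images <- rep(list(img), 1784)
  labels <- rep(list(lab), 1784)
  cfg <- al_config(init_count = 50, b = 50, steps = 6, T = 8, seed = 3)
  st <- initialize_al(images, labels, cfg, stub_learner())
  expect_length(unique(st$train_ids), 50L)
  expect_length(st$pool_ids, 1784L - 50L)
})

test_that("a step under all-equal uncertainty queries nothing", {
  pool <- tiny_pool(8, seed = 5)
  L <- stub_learner(disagree = FALSE)  # identical one-hot samples: BALD 0
  cfg <- al_config(init_count = 2, b = 6, steps = 1, T = 3,
                   n_segments = 4, seed = 7)
  st <- initialize_al(pool$images, pool$labels, cfg, L)
  st <- al_step(st, cfg, L)
  expect_identical(sum(st$ledger$labeled), 0L)
  expect_true(all(st$record$queried == 0L))
  # every added label is pure ignore
  expect_true(all(vapply(st$train_labels[-(1:2)],
                         function(l) all(l == 255L), logical(1))))
})

test_that("step arithmetic and ledger monotonicity hold across steps", {
  pool <- tiny_pool(14, seed = 6)
  L <- stub_learner(disagree = TRUE)
  cfg <- al_config(init_count = 4, b = 3, steps = 3, T = 3,
                   n_segments = 4, seed = 9)
  st <- initialize_al(pool$images, pool$labels, cfg, L)
  for (k in 1:3) {
    st <- al_step(st, cfg, L)
    expect_length(st$train_ids, 4L + 3L * k)
    expect_identical(st$record$step, k)
  }
  expect_true(all(diff(cumsum(st$ledger$labeled)) >= 0))
  expect_error(al_step(st, cfg, L), "smaller")
})

test_that("runs with the same seed are identical end to end", {
  pool <- tiny_pool(16, size = 24L, seed = 10)
  L <- tiny_learner(3, max_pixels = 3000L)
  cfg <- al_config(init_count = 4, b = 3, steps = 2, T = 4,
                   n_segments = 9, seed = 11)
  r1 <- run_active_learning(pool$images, pool$labels, cfg, L,
                            test_images = pool$images[1:2],
                            test_labels = pool$labels[1:2], n_classes = 3)
  r2 <- run_active_learning(pool$images, pool$labels, cfg, L,
                            test_images = pool$images[1:2],
                            test_labels = pool$labels[1:2], n_classes = 3)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$ledger, r2$ledger)
  # labeled-image bookkeeping matches init + k b
  expect_identical(r1$records$labeled_images, c(4L, 7L, 10L))
})
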