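mk_scores <- function(score, foreground = TRUE) {
  out <- data.frame(id = seq_along(score), score = score,
                    n_pixels = 1L,
                    foreground = rep_len(foreground, length(score)))
  class(out) <- c("superpixel_scores", class(out))
  out
}

test_that("image ranking takes the top-b by score with id tie-breaks", {
  pool <- data.frame(id = 1:3, score = c(0.9, 0.1, 0.5))
  expect_identical(rank_images(pool, 2), c(1L, 3L))
  expect_identical(rank_images(pool, 10), c(1L, 3L, 2L))
  expect_error(rank_images(pool[0, ], 1), "non-empty")
  expect_error(rank_images(pool, 0), ">= 1")
  for (seed in 1:10) {
    # duplicated scores exercise the tie rule
    sc <- withr::with_seed(seed, round(runif(200), 2))
    pool <- data.frame(id = seq_along(sc), score = sc)
    want <- pool$id[order(-sc, pool$id)][1:50]
    expect_identical(rank_images(pool, 50), want)
  }
})

test_that("dynamic selection returns exactly the Jenks high cluster", {
  expect_identical(select_dynamic(mk_scores(c(0.1, 0.1, 0.9, 0.95))),
                   c(3L, 4L))
  expect_identical(select_dynamic(mk_scores(rep(0.3, 6))), integer(0))
  for (seed in 1:15) {
    sc <- withr::with_seed(seed, runif(100))
    want <- which(sc %in% oracle_jenks(sc)$high)
    expect_identical(select_dynamic(mk_scores(sc)), as.integer(want))
  }
  # background-flagged segments are never selected
  s <- mk_scores(c(0.1, 5, 0.2, 6), foreground = c(TRUE, FALSE, TRUE, TRUE))
  expect_false(2L %in% select_dynamic(s))
  expect_warning(out <- select_dynamic(mk_scores(1:3, foreground = FALSE)),
                 "no eligible")
  expect_identical(out, integer(0))
})

test_that("static selection queries round(q m) by score, minimum one", {
  expect_identical(select_static(mk_scores(c(0.4, 0.9, 0.1, 0.8)), 0.5),
                   c(2L, 4L))
  expect_identical(select_static(mk_scores(c(0.2, 0.9, 0.1)), 0.01), 2L)
  expect_error(select_static(mk_scores(1:3), 0), "\\(0, 1\\]")
  expect_error(select_static(mk_scores(1:3), 1.1), "\\(0, 1\\]")
  for (seed in 1:10) {
    sc <- withr::with_seed(seed, runif(100))
    got <- select_static(mk_scores(sc), 0.31)
    expect_length(got, 31L)
    expect_identical(got, sort(order(-sc, seq_along(sc))[1:31]))
  }
  # cutoff ties break by ascending segment id
  tied <- mk_scores(c(0.5, 0.5, 0.5, 0.1))
  expect_identical(select_static(tied, 0.5), c(1L, 2L))
  # background segments neither selected nor counted in m_eligible
  s <- mk_scores(c(9, 1, 2, 3), foreground = c(FALSE, TRUE, TRUE, TRUE))
  expect_identical(select_static(s, 1 / 3), 4L)
})

test_that("partial labels conserve ground truth and ignore the rest", {
  sp <- random_spmap(6, 7, 5, seed = 3)
  full <- withr::with_seed(8, matrix(sample(0:2, 42, replace = TRUE), 6, 7))
  expect_identical(build_partial_label(full, sp, 1:5, 255L),
                   matrix(as.integer(full), 6, 7))
  expect_true(all(build_partial_label(full, sp, integer(0), 255L) == 255L))
  expect_error(build_partial_label(full, sp, c(1L, 9L), 255L), "queried")
  for (seed in 1:10) {
    queried <- withr::with_seed(seed, which(runif(5) < 0.5))
    got <- build_partial_label(full, sp, queried, 255L)
    for (i in seq_along(full)) {
      want <- if (sp$labels[i] %in% queried) full[i] else 255L
      expect_identical(got[i], as.integer(want))
    }
  }
})

test_that("budget ledger recomputes the pooled fraction from raw counts", {
  led <- record_step(budget_ledger(), 31L, 100L)
  expect_identical(labeled_fraction(led), 0.31)
  led2 <- record_step(budget_ledger(), c(10L, 30L), c(100L, 100L))
  expect_identical(labeled_fraction(led2), 0.2)
  expect_error(record_step(budget_ledger(), 5L, 4L), "exceeds")
  expect_error(record_step(budget_ledger(), c(1L, 2L), 3L), "equal length")
  for (seed in 1:5) {
    withr::with_seed(seed, {
      tot <- sample(50:200, 50, replace = TRUE)
      q <- vapply(tot, function(t) sample.int(t, 1), integer(1))
    })
    led <- budget_ledger()
    for (i in seq(1, 50, by = 10))
      led <- record_step(led, q[i:(i + 9)], tot[i:(i + 9)])
    expect_identical(labeled_fraction(led), sum(q) / sum(tot))
  }
})

test_that("static budgets matched to a dynamic run agree to rounding", {
  # dynamic over a pool of score vectors, then static at the recorded
  # average labeled fraction: totals differ by at most one per image
  for (seed in 1:5) {
    pools <- withr::with_seed(seed, lapply(1:20, function(i) {
      n_high <- sample(1:10, 1)
      c(runif(60, 0, 0.2), runif(n_high, 0.8, 1))
    }))
    dyn <- lapply(pools, function(sc) select_dynamic(mk_scores(sc)))
    led <- record_step(budget_ledger(), lengths(dyn), lengths(pools))
    q <- labeled_fraction(led)
    stat <- lapply(pools, function(sc) select_static(mk_scores(sc), q))
    expect_lte(abs(sum(lengths(stat)) - sum(lengths(dyn))), 20)
    # static size constant given pool size; dynamic varies with planted count
    expect_true(all(tapply(lengths(stat), lengths(pools),
                           function(v) length(unique(v)) == 1L)))
    expect_gt(length(unique(lengths(dyn))), 1L)
  }
})
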