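flat_rgb <- function(U, V, rgb) {
  img <- array(0, dim = c(U, V, 3))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  img
}

test_that("slic handles the whole-image and uniform-color cases", {
  img <- flat_rgb(20, 20, c(120, 100, 80))
  expect_equal(slic_segment(img, 1)$m, 1L)
  expect_error(slic_segment(img, 401), "exceeds pixel count")

  sp <- slic_segment(img, 4)
  expect_equal(sp$m, 4L)
  expect_identical(sort(unique(as.vector(sp$labels))), 1:4)
  areas <- tabulate(sp$labels, 4)
  expect_true(all(areas >= 100 * 0.5) && all(areas <= 100 * 1.5))
  # deterministic for fixed inputs
  expect_identical(slic_segment(img, 4)$labels, sp$labels)
})

test_that("slic places the boundary of a two-tone image at the tone edge", {
  img <- array(0, dim = c(40, 40, 3))
  img[, 21:40, ] <- 255
  sp <- slic_segment(img, 2)
  expect_equal(sp$m, 2L)
  trans <- apply(sp$labels, 1, function(r) which(diff(r) != 0))
  expect_true(all(vapply(trans, length, integer(1)) == 1L))
  expect_true(all(abs(unlist(trans) - 20) <= 2))
})

test_that("aggregate_scores means member pixels, with and without masks", {
  sp <- random_spmap(8, 9, 6, seed = 2)
  expect_equal(aggregate_scores(matrix(0.4, 8, 9), sp)$score, rep(0.4, 6))

  lab <- matrix(1L, 4, 4); lab[, 3:4] <- 2L
  sp2 <- superpixel_map(lab)
  map2 <- matrix(0, 4, 4); map2[, 1:2] <- 0.2; map2[, 3:4] <- 0.9
  expect_equal(aggregate_scores(map2, sp2)$score, c(0.2, 0.9))

  for (seed in 1:15) {
    sp <- random_spmap(7, 6, 5, seed = seed)
    map <- withr::with_seed(seed + 100, matrix(runif(42), 7, 6))
    fg <- withr::with_seed(seed + 200, matrix(runif(42) < 0.6, 7, 6))
    expect_equal(aggregate_scores(map, sp)$score,
                 oracle_aggregate(map, sp$labels, 5), tolerance = 1e-12)
    got <- aggregate_scores(map, sp, fg)
    expect_equal(got$score, oracle_aggregate(map, sp$labels, 5, fg),
                 tolerance = 1e-12)
    # background flag marks exactly the segments without foreground pixels
    expect_identical(got$foreground,
                     vapply(1:5, function(s) any(fg[sp$labels == s]),
                            logical(1)))
  }
  expect_error(aggregate_scores(matrix(0, 3, 3), random_spmap(4, 4, 2, 1)),
               "shape")
})

test_that("aggregate_scores is invariant to segment relabeling", {
  sp <- random_spmap(6, 6, 4, seed = 5)
  map <- withr::with_seed(9, matrix(runif(36), 6, 6))
  perm <- c(3L, 1L, 4L, 2L)
  relab <- superpixel_map(matrix(perm[sp$labels], 6, 6))
  expect_equal(aggregate_scores(map, relab)$score[perm],
               aggregate_scores(map, sp)$score, tolerance = 1e-12)
})

test_that("jenks split handles obvious gaps and degenerate inputs", {
  sp <- jenks_split_2(c(1, 1, 1, 10, 10))
  expect_identical(sp$high_ids, c(4L, 5L))
  expect_true(sp$break_value >= 1 && sp$break_value < 10)

  eq <- jenks_split_2(rep(2.5, 7))
  expect_identical(eq$high_ids, integer(0))
  expect_identical(eq$low_ids, 1:7)

  single <- jenks_split_2(3.3)
  expect_identical(single$high_ids, 1L)
  expect_error(jenks_split_2(numeric(0)), "non-empty")
})

test_that("jenks split equals the exhaustive minimum-SSD oracle", {
  for (seed in 1:30) {
    x <- withr::with_seed(seed, runif(20))
    got <- jenks_split_2(x)
    want <- oracle_jenks(x)
    expect_equal(sort(x[got$high_ids]), want$high)
    expect_equal(sort(x[got$low_ids]), want$low)
    expect_equal(got$break_value, want$break_value)
    # partition covers everything exactly once; high dominates low
    expect_identical(sort(c(got$high_ids, got$low_ids)), seq_along(x))
    expect_true(min(x[got$high_ids]) >= max(x[got$low_ids]))
  }
})

test_that("jenks ties at the break stay in the low class", {
  # values equal to the low-class maximum are never queried
  x <- c(1, 2, 2, 2, 9, 9)
  got <- jenks_split_2(x)
  expect_identical(got$high_ids, c(5L, 6L))
  expect_equal(got$break_value, 2)
  # tied data still achieve the oracle's minimal within-class SSD
  for (seed in 1:10) {
    x <- withr::with_seed(seed, round(runif(30, 0, 4)) / 2)
    if (length(unique(x)) < 2) next
    got <- jenks_split_2(x)
    ssd <- function(v) if (length(v)) sum((v - mean(v))^2) else 0
    expect_equal(ssd(x[got$high_ids]) + ssd(x[got$low_ids]),
                 oracle_jenks(x)$ssd, tolerance = 1e-12)
  }
})
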