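test_that("binarization thresholds strictly, ties to background", {
  p <- matrix(0.5, 3L, 3L)
  expect_true(all(binarize(p, 0.5) == 0L))
  expect_true(all(binarize(matrix(1, 3L, 3L)) == 1L))
  b <- binarize(matrix(runif(25), 5L), 0.5)
  expect_identical(binarize(b + 0, 0.5), b)  # idempotent on reloaded masks
})

test_that("thinning yields 1-px skeletons and preserves connectivity", {
  # 3-px-wide horizontal bar thins to (about) its centerline row
  bar <- matrix(0L, 11L, 20L)
  bar[5:7, 3:18] <- 1L
  sk <- skeletonize(bar)
  pts <- skeleton_points(sk)
  expect_true(all(pts[, 1L] == 6L))           # middle row
  expect_gte(nrow(pts), 16L - 4L)             # up to end-pixel erosion
  expect_equal(count_components(sk), 1L)

  single <- matrix(0L, 5L, 5L); single[3L, 3L] <- 1L
  expect_identical(skeletonize(single), single)

  # component count is preserved on random blob images
  set.seed(8)
  for (i in 1:5) {
    m <- matrix(0L, 40L, 40L)
    for (j in 1:6) {
      r <- sample(5:35, 1L); c <- sample(5:35, 1L); s <- sample(2:4, 1L)
      m[(r - s):(r + s), (c - s):(c + s)] <- 1L
    }
    expect_equal(count_components(skeletonize(m)), count_components(m))
  }
})

test_that("tolerance matching is strict and matches brute force", {
  A <- rbind(c(1, 1)); B <- rbind(c(1, 2))
  expect_equal(nrow(match_points(A, B, 2)), 1L)  # distance 1 < 2
  expect_equal(nrow(match_points(A, B, 1)), 0L)  # 1 is not < 1: no tolerance
  expect_equal(nrow(match_points(A, A[integer(0L), , drop = FALSE], 2)), 0L)

  set.seed(11)
  for (i in 1:200) {
    A <- random_points(sample(1:30, 1L))
    B <- random_points(sample(1:30, 1L))
    tau <- sample(c(1, 2, 3, 5), 1L)
    expect_identical(match_points(A, B, tau), brute_match(A, B, tau))
  }
})

test_that("delineation metrics reproduce the hand-worked example", {
  gt <- rbind(c(0, 0), c(0, 1), c(0, 2), c(0, 3)) + 5
  pred <- rbind(c(0, 0), c(0, 1), c(1, 5)) + 5
  m <- delineation_metrics(pred, gt, tau = 2)
  expect_equal(m$completeness, 3 / 4)   # gt (0,3) is at distance 2, unmatched
  expect_equal(m$correctness, 2 / 3)    # (1,5) is sqrt(5) >= 2 from gt
  expect_equal(m$quality, 0.5)
  o <- brute_metrics(pred, gt, 2)
  expect_equal(m$completeness, o$completeness)
  expect_equal(m$correctness, o$correctness)
  expect_equal(m$quality, o$quality)

  p <- delineation_metrics(gt, gt, tau = 1)
  expect_equal(c(p$completeness, p$correctness, p$quality), c(1, 1, 1))
})

test_that("degenerate skeleton pairs follow the documented conventions", {
  none <- matrix(0L, 4L, 4L)
  some <- matrix(0L, 4L, 4L); some[2L, 2L] <- 1L
  both_empty <- delineation_metrics(none, none, 2)
  expect_equal(both_empty$quality, 1)
  expect_true(both_empty$degenerate)
  expect_equal(delineation_metrics(none, some, 2)$quality, 0)
  expect_equal(delineation_metrics(some, none, 2)$quality, 0)
  expect_true(delineation_metrics(some, none, 2)$degenerate)
})

test_that("metric invariants hold on random skeleton pairs", {
  set.seed(13)
  for (i in 1:40) {
    A <- random_points(sample(2:40, 1L))
    B <- random_points(sample(2:40, 1L))
    taus <- c(1, 2, 3, 4)
    ms <- lapply(taus, function(t) delineation_metrics(A, B, t))
    # Quality never exceeds Correctness (shared numerator, denominator
    # inflated by the unexplained ground truth); it can exceed
    # Completeness when several predicted points match one gt point
    for (m in ms) {
      expect_lte(m$quality, m$correctness + 1e-12)
      expect_true(m$quality >= 0 && m$quality <= 1)
    }
    q <- vapply(ms, `[[`, numeric(1L), "quality")
    expect_true(all(diff(q) >= -1e-12))  # monotone in tau
    # translation invariance
    m0 <- ms[[2L]]
    mt <- delineation_metrics(A + 7, B + 7, 2)
    expect_equal(mt$quality, m0$quality)
  }
})

test_that("PR break-even behaves at the extremes and at chance", {
  gt <- matrix(0L, 64L, 64L)
  gt[20L, 10:50] <- 1L
  target <- dilate_centerline(gt)
  expect_equal(pr_breakeven(target + 0, gt)$breakeven, 1)     # perfect map
  expect_lte(pr_breakeven(1 - target, gt)$breakeven, 0.05)    # inverted map
  expect_error(pr_breakeven(matrix(0.5, 4, 4), matrix(0L, 4, 4)), "empty")

  # random scores: precision ~ prevalence at every threshold, so the
  # break-even sits near the target fraction q
  set.seed(3)
  gt2 <- matrix(rbinom(256 * 256, 1, 0.08), 256L)
  q <- mean(dilate_centerline(gt2))
  pr <- pr_breakeven(matrix(runif(256 * 256), 256L), gt2)
  expect_lte(abs(pr$breakeven - q), 0.05)
})

test_that("rater agreement is tolerance-monotone and asymmetric", {
  sk <- matrix(0L, 32L, 32L); sk[16L, 4:28] <- 1L
  expect_equal(unname(rater_agreement(sk, sk)), c(1, 1, 1))

  set.seed(5)
  a <- random_points(30, 30)
  b <- random_points(60, 30)
  qa <- rater_agreement(a, b, taus = c(1, 2, 3))
  expect_true(all(diff(qa) >= -1e-12))
  # |A| != |B| makes agreement direction-dependent in general
  qb <- rater_agreement(b, a, taus = c(1, 2, 3))
  expect_false(isTRUE(all.equal(unname(qa), unname(qb))))
})
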