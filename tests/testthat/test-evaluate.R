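# exhaustive set-count oracle for overlap scores
brute_overlap <- function(a, b) {
  A <- which(a == 1); B <- which(b == 1)
  inter <- length(intersect(A, B))
  uni <- length(union(A, B))
  list(
    dice = if (length(A) + length(B) == 0) 1
           else 2 * inter / (length(A) + length(B)),
    iou = if (uni == 0) 1 else inter / uni
  )
}

test_that("dice and iou match direct set counts on fixed cases", {
  a <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(dice(a, a), 1)
  expect_equal(iou(a, a), 1)

  b <- matrix(c(0, 0, 1, 1), 2, 2)
  expect_equal(dice(a, b), 0)
  expect_equal(iou(a, b), 0)

  # |A| = 2, |B| = 2, |A n B| = 1
  c2 <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(dice(a, c2), 0.5)
  # |A n B| = 1, |A u B| = 3
  expect_equal(iou(a, c2), 1 / 3)

  expect_equal(dice(a * 0, a * 0), 1)  # both empty
  expect_error(dice(a, matrix(0, 3, 3)), "shape")
})

test_that("dice/iou equal the exhaustive oracle and satisfy the
           algebraic identity on random masks", {
  set.seed(123)
  for (i in 1:1000) {
    pr <- random_mask_pair()
    d <- dice(pr$a, pr$b); j <- iou(pr$a, pr$b)
    o <- brute_overlap(pr$a, pr$b)
    expect_identical(d, o$dice)
    expect_identical(j, o$iou)
    expect_equal(j, d / (2 - d), tolerance = 1e-12)
    expect_identical(d, dice(pr$b, pr$a))  # symmetry
  }
})

test_that("dice_report separates volume and per-slice scores", {
  set.seed(9)
  p <- array(rbinom(4 * 4 * 3, 1, 0.4), dim = c(4, 4, 3))
  t <- array(rbinom(4 * 4 * 3, 1, 0.4), dim = c(4, 4, 3))
  rep <- dice_report(p, t)
  expect_equal(rep$volume_dice, dice(p, t))
  for (i in 1:3) {
    expect_equal(rep$per_slice_dice[i],
                 brute_overlap(p[, , i], t[, , i])$dice)
  }
  expect_equal(rep$slice_mean, mean(rep$per_slice_dice))

  same <- dice_report(t, t)
  expect_equal(same$volume_dice, 1)
  expect_true(all(same$per_slice_dice == 1))

  t2 <- t; t2[] <- 1L
  empty_pred <- dice_report(t * 0L, t2)
  expect_equal(empty_pred$volume_dice, 0)
  expect_true(all(empty_pred$per_slice_dice == 0))
})

test_that("quartile grouping distributes remainder slices bottom-up", {
  g8 <- quartile_groups(8)
  expect_equal(lengths(g8), c(2, 2, 2, 2))
  g10 <- quartile_groups(10)
  expect_equal(lengths(g10), c(3, 3, 2, 2))
  expect_equal(unlist(g10), 1:10)  # contiguous cover
  g4 <- quartile_groups(4)
  expect_equal(lengths(g4), c(1, 1, 1, 1))
  expect_error(quartile_groups(3), "at least 4")
})

test_that("Bland-Altman recovers bias and limits of agreement", {
  x <- c(10, 20, 30)
  same <- bland_altman(x, x)
  expect_equal(same$bias, 0)
  expect_equal(same$sd, 0)
  expect_equal(c(same$loa_low, same$loa_high), c(0, 0))

  off <- bland_altman(x, x + 2)
  expect_equal(off$bias, 2)
  expect_equal(off$sd, 0)

  # d = {+2, -2}: mean 0, sd sqrt(8) with the n-1 denominator
  ba <- bland_altman(c(0, 0), c(2, -2))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd, sqrt(8))
  expect_equal(ba$loa_high, 1.96 * sqrt(8))
  expect_equal(ba$loa_low, -1.96 * sqrt(8))

  expect_error(bland_altman(1:3, 1:4), "length")
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("Bland-Altman recovers injected differences in simulation", {
  set.seed(77)
  ref <- runif(500, 50, 150)
  d <- rnorm(500, mean = 3, sd = 5)
  ba <- bland_altman(ref, ref + d)
  expect_equal(ba$bias, mean(d))
  expect_equal(ba$sd, sd(d))
  expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * sd(d))
})

test_that("origin fit computes y = mx slope with Pearson correlation", {
  x <- c(1, 2, 3, 4)
  f2 <- origin_fit(x, 2 * x)
  expect_equal(f2$slope, 2)
  expect_equal(f2$r, 1)

  fm <- origin_fit(x, -x)
  expect_equal(fm$slope, -1)
  expect_equal(fm$r, -1)

  # hand oracle: m = sum(xy)/sum(x^2) = 29/14; r by the raw formula
  x3 <- c(1, 2, 3); y3 <- c(2, 3, 7)
  f3 <- origin_fit(x3, y3)
  expect_equal(f3$slope, 29 / 14)
  r_brute <- sum((x3 - mean(x3)) * (y3 - mean(y3))) /
    sqrt(sum((x3 - mean(x3))^2) * sum((y3 - mean(y3))^2))
  expect_equal(f3$r, r_brute)

  expect_error(origin_fit(c(0, 0), c(1, 2)), "degenerate")
})

test_that("origin fit recovers a generating slope under noise", {
  set.seed(31)
  x <- runif(200, 10, 200)
  y <- 0.97 * x + rnorm(200, sd = 8)
  f <- origin_fit(x, y)
  # sampling sd of the through-origin slope estimate
  se <- 8 / sqrt(sum(x^2))
  expect_lt(abs(f$slope - 0.97), 2 * se)
  expect_gt(f$r, 0.95)
})

test_that("percent error is signed and summarised over cohorts", {
  expect_equal(percent_error(100, 100), 0)
  expect_equal(percent_error(110, 100), 10)
  expect_equal(percent_error(95, 100), -5)
  co <- percent_error(c(110, 95), c(100, 100))
  expect_equal(co$percent, c(10, -5))
  expect_equal(co$mean, 2.5)
  expect_error(percent_error(10, 0), "positive")
})

test_that("paired t handles identity, degeneracy and a hand-formula case", {
  x <- c(1, 2, 3, 4)
  same <- paired_t(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_error(paired_t(x + 1, x), "degenerate")

  d <- c(2, -2, 2, -2, 2)
  got <- paired_t(d, rep(0, 5))
  t_brute <- mean(d) / (sd(d) / sqrt(5))
  p_brute <- 2 * pt(-abs(t_brute), df = 4)
  expect_equal(got$t, t_brute)
  expect_equal(got$p, p_brute)
  expect_equal(got$mean_diff, mean(d))
})
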