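test_that("attention window maps HU to 8-bit with round-half-up", {
  spec <- window_spec(350, 40)
  expect_equal(spec$lo, -135)
  expect_equal(spec$hi, 215)
  v <- array(c(-135, 215, 40, -1000, 1000), dim = c(5, 1, 1))
  got <- hu_window_to_8bit(v, spec)
  # 40 HU: (40 + 135)/350 * 255 = 127.5 -> 128 under round-half-up
  expect_equal(as.vector(got), c(0L, 255L, 128L, 0L, 255L))
})

test_that("windowing is monotone over a full HU sweep", {
  hu <- array(seq(-1200, 1200, by = 0.5), dim = c(4801, 1, 1))
  v8 <- hu_window_to_8bit(hu, window_spec())
  expect_true(all(diff(as.vector(v8)) >= 0))
  expect_true(all(v8 >= 0L & v8 <= 255L))
})

test_that("bisect plan sequences each half toward the middle", {
  p6 <- bisect_plan(6)
  expect_equal(p6$k, c(1, 2, 3, 6, 5, 4))
  expect_equal(p6$s, c(1, 1, 1, -1, -1, -1))
  expect_equal(attr(p6, "split"), 3L)

  # odd count: lower half gets floor(n/2) slices
  p7 <- bisect_plan(7)
  expect_equal(p7$k, c(1, 2, 3, 7, 6, 5, 4))
  expect_equal(p7$s, c(1, 1, 1, -1, -1, -1, -1))

  expect_error(bisect_plan(2), "at least 3")
})

test_that("bisect plan is an exactly-once permutation for all n", {
  for (n in 3:40) {
    p <- bisect_plan(n)
    expect_equal(sort(p$k), 1:n)
    split <- attr(p, "split")
    lower <- p[seq_len(split), ]
    upper <- p[-seq_len(split), ]
    expect_true(all(lower$s == 1))
    expect_true(all(diff(lower$k) == 1))
    expect_true(all(upper$s == -1))
    expect_true(all(diff(upper$k) == -1))
    expect_equal(upper$k[1], n)
  }
})

test_that("slab assembly stacks (k, k+s, k+2s) and clamps at borders", {
  v8 <- array(0L, dim = c(4, 4, 6))
  for (i in 1:6) v8[, , i] <- i  # slice index as fill value
  s1 <- assemble_slab(v8, k = 3, s = 1)
  expect_equal(unique(as.vector(s1[, , 1])), 3)
  expect_equal(unique(as.vector(s1[, , 2])), 4)
  expect_equal(unique(as.vector(s1[, , 3])), 5)  # crosses the midline

  s2 <- assemble_slab(v8, k = 6, s = -1)
  expect_equal(sapply(1:3, function(ch) unique(as.vector(s2[, , ch]))),
               c(6, 5, 4))

  s3 <- assemble_slab(v8[, , 1:3], k = 1, s = 1)
  expect_equal(sapply(1:3, function(ch) unique(as.vector(s3[, , ch]))),
               c(1, 2, 3))

  # look-ahead beyond the extent border replicates the nearest slice
  s4 <- assemble_slab(v8, k = 6, s = 1)
  expect_equal(sapply(1:3, function(ch) unique(as.vector(s4[, , ch]))),
               c(6, 6, 6))
  expect_error(assemble_slab(v8, k = 7, s = 1), "outside")
})

test_that("physical median kernel follows the mm-to-voxel rule", {
  # spacing (0.7, 0.7, 2.5) with a 3 mm kernel: 5 x 5 x 1 voxels
  set.seed(2)
  v <- ct_volume(array(rnorm(10 * 10 * 4), dim = c(10, 10, 4)),
                 spacing = c(0.7, 0.7, 2.5))
  expect_message(median_filter_mm(v, 3), "\\(5, 5, 1\\)")
  expect_message(median_filter_mm(v, 3), "in-plane only")
})

test_that("median filter matches a brute-force oracle and removes impulses", {
  set.seed(7)
  v <- ct_volume(array(round(rnorm(7 * 7 * 3, 0, 50)), dim = c(7, 7, 3)),
                 spacing = c(1, 1, 1))
  got <- median_filter_mm(v, 3, quiet = TRUE)
  expect_equal(got$voxels, brute_median3d(v$voxels, c(3L, 3L, 3L)))

  # constant volume unchanged
  cv <- ct_volume(array(-100, dim = c(6, 6, 3)), spacing = c(1, 1, 1))
  expect_equal(median_filter_mm(cv, 3, quiet = TRUE)$voxels, cv$voxels)

  # lone +1000 HU impulse in a -100 HU background is erased
  imp <- cv
  imp$voxels[3, 3, 2] <- 1000
  expect_equal(median_filter_mm(imp, 3, quiet = TRUE)$voxels, cv$voxels)
})

test_that("median filter commutes with global HU shifts", {
  set.seed(8)
  v <- array(round(rnorm(8 * 8 * 3, 0, 30)), dim = c(8, 8, 3))
  a <- median_filter_mm(ct_volume(v, c(1, 1, 1)), 3, quiet = TRUE)$voxels
  b <- median_filter_mm(ct_volume(v + 57, c(1, 1, 1)), 3,
                        quiet = TRUE)$voxels
  expect_equal(b, a + 57)
})
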