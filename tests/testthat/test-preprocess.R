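test_that("mean filter matches the brute-force oracle and its closed forms", {
  # constant volume is a fixed point
  cv <- volume3d(array(3.5, c(5, 6, 4)))
  expect_equal(denoise_mean3(cv)$data, cv$data)
  # single interior spike of 27 spreads to its 27-neighbourhood as ones
  z <- array(0, c(7, 7, 7)); z[4, 4, 4] <- 27
  f <- denoise_mean3(z)
  expect_equal(f[3:5, 3:5, 3:5], array(1, c(3, 3, 3)))
  expect_equal(sum(f), 27)  # linearity preserves mass away from borders
  # random volume equals the triple-loop oracle (including reflected borders)
  set.seed(4)
  r <- array(rnorm(8^3), c(8, 8, 8))
  expect_equal(denoise_mean3(r), brute_mean3(r), tolerance = 1e-12)
})

test_that("mean filter output stays within the input range and is linear", {
  set.seed(5)
  a <- array(runif(6^3), c(6, 6, 6))
  b <- array(runif(6^3), c(6, 6, 6))
  fa <- denoise_mean3(a)
  expect_gte(min(fa), min(a)); expect_lte(max(fa), max(a))
  expect_equal(denoise_mean3(2 * a + 3 * b), 2 * fa + 3 * denoise_mean3(b),
               tolerance = 1e-12)
})

test_that("intensity standardization reaches the target moments and is affine-invariant", {
  set.seed(6)
  v <- volume3d(array(rnorm(5^3, 10, 4), c(5, 5, 5)))
  s <- normalize_intensity(v)
  expect_equal(mean(s$data), 0, tolerance = 1e-12)
  expect_equal(mean(s$data^2), 1, tolerance = 1e-12)
  expect_equal(normalize_intensity(s)$data, s$data, tolerance = 1e-12)
  w <- volume3d(v$data * 7 - 2, v$spacing_mm)
  expect_equal(normalize_intensity(w)$data, s$data, tolerance = 1e-10)
  s2 <- normalize_intensity(v, ref_mean = 5, ref_var = 4)
  expect_equal(mean(s2$data), 5, tolerance = 1e-12)
  expect_equal(mean((s2$data - 5)^2), 4, tolerance = 1e-12)
  expect_error(normalize_intensity(volume3d(array(1, c(3, 3, 3)))),
               "variance")
})

test_that("z-flip is an involution that records orientation", {
  set.seed(7)
  v <- volume3d(array(rnorm(4 * 5 * 6), c(4, 5, 6)))
  f <- flip_z(v)
  expect_true(f$flipped_z)
  expect_equal(f$data[1, , ], v$data[4, , ])
  expect_identical(flip_z(f)$data, v$data)
  expect_false(flip_z(f)$flipped_z)
  ramp <- array(rep(1:4, 5 * 6), c(4, 5, 6))
  expect_equal(flip_z(ramp)[, 1, 1], 4:1)
})

test_that("bbox cropping clamps the buffer at the volume border", {
  v <- volume3d(array(seq_len(64^3), c(64, 64, 64)))
  full <- rbind(lo = c(1, 1, 1), hi = c(64, 64, 64))
  expect_identical(crop_to_bbox(v, full, 0)$data, v$data)
  bb <- rbind(lo = c(11, 11, 11), hi = c(20, 20, 20))
  out <- crop_to_bbox(v, bb, 25)
  expect_equal(dim(out$data), c(45, 45, 45))
  expect_equal(out$data[1, 1, 1], v$data[1, 1, 1])
  expect_error(crop_to_bbox(v, rbind(c(5, 5, 5), c(4, 4, 4))), "bbox")
})

test_that("cropping to the foreground bbox keeps every foreground voxel", {
  fx <- phantom_set(1, grid = 24, seed = 31, denoise = FALSE)
  lab <- fx$pairs[[1]]$labels
  bb <- foreground_bbox(lab)
  cropped <- crop_to_bbox(lab, bb, 0)
  expect_equal(sum(cropped$data != 0), sum(lab$data != 0))
})
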