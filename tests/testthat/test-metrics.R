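test_that("Dice handles identity, hand-counted overlap and empty-label conventions", {
  A <- array(0L, c(4, 4, 4)); A[1:2, 1:2, 1] <- 1L     # 4 voxels
  B <- array(0L, c(4, 4, 4)); B[1:2, 2:3, 1] <- 1L     # 4 voxels, overlap 2
  d <- dice(A, B, label_ids = 1L)
  expect_equal(unname(d$per_label["1"]), 0.5)
  expect_equal(d$total, 0.5)
  expect_equal(dice(A, A, label_ids = 1L)$total, 1)
  d2 <- dice(A, B, label_ids = c(1L, 2L))              # label 2 absent both
  expect_equal(unname(d2$per_label["2"]), 1)
  expect_equal(d2$empty_labels, 2L)
  expect_error(dice(A, array(0L, c(3, 4, 4))), "shape")
})

test_that("ASSD closed forms: identity and two isolated voxels", {
  A <- array(0L, c(9, 5, 5)); A[2, 3, 3] <- 1L
  B <- array(0L, c(9, 5, 5)); B[5, 3, 3] <- 1L
  a <- assd(A, B, label_ids = 1L)
  expect_equal(unname(a$per_label["1"]), 3)
  expect_equal(a$total, 3)
  expect_equal(assd(A, A, label_ids = 1L)$total, 0)
  # label empty on exactly one side is undefined and flagged
  C <- array(0L, c(9, 5, 5))
  u <- assd(A, C, label_ids = 1L)
  expect_true(is.na(u$per_label["1"]))
  expect_equal(u$undefined_labels, 1L)
  # empty on both sides contributes zero
  expect_equal(assd(C, C, label_ids = 1L)$per_label[["1"]], 0)
})

test_that("Dice and ASSD agree with brute-force oracles on random volumes", {
  for (s in 1:25) {
    rp <- random_label_pair(dmax = 10, k = 3, seed = s)
    d <- dice(rp$A, rp$B, label_ids = rp$ids)
    bd <- brute_dice(rp$A, rp$B, rp$ids)
    expect_identical(unname(d$per_label), unname(bd$per_label))
    expect_identical(d$total, bd$total)
    a <- assd(rp$A, rp$B, label_ids = rp$ids)
    ba <- brute_assd(rp$A, rp$B, rp$ids)
    expect_equal(unname(a$per_label), unname(ba$per_label), tolerance = 1e-9)
    expect_equal(a$total, ba$total, tolerance = 1e-9)
  }
})

test_that("both metrics are symmetric and Dice grows with overlap", {
  rp <- random_label_pair(dmax = 9, k = 2, seed = 99)
  expect_equal(dice(rp$A, rp$B, rp$ids)$total, dice(rp$B, rp$A, rp$ids)$total)
  expect_equal(assd(rp$A, rp$B, rp$ids)$total, assd(rp$B, rp$A, rp$ids)$total)
  # growing overlap at fixed sizes never decreases Dice
  A <- array(0L, c(6, 6, 6)); A[1:3, 1:3, 1] <- 1L
  dices <- sapply(0:2, function(shift) {
    B <- array(0L, c(6, 6, 6)); B[1:3, (3 - shift):(5 - shift), 1] <- 1L
    dice(A, B, 1L)$total
  })
  expect_true(all(diff(dices) >= 0))
})

test_that("error triage categories follow the published error bands", {
  expect_equal(error_category(1.0)$category, "negligible")
  e1 <- error_category(0.987)
  expect_equal(e1$error_pct, 1.3, tolerance = 1e-9)
  expect_equal(e1$category, "slight")
  e2 <- error_category(0.877)
  expect_equal(e2$error_pct, 12.3, tolerance = 1e-9)
  expect_equal(e2$category, "flawed")
  expect_equal(error_category(1 - 0.00005 / 100)$category, "negligible")
  expect_error(error_category(1.2), "0, 1")
})

test_that("evaluate_segmentation composes metrics consistently", {
  rp <- random_label_pair(dmax = 8, k = 2, seed = 5)
  ev <- evaluate_segmentation(label_volume(rp$A, spacing_mm = 0.01),
                              label_volume(rp$B, spacing_mm = 0.01))
  expect_equal(ev$total_dice, dice(rp$A, rp$B, 1:6)$total)
  expect_equal(ev$error_pct, (1 - ev$total_dice) * 100)
  expect_equal(ev$total_assd_mm, ev$total_assd * 0.01)
})
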