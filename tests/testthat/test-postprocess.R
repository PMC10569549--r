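mk_lab <- function(d = c(20, 20, 20)) array(0L, d)

test_that("island removal follows the fractional threshold rule and idempotence", {
  A <- mk_lab()
  A[1:5, 1:5, 1:4] <- 1L                 # 100-voxel component
  A[15, 15, 15] <- 1L                    # 1-voxel satellite
  A[18:19, 18, 18] <- 1L                 # 2-voxel satellite
  A[1:5, 12:16, 1:4] <- 1L               # second 100-voxel body (paired-like)
  lv <- label_volume(A)
  out <- remove_islands(lv, threshold = 0.1)
  expect_equal(sum(out$data == 1), 200)  # both large bodies kept, satellites gone
  expect_identical(remove_islands(out, 0.1)$data, out$data)
  # threshold semantics: a 5-voxel island against a 100-voxel main body
  B <- mk_lab(); B[1:5, 1:5, 1:4] <- 2L; B[12:16, 12, 12] <- 2L
  out2 <- remove_islands(label_volume(B), threshold = 0.1)
  expect_equal(sum(out2$data == 2), 100)  # 5 < 0.1 * 100 -> removed
  B2 <- mk_lab(); B2[1:5, 1:5, 1:4] <- 2L; B2[12:16, 12:13, 1:1] <- 2L
  out3 <- remove_islands(label_volume(B2), threshold = 0.1)
  expect_equal(sum(out3$data == 2), 110)  # 10 >= 0.1 * 100 -> kept
})

test_that("two equal components of a paired neuropil are both kept", {
  A <- mk_lab()
  A[1:4, 1:4, 1:4] <- 1L
  A[10:13, 10:13, 10:13] <- 1L
  out <- remove_islands(label_volume(A), threshold = 0.1)
  expect_equal(sum(out$data == 1), 128)
})

test_that("excluded labels pass through untouched and removal never grows labels", {
  A <- mk_lab()
  A[5:8, 5:8, 5:8] <- 3L       # CX body
  A[15, 15, 15] <- 3L          # CX satellite: excluded by default
  out <- remove_islands(label_volume(A), threshold = 0.1)
  expect_equal(sum(out$data == 3), 65)
  out2 <- remove_islands(label_volume(A), threshold = 0.1, exclude = character(0))
  expect_equal(sum(out2$data == 3), 64)
  expect_lte(sum(out2$data != 0), sum(A != 0))
})

test_that("left/right split assigns disjoint components by centroid side", {
  A <- mk_lab()
  A[8:12, 8:12, 3:6] <- 1L      # left AL (low x)
  A[8:12, 8:12, 15:18] <- 1L    # right AL
  s <- split_left_right(label_volume(A), paired = "AL")
  expect_true(s$separable)
  expect_equal(s$left, s$right)
  expect_equal(s$left + s$right, sum(A == 1))
})

test_that("a single component spanning the midline is flagged non-separable", {
  A <- mk_lab()
  A[8:12, 8:12, 3:18] <- 2L     # merged MB across the midline
  A[8:12, 2:4, 3:6] <- 1L; A[8:12, 2:4, 15:18] <- 1L
  s <- split_left_right(label_volume(A), paired = c("AL", "MB"))
  expect_false(s$separable[s$label == "MB"])
  expect_true(is.na(s$left[s$label == "MB"]))
  expect_true(s$separable[s$label == "AL"])
})

test_that("a blob entirely on one side counts fully left", {
  A <- mk_lab()
  A[5:10, 5:10, 2:5] <- 4L
  A[3:6, 3:6, 15:17] <- 5L      # other paired label on the right fixes midline
  s <- split_left_right(label_volume(A), paired = c("ME", "LO"))
  me <- s[s$label == "ME", ]
  expect_equal(me$left, sum(A == 4)); expect_equal(me$right, 0)
  expect_warning(split_left_right(label_volume(mk_lab()), paired = "AL"),
                 "no paired-label voxels")
})

test_that("volume measurement is voxel count times cubed spacing with consistent derived columns", {
  A <- mk_lab()
  A[1:10, 1:10, 1:10] <- 6L            # 1000 voxels of OTH
  A[1:2, 12:13, 1:2] <- 1L; A[1:2, 12:13, 15:16] <- 1L
  A[3:4, 15:16, 1:2] <- 4L; A[3:4, 15:16, 15:16] <- 4L
  A[6:7, 15:16, 1:2] <- 5L; A[6:7, 15:16, 15:16] <- 5L
  A[10:11, 15:16, 1:2] <- 2L; A[10:11, 15:16, 15:16] <- 2L
  A[15, 15, 10] <- 3L
  lv <- label_volume(A, spacing_mm = 0.0054)
  rec <- measure_volumes(lv, meta = list(specimen = "t1", hive = "H1"))
  expect_equal(rec$OTH, 1000 * 0.0054^3, tolerance = 1e-15)
  expect_equal(rec$OTH, 1.57464e-4, tolerance = 1e-9)
  expect_equal(rec$total, rec$AL + rec$MB + rec$CX + rec$ME + rec$LO + rec$OTH)
  expect_equal(rec$OL, rec$ME + rec$LO)
  expect_equal(rec$AL_left + rec$AL_right, rec$AL)
  rel <- rec$AL_rel + rec$MB_rel + rec$OL_rel + rec$CX_rel + rec$OTH_rel
  expect_equal(rel, 100)
  expect_error(suppressWarnings(measure_volumes(label_volume(mk_lab()))),
               "empty")
})

test_that("measurement is invariant to axis permutation of the grid", {
  fx <- phantom_set(1, grid = 24, seed = 31, denoise = FALSE)
  lv <- fx$pairs[[1]]$labels
  r1 <- measure_volumes(lv)
  lv2 <- label_volume(aperm(lv$data, c(2, 3, 1)), lv$labels, lv$spacing_mm)
  r2 <- measure_volumes(lv2)
  for (r in c("AL", "MB", "CX", "ME", "LO", "OTH", "total"))
    expect_equal(r1[[r]], r2[[r]])
})

test_that("ground-truth phantom labels measure back to the generator's achieved volumes", {
  fx <- phantom_set(2, grid = 24, seed = 31, denoise = FALSE)
  for (p in fx$pairs) {
    rec <- measure_volumes(p$labels)
    for (r in c("AL", "MB", "CX", "ME", "LO", "OTH"))
      expect_equal(rec[[r]], unname(p$achieved[r]))
    if (rec$mb_separable && !p$merged_mb) {
      sp3 <- p$labels$spacing_mm^3
      expect_equal(rec$ME_left, unname(p$sides$ME["left"]) * sp3)
    }
  }
})
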