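test_that("degenerate draws: zero CVs, zero deficit, no hive effect give identical symmetric specimens", {
  pp <- phantom_params(neuropil_cv = c(AL = 0, MB = 0, CX = 0, ME = 0,
                                       LO = 0, OTH = 0),
                       lateral_noise_cv = 0, hive_sigma = 0, seed = 2)
  co <- sample_cohort(pp, hive_plan = c(H1 = 5, H2 = 5))
  for (r in c("AL", "MB", "CX", "ME", "LO", "OTH"))
    expect_equal(var(co[[r]]), 0)
  expect_equal(co$AL_left, co$AL_right)
  expect_equal(co$ME_left, co$ME_right)
  expect_equal(co$AL, species_preset("honeybee")$means[["AL"]] + 0 * co$AL)
})

test_that("a pure lateral deficit with no noise gives the exact left/right ratio", {
  pp <- phantom_params(lateral_delta = c(OL = 0.05), lateral_noise_cv = 0,
                       seed = 5)
  co <- sample_cohort(pp, hive_plan = c(H1 = 10))
  expect_equal(co$ME_left, 0.95 * co$ME_right, tolerance = 1e-12)
  expect_equal(co$LO_left, 0.95 * co$LO_right, tolerance = 1e-12)
  # OL named deficit must not touch the antennal lobes
  expect_equal(mean(log(co$AL_left / co$AL_right)), 0, tolerance = 1e-12)
})

test_that("cohort sampling recovers the preset parameters at n = 1000", {
  # hive effects off: with them the draws are clustered and the naive
  # standard error of the mean would not apply
  pp <- phantom_params(seed = 7, lateral_delta = c(ME = 0.03),
                       lateral_noise_cv = 0.05, hive_sigma = 0)
  co <- sample_cohort(pp, hive_plan = c(A = 500, B = 500))
  pre <- species_preset("honeybee")
  for (r in names(pre$means)) {
    se <- sd(co[[r]]) / sqrt(nrow(co))
    expect_lt(abs(mean(co[[r]]) - pre$means[[r]]), 2 * se + 1e-12)
  }
  lr <- log(co$ME_left / co$ME_right)
  expect_lt(abs(mean(lr) - log(1 - 0.03)), 2 * sd(lr) / sqrt(nrow(co)))
})

test_that("cohorts and phantoms are bit-identical under identical seeds", {
  pp <- phantom_params(grid_shape = c(20, 20, 20), seed = 9)
  co1 <- sample_cohort(pp, hive_plan = c(H1 = 3))
  co2 <- sample_cohort(pp, hive_plan = c(H1 = 3))
  expect_identical(co1, co2)
  p1 <- render_phantom(co1[1, ], pp, seed = 42)
  p2 <- render_phantom(co2[1, ], pp, seed = 42)
  expect_identical(p1$image$data, p2$image$data)
  expect_identical(p1$labels$data, p2$labels$data)
})

test_that("invalid generator parameters are rejected", {
  expect_error(phantom_params(neuropil_cv = c(AL = -0.1, MB = 1, CX = 1,
                                              ME = 1, LO = 1, OTH = 1)),
               "CV")
  expect_error(phantom_params(lateral_delta = c(AL = 1)), "delta")
  pp <- phantom_params()
  expect_error(sample_cohort(pp, hive_plan = integer(0)), "empty|named")
  expect_error(sample_cohort(pp, n_specimens = 5, hive_plan = c(H1 = 4)),
               "equal")
})

test_that("rendered labels conserve voxels and record voxel-true volumes", {
  fx <- phantom_set(2, grid = 24, seed = 31, denoise = FALSE)
  for (p in fx$pairs) {
    lab <- p$labels$data
    tab <- tabulate(lab + 1L, nbins = 7)
    expect_equal(sum(tab), 24^3)                     # conservation
    sp3 <- fx$params$spacing_mm^3
    for (k in 1:6) {
      nm <- neuropil_labels()$name[k]
      expect_equal(tab[k + 1] * sp3, unname(p$achieved[nm]))
    }
  }
})

test_that("noise-free, blur-free rendering has exactly |labels| + 1 intensities", {
  pp <- phantom_params(grid_shape = c(24, 24, 24), noise_sd = 0,
                       blur_sigma = 0, seed = 13)
  co <- sample_cohort(pp, hive_plan = c(H1 = 1))
  ph <- render_phantom(co[1, ], pp)
  expect_equal(length(unique(as.vector(ph$image$data))), 7)
})

test_that("forced mushroom-body merge yields one 26-connected component across the midline", {
  pp <- phantom_params(grid_shape = c(32, 32, 32), p_merge_mb = 1, seed = 17)
  co <- sample_cohort(pp, hive_plan = c(H1 = 2))
  for (i in 1:2) {
    ph <- render_phantom(co[i, ], pp)
    expect_true(ph$merged_mb)
    mb <- ph$labels$data == 2L
    cc <- hivemorph:::.cc26_cpp(as.integer(mb), dim(mb))
    expect_equal(length(attr(cc, "sizes")), 1)
    xs <- ((which(mb) - 1) %/% (32 * 32)) + 1
    mid <- (32 + 1) / 2
    expect_gt(sum(xs < mid), 0)
    expect_gt(sum(xs > mid), 0)
  }
})

test_that("structures that cannot fit the grid raise a named render error", {
  pp <- phantom_params(grid_shape = c(16, 16, 16), fill_fraction = 0.9,
                       seed = 3)
  co <- sample_cohort(pp, hive_plan = c(H1 = 1))
  expect_error(render_phantom(co[1, ], pp), "overflow")
})

test_that("cohort tables normalize relative volumes and honour the side split", {
  pp <- phantom_params(seed = 23)
  co <- sample_cohort(pp, hive_plan = c(H1 = 3))
  tab <- cohort_to_table(co)
  expect_equal(nrow(tab), 3)
  rel <- tab$AL_rel + tab$MB_rel + tab$OL_rel + tab$CX_rel + tab$OTH_rel
  expect_equal(rel, rep(100, 3))
  expect_equal(tab$OL, tab$ME + tab$LO)
  expect_equal(tab$total, tab$AL + tab$MB + tab$CX + tab$ME + tab$LO + tab$OTH)
  # degenerate cohort: left equals right in the table too
  pp0 <- phantom_params(lateral_noise_cv = 0, seed = 2)
  t0 <- cohort_to_table(sample_cohort(pp0, hive_plan = c(H1 = 3)))
  expect_equal(t0$AL_left, t0$AL_right)
})

test_that("large-cohort mean relative AL volume matches the preset-implied value", {
  pp <- phantom_params(seed = 29, hive_sigma = 0.01)
  tab <- cohort_to_table(sample_cohort(pp, hive_plan = c(H1 = 1000)))
  pre <- species_preset("honeybee")
  implied <- 100 * pre$means[["AL"]] / sum(pre$means)
  expect_lt(abs(mean(tab$AL_rel) - implied), 0.2)
})
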