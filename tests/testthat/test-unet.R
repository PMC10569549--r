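test_that("backpropagation matches finite-difference gradients", {
  cfg <- net_config(patch_size = 8, stride = 8, scaled_shape = c(8, 8, 8),
                    base_channels = 2, max_channels = 8, epochs = 1,
                    batch_size = 2, n_labels = 3, seed = 7)
  m <- build_unet(cfg)
  set.seed(1)
  B <- 2; N <- 8^3
  X <- matrix(rnorm(B * N), B * N, 1)
  y <- sample(1:3, B * N, replace = TRUE)
  loss_of <- function(mm) {
    fw <- hivemorph:::unet_fwd(mm, X, rep(8L, 3), B, training = TRUE)
    hivemorph:::softmax_ce(fw$logits, y)$loss
  }
  fw <- hivemorph:::unet_fwd(m, X, rep(8L, 3), B, training = TRUE)
  ce <- hivemorph:::softmax_ce(fw$logits, y)
  gr <- hivemorph:::unet_bwd(m, ce$dZ, fw, rep(8L, 3), B)
  for (nm in c("enc1a_W", "enc2a_W", "enc3b_W", "dec2a_W", "dec1b_W",
               "enc1a_g", "dec1a_b", "out_W", "out_b")) {
    for (t in 1:2) {
      ix <- sample(length(m$params[[nm]]), 1)
      m2 <- m; m2$params[[nm]][ix] <- m$params[[nm]][ix] + 1e-5
      m3 <- m; m3$params[[nm]][ix] <- m$params[[nm]][ix] - 1e-5
      num <- (loss_of(m2) - loss_of(m3)) / 2e-5
      ana <- gr[[nm]][ix]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-5)
    }
  }
})

test_that("architecture follows the doubling-channel contract", {
  cfg32 <- net_config(patch_size = 32, base_channels = 32, max_channels = 1024,
                      scaled_shape = c(64, 64, 64), stride = 32)
  expect_equal(cfg32$levels, 6)          # 32,64,128,256,512,1024
  cfg512 <- net_config(patch_size = 32, base_channels = 32, max_channels = 512,
                       scaled_shape = c(64, 64, 64), stride = 32)
  expect_equal(cfg512$levels, cfg32$levels - 1)
  m <- build_unet(net_config(patch_size = 8, base_channels = 2,
                             max_channels = 4, stride = 8,
                             scaled_shape = c(8, 8, 8), n_labels = 1))
  expect_equal(ncol(m$params$out_W), 1)  # single output channel
  expect_equal(dim(m$params$enc2a_W), c(27 * 2, 4))
  expect_error(net_config(patch_size = 8, base_channels = 8, max_channels = 12),
               "2\\^k")
  expect_error(net_config(patch_size = 20, base_channels = 4,
                          max_channels = 32), "divisible")
})

test_that("patch extraction produces the documented grids", {
  big <- array(0, c(256, 256, 256))
  ep <- extract_patches(big, 64, 32)
  expect_equal(nrow(ep$offsets), 343)    # 7 positions per axis
  expect_equal(ep$pad, c(0, 0, 0))
  ep2 <- extract_patches(array(0, c(64, 64, 64)), 64, 64)
  expect_equal(nrow(ep2$offsets), 1)
  ep3 <- extract_patches(big, 64, 64)
  expect_equal(nrow(ep3$offsets), 64)    # non-overlapping tiling
  ep4 <- extract_patches(array(0, c(42, 42, 42)), 16, 8)
  expect_equal(ep4$padded_dim, c(48, 48, 48))
  ep5 <- extract_patches(array(0, c(40, 40, 40)), 16, 8)
  expect_equal(ep5$padded_dim, c(40, 40, 40))  # already a stride multiple
  expect_error(extract_patches(array(0, c(8, 8, 8)), 16, 32), "stride")
  rm(big)
})

test_that("non-overlapping stitching equals per-patch argmax reassembly exactly", {
  fx <- tiny_model()
  m <- fx$model
  img <- fx$fx$pairs[[3]]$image
  pred <- predict_volume(m, img, stride = 8)$data
  # manual reassembly
  p <- hivemorph:::prep_pair(img, NULL, m$cfg)
  ep <- extract_patches(p$img, 8, 8)
  manual <- array(0L, ep$padded_dim)
  for (r in seq_len(nrow(ep$offsets))) {
    off <- ep$offsets[r, ]
    patch <- hivemorph:::get_patch(ep$padded, off, 8)
    fw <- hivemorph:::unet_fwd(m, matrix(as.vector(patch)), rep(8L, 3), 1)
    cls <- max.col(fw$logits, ties.method = "first") - 1L
    manual[off[1]:(off[1] + 7), off[2]:(off[2] + 7), off[3]:(off[3] + 7)] <-
      array(cls, c(8, 8, 8))
  }
  manual <- hivemorph:::unpad(manual, dim(img$data))
  expect_identical(pred, manual)
})

test_that("training is deterministic, tracks history and keeps the best epoch", {
  fx <- tiny_model()
  m <- fx$model
  expect_equal(nrow(m$history), fx$cfg$epochs)
  vd <- m$history$val_dice
  expect_equal(max(vd, na.rm = TRUE), vd[m$best_epoch])
  m2 <- train_unet(fx$fx$pairs[1:2], fx$fx$pairs[3], fx$cfg)
  expect_identical(m$history, m2$history)
  expect_identical(m$params, m2$params)
  # config errors
  expect_error(train_unet(list(), list(), fx$cfg), "at least one")
  expect_error(train_unet(fx$fx$pairs[1], list(), fx$cfg), "validation")
  bad <- fx$fx$pairs[[1]]
  bad$labels <- label_volume(array(1L, dim(bad$labels$data)),
                             data.frame(id = 1, name = "X", paired = FALSE),
                             bad$labels$spacing_mm)
  cfg1 <- fx$cfg; cfg1$n_labels <- 1L
  expect_error(train_unet(list(bad), fx$fx$pairs[3], cfg1), "label id")
})

test_that("overfit on a single phantom reaches high self-Dice", {
  fx <- phantom_set(1, grid = 16, seed = 41)
  cfg <- net_config(patch_size = 8, stride = 4, scaled_shape = c(16, 16, 16),
                    base_channels = 8, max_channels = 32, epochs = 60,
                    batch_size = 4, val_freq = 10, n_labels = 7, seed = 2)
  m <- train_unet(fx$pairs[1], fx$pairs[1], cfg)
  pred <- predict_volume(m, fx$pairs[[1]]$image)
  expect_gt(dice(pred, fx$pairs[[1]]$labels)$total, 0.95)
})

test_that("prediction contract: shapes, label range, determinism", {
  fx <- tiny_model()
  noisevol <- volume3d(array(rnorm(16^3), c(16, 16, 16)))
  out <- predict_volume(fx$model, noisevol)
  expect_equal(dim(out$data), c(16, 16, 16))
  expect_true(all(out$data %in% 0:6))
  out2 <- predict_volume(fx$model, noisevol)
  expect_identical(out$data, out2$data)
  expect_error(predict_volume(build_unet(fx$cfg), noisevol), "not trained")
})

test_that("label scaling round-trip preserves majority structure", {
  fx <- phantom_set(1, grid = 96, seed = 51, denoise = FALSE)
  lab <- fx$pairs[[1]]$labels$data
  down <- resize_array(lab, c(64, 64, 64), "nearest")
  up <- resize_array(down, c(96, 96, 96), "nearest")
  expect_gt(dice(lab, up, label_ids = 1:6)$total, 0.9)
})

test_that("encoder fine-tuning freezes the decoder and head", {
  fx <- tiny_model()
  newfx <- phantom_set(2, grid = 16, seed = 61)
  cfg <- fx$cfg; cfg$epochs <- 2L
  ft <- finetune_encoder(fx$model, newfx$pairs[1], newfx$pairs[2], cfg)
  for (nm in names(ft$params)) {
    if (grepl("^enc", nm)) next
    expect_identical(ft$params[[nm]], fx$model$params[[nm]])
  }
  changed <- any(vapply(grep("^enc.*_W$", names(ft$params), value = TRUE),
                        function(nm) !identical(ft$params[[nm]],
                                                fx$model$params[[nm]]),
                        logical(1)))
  expect_true(changed)
  expect_lt(attr(ft$history, "trainable_parameters"),
            attr(ft$history, "total_parameters"))
  expect_error(finetune_encoder(fx$model, list(), newfx$pairs[2], cfg),
               "at least one")
})

test_that("learning curve validates inputs and is reproducible", {
  fx <- tiny_model()
  cfg <- fx$cfg; cfg$epochs <- 2L
  expect_error(learning_curve(fx$fx$pairs[1:2], c(0, 1), fx$fx$pairs[3],
                              fx$fx$pairs[3], cfg), ">= 1")
  expect_error(learning_curve(fx$fx$pairs[1:2], 3, fx$fx$pairs[3],
                              fx$fx$pairs[3], cfg), "pool")
  expect_error(learning_curve(fx$fx$pairs[1:2], 2, fx$fx$pairs[3],
                              list(), cfg), "empty")
  lc1 <- learning_curve(fx$fx$pairs[1:2], 2, fx$fx$pairs[3], fx$fx$pairs[3],
                        cfg)
  lc2 <- learning_curve(fx$fx$pairs[1:2], 2, fx$fx$pairs[3], fx$fx$pairs[3],
                        cfg)
  expect_identical(lc1, lc2)
})
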