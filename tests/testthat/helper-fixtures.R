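# Shared phantom fixtures, built once per test run and cached in the helper
# environment (test files run in one session under test_dir).

.fixture_cache <- new.env(parent = emptyenv())

phantom_set <- function(n, grid = 32, seed = 11, denoise = TRUE, ...) {
  key <- paste(n, grid, seed, denoise, ...)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  pp <- phantom_params(grid_shape = rep(grid, 3), seed = seed, ...)
  co <- sample_cohort(pp, hive_plan = c(H1 = n))
  pairs <- lapply(seq_len(n), function(i) {
    ph <- render_phantom(co[i, ], pp, seed = seed + 100 + i)
    img <- if (denoise) denoise_mean3(ph$image) else ph$image
    list(image = img, labels = ph$labels, achieved = ph$achieved,
         sides = ph$sides, merged_mb = ph$merged_mb)
  })
  out <- list(params = pp, cohort = co, pairs = pairs)
  .fixture_cache[[key]] <- out
  out
}

# tiny trained model shared across unit tests (16^3 phantoms, patch 8)
tiny_model <- function() {
  if (!is.null(.fixture_cache$tiny_model)) return(.fixture_cache$tiny_model)
  fx <- phantom_set(3, grid = 16, seed = 21)
  cfg <- net_config(patch_size = 8, stride = 8, scaled_shape = c(16, 16, 16),
                    base_channels = 4, max_channels = 16, epochs = 6,
                    batch_size = 4, n_labels = 7, val_freq = 2, seed = 3)
  m <- train_unet(fx$pairs[1:2], fx$pairs[3], cfg)
  .fixture_cache$tiny_model <- list(model = m, fx = fx, cfg = cfg)
  .fixture_cache$tiny_model
}
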