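# Shared tiny fixtures used across the test files.

# A flat single-color image.
flat_image <- function(r, g, b, h = 8L, w = 8L) {
  px <- array(0L, dim = c(h, w, 3))
  px[, , 1] <- as.integer(r)
  px[, , 2] <- as.integer(g)
  px[, , 3] <- as.integer(b)
  rgb_image(px)
}

# A flat image of the given HSV hue (degrees), via the base converter.
hue_image <- function(hue, s = 1, v = 1, h = 8L, w = 8L) {
  ch <- grDevices::col2rgb(grDevices::hsv(hue / 360, s, v))
  flat_image(ch[1], ch[2], ch[3], h, w)
}

# Two jitter-free scenes whose plant hues (45 and 195 degrees) lie strictly
# inside the degree band [40, 200] while their soil hues (35 and 205) lie
# strictly outside it. On the default search grid, only the range
# (a, b) = (20, 100) grid units separates plants from soil in both scenes,
# so the grid search must recover exactly that band with zero SSE.
recovery_scenes <- function() {
  list(
    generate_field(field_scenario(plant_hue = 45, soil_hue = 35,
                                  hue_jitter = 0, weed_count = 0,
                                  shade_fraction = 0, seed = 101L), 64, 64),
    generate_field(field_scenario(plant_hue = 195, soil_hue = 205,
                                  hue_jitter = 0, weed_count = 0,
                                  shade_fraction = 0, seed = 102L), 64, 64)
  )
}

# A color-separable scene sampler (green plants on brown soil, no weeds,
# low jitter): easy enough that every model family can learn it quickly.
separable_sampler <- function() {
  function(seed) {
    field_scenario(growth_stage = runif(1, 0.3, 0.8),
                   plant_count = sample(3:6, 1),
                   weed_count = 0,
                   plant_hue = 120, soil_hue = 25, hue_jitter = 2,
                   shade_fraction = 0, seed = seed)
  }
}

separable_dataset <- function(n, seed = 5L, height = 64, width = 64) {
  generate_dataset(n, separable_sampler(), seed = seed,
                   height = height, width = width)
}

# A small pool of 16x16 separable patches (fast to train on).
tiny_pool <- function(n_scenes, seed = 3L) {
  scenes <- separable_dataset(n_scenes, seed = seed, height = 32, width = 32)
  tile_scenes(scenes, 16)
}

# The fastest trainable network configuration used by unit tests.
tiny_net_config <- function(seed = 1L, epochs = 2L, samples_per_epoch = 16L,
                            ...) {
  net_config(input_size = 16L, epochs = epochs,
             samples_per_epoch = samples_per_epoch,
             batch_size = 4L, seed = seed, ...)
}

# Oracle helper: brute-force IoU from explicit pixel counts.
count_iou <- function(pred, truth, k) {
  p <- unclass(pred) == k
  t <- unclass(truth) == k
  u <- sum(p | t)
  if (u == 0) 1 else sum(p & t) / u
}
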