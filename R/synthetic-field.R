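# Synthetic maize-field scene generator.
#
# Emulates the qualitative structure of nadir RGB field imagery: textured
# brown soil, green plant canopies built from lobed (leaf-like) ellipses,
# optional leaf yellowing late in the season, small green weed blobs that
# belong to the background class, and sun-lit vs. shaded illumination.
# Everything is deterministic in the scenario seed.

#' Describe a synthetic field scene
#'
#' @param growth_stage Real in `[0, 1]`; 0 = emergence (tiny sparse plants),
#'   1 = maturity (large canopies).
#' @param plant_count Number of crop plants.
#' @param plant_scale Mean plant blob radius in pixels.
#' @param weed_count Number of small green weed blobs (labeled background).
#' @param illumination `"sunny"` (bright, hard shade) or `"cloudy"`
#'   (dimmer, soft shade).
#' @param shade_fraction Fraction of the scene under shade, in `[0, 1]`.
#' @param yellowing Real in `[0, 1]`; shifts plant hue from green (~110
#'   degrees) toward yellow/brown (~50 degrees).
#' @param soil_noise Amplitude of the multiplicative log-normal soil
#'   texture (sd on the log scale).
#' @param seed Integer RNG seed; fixes the scene exactly.
#' @param plant_hue,soil_hue Optional fixed hues (degrees) overriding the
#'   stage-dependent defaults; used to build color-separable scenes.
#' @param hue_jitter Per-primitive hue jitter in degrees (default 12; set 0
#'   for exactly controlled hues).
#' @return A `field_scenario` list.
#' @export
field_scenario <- function(growth_stage = 0.5, plant_count = 6,
                           plant_scale = 18, weed_count = 3,
                           illumination = c("sunny", "cloudy"),
                           shade_fraction = 0.3, yellowing = 0,
                           soil_noise = 0.15, seed = 1L,
                           plant_hue = NULL, soil_hue = NULL,
                           hue_jitter = 12) {
  illumination <- match.arg(illumination)
  stopifnot(
    growth_stage >= 0, growth_stage <= 1,
    is_count(plant_count), plant_count >= 0,
    plant_scale > 0,
    is_count(weed_count), weed_count >= 0,
    shade_fraction >= 0, shade_fraction <= 1,
    yellowing >= 0, yellowing <= 1,
    soil_noise >= 0, hue_jitter >= 0
  )
  structure(
    list(growth_stage = growth_stage, plant_count = as.integer(plant_count),
         plant_scale = plant_scale, weed_count = as.integer(weed_count),
         illumination = illumination, shade_fraction = shade_fraction,
         yellowing = yellowing, soil_noise = soil_noise,
         seed = as.integer(seed), plant_hue = plant_hue, soil_hue = soil_hue,
         hue_jitter = hue_jitter),
    class = "field_scenario"
  )
}

# Vectorized HSV (h in degrees, s/v in [0,1]) -> 8-bit RGB matrices.
hsv_to_rgb_channels <- function(h, s, v) {
  h <- (h %% 360) / 60
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- g <- b <- v
  sel <- i == 0; r[sel] <- v[sel]; g[sel] <- t[sel]; b[sel] <- p[sel]
  sel <- i == 1; r[sel] <- q[sel]; g[sel] <- v[sel]; b[sel] <- p[sel]
  sel <- i == 2; r[sel] <- p[sel]; g[sel] <- v[sel]; b[sel] <- t[sel]
  sel <- i == 3; r[sel] <- p[sel]; g[sel] <- q[sel]; b[sel] <- v[sel]
  sel <- i == 4; r[sel] <- t[sel]; g[sel] <- p[sel]; b[sel] <- v[sel]
  sel <- i == 5; r[sel] <- v[sel]; g[sel] <- p[sel]; b[sel] <- q[sel]
  list(r = r, g = g, b = b)
}

# Paint a lobed "plant" (rosette of rotated ellipse leaves) into the hue/
# saturation/value planes; returns the logical footprint.
paint_plant <- function(h_pl, s_pl, v_pl, cy, cx, size, hue, hue_jitter, H, W) {
  n_leaves <- sample(4:8, 1)
  angles <- runif(1, 0, 2 * pi) + seq(0, 2 * pi, length.out = n_leaves + 1)[-(n_leaves + 1)]
  footprint <- matrix(FALSE, H, W)
  for (a in angles) {
    len <- size * runif(1, 0.7, 1.3)
    wid <- max(1.5, len * runif(1, 0.25, 0.4))
    ecy <- cy + 0.6 * len * sin(a)
    ecx <- cx + 0.6 * len * cos(a)
    rr <- max(1, floor(ecy - len)):min(H, ceiling(ecy + len))
    cc <- max(1, floor(ecx - len)):min(W, ceiling(ecx + len))
    dy <- outer(rr - ecy, rep(1, length(cc)))
    dx <- outer(rep(1, length(rr)), cc - ecx)
    u <- (dx * cos(a) + dy * sin(a)) / len
    w <- (-dx * sin(a) + dy * cos(a)) / wid
    inside <- u * u + w * w <= 1
    if (!any(inside)) next
    leaf_hue <- hue + runif(1, -hue_jitter, hue_jitter)
    leaf_s <- runif(1, 0.55, 0.9)
    leaf_v <- runif(1, 0.45, 0.8)
    idx_r <- rep(rr, times = length(cc))[inside]
    idx_c <- rep(cc, each = length(rr))[inside]
    lin <- cbind(idx_r, idx_c)
    h_pl[lin] <- leaf_hue + rnorm(nrow(lin), 0, hue_jitter / 6)
    s_pl[lin] <- pmin(1, pmax(0.2, leaf_s + rnorm(nrow(lin), 0, 0.04)))
    v_pl[lin] <- pmin(1, pmax(0.1, leaf_v + rnorm(nrow(lin), 0, 0.05)))
    footprint[lin] <- TRUE
  }
  list(h = h_pl, s = s_pl, v = v_pl, footprint = footprint)
}

#' Generate one labeled synthetic field scene
#'
#' Painting order is soil, then weeds, then crop plants; only crop
#' primitives ever write label 1, so weeds are background by construction.
#'
#' @param scenario A [field_scenario()].
#' @param height,width Scene dimensions in pixels (each at least 32).
#' @return A list with elements `image` ([rgb_image()]) and `mask`
#'   ([label_mask()]), deterministic in `scenario$seed`.
#' @export
#' @examples
#' sc <- field_scenario(plant_count = 2, weed_count = 1, seed = 42)
#' scene <- generate_field(sc, 64, 64)
#' mean(scene$mask == 1)  # crop cover fraction
generate_field <- function(scenario, height, width) {
  stopifnot(inherits(scenario, "field_scenario"))
  if (height < 32 || width < 32) {
    stop_bagseg("scene dimensions must be at least 32 x 32", "bagseg_size_error")
  }
  if (scenario$plant_count * scenario$plant_scale^2 > 5 * height * width) {
    stop_bagseg("plants cannot pack into the scene area", "bagseg_generation_error")
  }
  with_seed(scenario$seed, {
    H <- as.integer(height); W <- as.integer(width)
    n_px <- H * W
    sunny <- scenario$illumination == "sunny"

    # soil: brown, low saturation, multiplicative log-normal texture
    soil_hue <- if (is.null(scenario$soil_hue)) runif(1, 15, 35) else scenario$soil_hue
    h <- matrix(soil_hue + if (scenario$hue_jitter > 0) rnorm(n_px, 0, 1.5) else 0, H, W)
    s <- matrix(pmin(0.9, pmax(0.05, runif(1, 0.35, 0.55) + rnorm(n_px, 0, 0.03))), H, W)
    v_base <- if (sunny) 0.55 else 0.38
    v <- matrix(v_base * rlnorm(n_px, 0, scenario$soil_noise), H, W)

    # weeds: small green blobs, remain background (label 0)
    size_factor <- 0.35 + 0.85 * scenario$growth_stage
    for (i in seq_len(scenario$weed_count)) {
      cy <- runif(1, 1, H); cx <- runif(1, 1, W)
      r0 <- max(1.5, scenario$plant_scale * 0.2 * runif(1, 0.6, 1.4))
      rr <- max(1, floor(cy - r0)):min(H, ceiling(cy + r0))
      cc <- max(1, floor(cx - r0)):min(W, ceiling(cx + r0))
      dy <- outer(rr - cy, rep(1, length(cc)))
      dx <- outer(rep(1, length(rr)), cc - cx)
      inside <- dy * dy + dx * dx <= r0 * r0
      if (!any(inside)) next
      idx <- cbind(rep(rr, times = length(cc))[inside],
                   rep(cc, each = length(rr))[inside])
      h[idx] <- runif(1, 100, 130) + rnorm(nrow(idx), 0, scenario$hue_jitter / 6)
      s[idx] <- pmin(1, runif(1, 0.5, 0.8) + rnorm(nrow(idx), 0, 0.04))
      v[idx] <- pmin(1, pmax(0.1, runif(1, 0.35, 0.6) + rnorm(nrow(idx), 0, 0.05)))
    }

    # crop plants: lobed rosettes, hue green -> yellow with yellowing
    plant_hue <- if (is.null(scenario$plant_hue)) {
      110 * (1 - scenario$yellowing) + 50 * scenario$yellowing
    } else {
      scenario$plant_hue
    }
    mask <- matrix(0L, H, W)
    for (i in seq_len(scenario$plant_count)) {
      cy <- runif(1, 1, H); cx <- runif(1, 1, W)
      size <- max(2, scenario$plant_scale * size_factor * runif(1, 0.8, 1.2))
      res <- paint_plant(h, s, v, cy, cx, size, plant_hue,
                         scenario$hue_jitter, H, W)
      h <- res$h; s <- res$s; v <- res$v
      mask[res$footprint] <- 1L
    }

    # illumination: shaded band attenuates the value channel only
    if (scenario$shade_fraction > 0) {
      att <- if (sunny) 0.45 else 0.8
      n_shade <- round(scenario$shade_fraction * W)
      if (n_shade > 0) {
        from_left <- runif(1) < 0.5
        cols <- if (from_left) seq_len(n_shade) else (W - n_shade + 1):W
        v[, cols] <- v[, cols] * att
      }
    }
    if (!sunny) v <- v * 0.9

    ch <- hsv_to_rgb_channels(h, pmin(1, pmax(0, s)), pmin(1, pmax(0, v)))
    px <- array(0L, dim = c(H, W, 3))
    px[, , 1] <- pmin(255L, pmax(0L, as.integer(round(ch$r * 255))))
    px[, , 2] <- pmin(255L, pmax(0L, as.integer(round(ch$g * 255))))
    px[, , 3] <- pmin(255L, pmax(0L, as.integer(round(ch$b * 255))))
    list(image = rgb_image(px), mask = label_mask(mask, 2L))
  })
}

#' A sampler of field scenarios spanning the season
#'
#' Returns a function that, when called under a seeded RNG, draws one
#' [field_scenario()]: growth stage uniform over the season, plant count
#' and size tied to stage, yellowing concentrated late, sunny/cloudy mix,
#' and a variable shaded fraction. These are the study conditions every
#' downstream experiment runs under.
#'
#' @param growth_range Range the growth stage is drawn from.
#' @param plant_range Integer range of plant counts.
#' @param weed_range Integer range of weed counts.
#' @param plant_scale Mean plant radius in pixels.
#' @return A function `(seed) -> field_scenario`.
#' @export
default_scenario_sampler <- function(growth_range = c(0.1, 1),
                                     plant_range = c(2L, 8L),
                                     weed_range = c(0L, 4L),
                                     plant_scale = 16) {
  force(growth_range); force(plant_range); force(weed_range); force(plant_scale)
  function(seed) {
    stage <- runif(1, growth_range[1], growth_range[2])
    field_scenario(
      growth_stage = stage,
      plant_count = sample(plant_range[1]:plant_range[2], 1),
      plant_scale = plant_scale,
      weed_count = sample(weed_range[1]:weed_range[2], 1),
      illumination = if (runif(1) < 0.6) "sunny" else "cloudy",
      shade_fraction = runif(1, 0, 0.5),
      yellowing = max(0, stage - 0.6) / 0.4 * runif(1, 0.5, 1),
      soil_noise = runif(1, 0.08, 0.2),
      seed = seed
    )
  }
}

#' Generate a reproducible synthetic dataset
#'
#' @param n_images Number of scenes.
#' @param scenario_sampler A function `(seed) -> field_scenario`, e.g. from
#'   [default_scenario_sampler()]; called under a per-scene derived seed.
#' @param seed Master seed; per-scene seeds are derived from it.
#' @param height,width Scene dimensions.
#' @return List of scenes, each a list `(image, mask, scenario)`.
#' @export
generate_dataset <- function(n_images, scenario_sampler = default_scenario_sampler(),
                             seed = 1L, height = 64, width = 64) {
  stopifnot(is_count(n_images), n_images >= 1)
  lapply(seq_len(n_images), function(i) {
    scene_seed <- derive_seed(seed, paste0("scene", i))
    sc <- with_seed(scene_seed, scenario_sampler(scene_seed))
    out <- generate_field(sc, height, width)
    out$scenario <- sc
    out
  })
}

#' Tile a list of scenes into a patch pool
#'
#' @param scenes Output of [generate_dataset()].
#' @param patch_size Tile side.
#' @return Flat list of [patch_pair()]s.
#' @export
tile_scenes <- function(scenes, patch_size) {
  out <- lapply(seq_along(scenes), function(i) {
    crop_to_patches(scenes[[i]]$image, scenes[[i]]$mask, patch_size,
                    source_id = sprintf("scene%03d", i))
  })
  unlist(out, recursive = FALSE)
}
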