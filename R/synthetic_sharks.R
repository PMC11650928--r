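# Synthetic spot-pattern generator.
#
# Emulates the statistical structure of a captive photo-ID study on
# epaulette sharks: every individual carries a unique spot pattern; adults
# keep it for life, while juvenile and neonate patterns drift as the animal
# grows. Each individual is rendered as an elongated capsule body with a
# dark ocellus landmark behind the pectoral region, photographed under
# nuisance variation (in-plane view angle, gamma, blur, sensor noise,
# background), and annotated with four rotated skin patches
# (head, pec, FDF, FDB) aligned to the body axis.

STAGE_DRIFT <- c(adult = 0.00, juvenile = 0.02, neonate = 0.08)
STAGE_LENGTH <- c(adult = 170, juvenile = 140, neonate = 110)

# spot count is species-typical, not stage-typical: identity is carried by
# the spatial arrangement of spots, so the count range is common to all
# stages (drawn once per individual)
SPOT_COUNT_RANGE <- c(34L, 42L)

# body half-width as a fraction of body length
BODY_HALF_WIDTH_FRAC <- 0.13

# patch layout in body coordinates (x toward the head), fractions of
# body length / body width; chosen so all four boxes sit inside the body
PATCH_LAYOUT <- data.frame(
  patch_type = PATCH_TYPES,
  fx = c(0.345, 0.125, -0.095, -0.315),  # center x / body_length
  fw = c(0.19,  0.20,   0.20,   0.20),   # width    / body_length
  stringsAsFactors = FALSE
)

#' Build a synthetic population of individually patterned sharks
#'
#' @param n_adults,n_juveniles,n_neonates Number of individuals per life
#'   stage (non-negative integers).
#' @param seed Integer seed; identical inputs give identical populations.
#' @return A list of `IndividualSpec` lists with fields `shark_id`,
#'   `life_stage`, `base_seed`, `n_spots`, `spot_radius_range`,
#'   `body_length` and `drift_rate` (per-time-step; 0 for adults).
#' @export
make_population <- function(n_adults, n_juveniles, n_neonates, seed) {
  counts <- c(adult = n_adults, juvenile = n_juveniles, neonate = n_neonates)
  if (any(counts < 0)) stopf("population counts must be >= 0")
  specs <- list()
  i <- 0L
  for (stage in names(counts)) {
    for (j in seq_len(counts[[stage]])) {
      i <- i + 1L
      sid <- sprintf("HO_%03d", 100L + i)
      s <- derive_seed(seed, "shark", sid)
      jit <- with_seed(s, list(
        n_spots = SPOT_COUNT_RANGE[1] +
          sample.int(diff(SPOT_COUNT_RANGE) + 1L, 1L) - 1L,
        len = STAGE_LENGTH[[stage]] * stats::runif(1, 0.95, 1.05)
      ))
      specs[[i]] <- structure(list(
        shark_id = sid,
        life_stage = stage,
        base_seed = s,
        n_spots = max(1L, jit$n_spots),
        spot_radius_range = c(2.4, 4.8) * jit$len / STAGE_LENGTH[["adult"]],
        body_length = jit$len,
        drift_rate = STAGE_DRIFT[[stage]]
      ), class = "IndividualSpec")
    }
  }
  specs
}

# sample n spot centers uniformly inside the capsule, keeping each whole
# spot disc within the body outline
sample_spot_positions <- function(n, body_length, radii) {
  hw <- BODY_HALF_WIDTH_FRAC * body_length
  half_seg <- body_length / 2 - hw      # segment endpoints of the capsule
  x <- numeric(n); y <- numeric(n)
  for (i in seq_len(n)) {
    margin <- radii[i] + 1
    repeat {
      px <- stats::runif(1, -half_seg - hw + margin, half_seg + hw - margin)
      lim <- capsule_halfwidth(px, half_seg, hw) - margin
      if (lim <= 0) next
      py <- stats::runif(1, -lim, lim)
      x[i] <- px; y[i] <- py
      break
    }
  }
  cbind(x = x, y = y)
}

# half-width of the capsule outline at axial position x
capsule_halfwidth <- function(x, half_seg, hw) {
  ax <- pmax(abs(x) - half_seg, 0)
  out <- hw^2 - ax^2
  sqrt(pmax(out, 0))
}

#' Spot pattern of an individual at a given time step
#'
#' The base pattern (t = 0) is fixed by `base_seed`. Each step, every spot
#' center takes an isotropic Gaussian step with per-axis standard deviation
#' `drift_rate * body_length`, and each spot is independently deleted with
#' probability `drift_rate`, a new spot being born elsewhere in its place.
#' Adults (`drift_rate = 0`) are a fixed point. Reproducible from
#' `(base_seed, t)`.
#'
#' @param spec An `IndividualSpec`.
#' @param t Non-negative integer time step.
#' @return Data frame with columns `id` (spot lineage; reborn spots get a
#'   fresh id), `x`, `y` (body coordinates, pixels) and `r` (radius).
#' @export
drift_pattern <- function(spec, t) {
  if (t < 0) stopf("t must be >= 0")
  hw <- BODY_HALF_WIDTH_FRAC * spec$body_length
  half_seg <- spec$body_length / 2 - hw
  base <- with_seed(derive_seed(spec$base_seed, "pattern0"), {
    r <- stats::runif(spec$n_spots, spec$spot_radius_range[1],
                      spec$spot_radius_range[2])
    xy <- sample_spot_positions(spec$n_spots, spec$body_length, r)
    data.frame(id = seq_len(spec$n_spots), x = xy[, "x"], y = xy[, "y"],
               r = r)
  })
  if (spec$drift_rate == 0 || t == 0) return(base)
  spots <- base
  next_id <- spec$n_spots + 1L
  for (step in seq_len(t)) {
    spots <- with_seed(derive_seed(spec$base_seed, "drift", step), {
      n <- nrow(spots)
      sd_step <- spec$drift_rate * spec$body_length
      spots$x <- spots$x + stats::rnorm(n, 0, sd_step)
      spots$y <- spots$y + stats::rnorm(n, 0, sd_step)
      reborn <- stats::runif(n) < spec$drift_rate
      if (any(reborn)) {
        k <- sum(reborn)
        r_new <- stats::runif(k, spec$spot_radius_range[1],
                              spec$spot_radius_range[2])
        xy <- sample_spot_positions(k, spec$body_length, r_new)
        spots$x[reborn] <- xy[, "x"]; spots$y[reborn] <- xy[, "y"]
        spots$r[reborn] <- r_new
        spots$id[reborn] <- next_id + seq_len(k) - 1L
        next_id <- next_id + k
      }
      spots
    })
  }
  spots
}

#' Rendering configuration for one synthetic photograph
#'
#' @param image_size `(H, W)` in pixels, both >= 128.
#' @param view_angle In-plane body rotation, degrees (clockwise positive in
#'   pixel coordinates).
#' @param gamma Lighting gamma factor (> 0).
#' @param blur_sigma Gaussian blur sigma in pixels (>= 0).
#' @param noise_sd Additive Gaussian noise sd on the `[0, 1]` scale (>= 0).
#' @param background One of `"plain"`, `"gravel"`, `"sand"`.
#' @param render_seed Integer seed driving noise and background texture only.
#' @return A `RenderConfig` list.
#' @export
render_config <- function(image_size = c(224, 224), view_angle = 0,
                          gamma = 1, blur_sigma = 0, noise_sd = 0,
                          background = "plain", render_seed = 1L) {
  if (any(image_size < 128)) stopf("image_size must be >= 128 pixels")
  if (gamma <= 0) stopf("gamma must be > 0")
  if (blur_sigma < 0 || noise_sd < 0) stopf("blur/noise must be >= 0")
  background <- match.arg(background, c("plain", "gravel", "sand"))
  structure(list(image_size = as.integer(image_size), view_angle = view_angle,
                 gamma = gamma, blur_sigma = blur_sigma, noise_sd = noise_sd,
                 background = background, render_seed = as.integer(render_seed)),
            class = "RenderConfig")
}

# paint filled discs into a matrix (body-frame canvas), vectorized per spot
paint_discs <- function(canvas, cx, cy, r, value) {
  H <- nrow(canvas); W <- ncol(canvas)
  for (i in seq_along(cx)) {
    x0 <- max(0, floor(cx[i] - r[i] - 1)); x1 <- min(W - 1, ceiling(cx[i] + r[i] + 1))
    y0 <- max(0, floor(cy[i] - r[i] - 1)); y1 <- min(H - 1, ceiling(cy[i] + r[i] + 1))
    if (x1 < x0 || y1 < y0) next
    xs <- x0:x1; ys <- y0:y1
    dd <- outer((ys - cy[i])^2, (xs - cx[i])^2, "+")
    sel <- dd <= r[i]^2
    sub <- canvas[ys + 1, xs + 1, drop = FALSE]
    sub[sel] <- value
    canvas[ys + 1, xs + 1] <- sub
  }
  canvas
}

# rotated boxes for the four patches, in image coordinates
body_boxes <- function(spec, center, theta) {
  hw <- BODY_HALF_WIDTH_FRAC * spec$body_length
  cs <- snap_trig(theta)
  boxes <- lapply(seq_len(nrow(PATCH_LAYOUT)), function(i) {
    bx <- PATCH_LAYOUT$fx[i] * spec$body_length
    w <- PATCH_LAYOUT$fw[i] * spec$body_length
    h <- 1.5 * hw
    rotated_box(patch_type = PATCH_LAYOUT$patch_type[i],
                cx = center[1] + cs[1] * bx,
                cy = center[2] + cs[2] * bx,
                w = w, h = h,
                angle = ((theta %% (2 * pi)) + 2 * pi) %% (2 * pi))
  })
  names(boxes) <- PATCH_LAYOUT$patch_type
  boxes
}

#' Render one synthetic photograph of an individual
#'
#' Draws the capsule body with its spot pattern at time `t` and the ocellus
#' landmark, rotates by the view angle, then applies gamma, blur, noise and
#' background texture. Also emits the binary mask and the four rotated patch
#' boxes aligned to the body axis (box x-axis toward the head).
#'
#' @param spec An `IndividualSpec`.
#' @param t Time step passed to [drift_pattern()].
#' @param cfg A `RenderConfig`.
#' @return A `RenderedSample` list: `image` (H x W x 3 in `[0, 1]`), `mask`
#'   (H x W in `{0, 1}`), `boxes` (named list of 4 `RotatedBox`), plus
#'   `shark_id`, `series` (filled by [write_dataset()]), `time_marker`.
#' @export
render <- function(spec, t, cfg) {
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  L <- spec$body_length
  if (L + 4 > min(H, W))
    stopf("body of length %.0f does not fit in a %d x %d image", L, H, W)
  theta <- cfg$view_angle * pi / 180
  center <- c((W - 1) / 2, (H - 1) / 2)
  hw <- BODY_HALF_WIDTH_FRAC * L
  half_seg <- L / 2 - hw

  # body-frame canvas: mask and pattern layer (painted axis-aligned)
  xs <- 0:(W - 1) - center[1]
  ys <- 0:(H - 1) - center[2]
  limw <- capsule_halfwidth(xs, half_seg, hw)
  mask0 <- outer(ys, limw, function(y, l) abs(y) <= l & l > 0) * 1

  skin <- 0.55
  canvas <- mask0 * skin
  spots <- drift_pattern(spec, t)
  # clamp drifted spot centers back inside the outline so every spot pixel
  # stays on the body
  marg <- spots$r + 1
  spots$x <- pmin(pmax(spots$x, -half_seg - hw + marg), half_seg + hw - marg)
  lim <- pmax(capsule_halfwidth(spots$x, half_seg, hw) - marg, 0)
  spots$y <- pmin(pmax(spots$y, -lim), lim)
  canvas <- paint_discs(canvas, spots$x + center[1], spots$y + center[2],
                        spots$r, 0.12)
  # ocellus landmark: dark disc with pale ring behind the pec region
  oc <- c(0.04 * L + center[1], -0.45 * hw + center[2])
  canvas <- paint_discs(canvas, oc[1], oc[2], 0.42 * hw, 0.75)
  canvas <- paint_discs(canvas, oc[1], oc[2], 0.30 * hw, 0.05)

  if (abs(theta) > 1e-12) {
    canvas <- rotate_image(canvas, theta)
    maskr <- rotate_image(mask0, theta)
    mask <- (maskr > 0.5) * 1
  } else mask <- mask0
  canvas[mask == 0] <- 0

  # colorize: brownish skin, channel-weighted pattern layer
  img <- array(0, c(H, W, 3))
  img[, , 1] <- canvas * 1.00
  img[, , 2] <- canvas * 0.82
  img[, , 3] <- canvas * 0.58

  img <- with_seed(derive_seed(cfg$render_seed, "nuisance"), {
    bg <- matrix(0, H, W)
    if (cfg$background != "plain") {
      base <- if (cfg$background == "gravel") 0.35 else 0.72
      bg <- matrix(stats::runif(H * W, base - 0.12, base + 0.12), H, W)
      bg <- gaussian_blur(bg, if (cfg$background == "gravel") 1 else 2.5)
    }
    for (c in 1:3) {
      pl <- img[, , c]
      pl[mask == 0] <- bg[mask == 0] * c(1, 0.95, 0.85)[c]
      img[, , c] <- pl
    }
    img <- clip01(img)^cfg$gamma
    img <- gaussian_blur(img, cfg$blur_sigma)
    if (cfg$noise_sd > 0)
      img <- img + array(stats::rnorm(H * W * 3, 0, cfg$noise_sd), c(H, W, 3))
    clip01(img)
  })

  structure(list(image = img, mask = mask,
                 boxes = body_boxes(spec, center, theta),
                 shark_id = spec$shark_id, series = NA_character_,
                 time_marker = ""),
            class = "RenderedSample")
}

# nuisance configuration for one photograph, drawn from the study-like
# ranges (free view angle, mild lighting/blur/noise variation)
draw_render_config <- function(seed, image_size = c(224, 224)) {
  with_seed(seed, render_config(
    image_size = image_size,
    view_angle = stats::runif(1, 0, 360),
    gamma = stats::runif(1, 0.8, 1.25),
    blur_sigma = stats::runif(1, 0, 0.7),
    noise_sd = stats::runif(1, 0.005, 0.025),
    background = sample(c("plain", "gravel", "sand"), 1),
    render_seed = derive_seed(seed, "render")
  ))
}

#' Write a complete synthetic dataset to disk
#'
#' Baseline replicates of a shark share the same time step (same-day
#' photographs: no drift between them) and differ only in nuisance; time
#' images advance the drift clock and carry markers `T0..T(time_steps-1)`,
#' with marker `Tk` at drift time `t = k + 1`.
#'
#' @param population List of `IndividualSpec` from [make_population()].
#' @param baseline_replicates Same-day baseline photographs per shark (>= 1).
#' @param time_steps Number of time markers (0 for baseline-only).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; a re-run writes a byte-identical manifest.
#' @param time_replicates Photographs per time marker (default 1).
#' @param image_size `(H, W)` of the rendered photographs.
#' @return Path of the manifest CSV (columns `image_path, mask_path,
#'   annotation_path, shark_id, life_stage, series, time_marker`).
#' @export
write_dataset <- function(population, baseline_replicates, time_steps,
                          out_dir, seed, time_replicates = 1L,
                          image_size = c(224, 224)) {
  if (baseline_replicates < 1) stopf("baseline_replicates must be >= 1")
  for (d in c("images", "masks", "annotations"))
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (spec in population) {
    shots <- data.frame(series = character(0), marker = character(0),
                        t = integer(0), rep = integer(0))
    for (b in seq_len(baseline_replicates))
      shots <- rbind(shots, data.frame(series = "baseline", marker = "",
                                       t = 0L, rep = b))
    if (time_steps > 0) for (k in 0:(time_steps - 1L))
      for (b in seq_len(time_replicates))
        shots <- rbind(shots, data.frame(series = "time",
                                         marker = sprintf("T%d", k),
                                         t = k + 1L, rep = b))
    for (i in seq_len(nrow(shots))) {
      sh <- shots[i, ]
      tag <- if (sh$series == "baseline") sprintf("B0P%d", sh$rep)
             else sprintf("%sP%d", sh$marker, sh$rep)
      stem <- sprintf("%s_%s", spec$shark_id, tag)
      cfg <- draw_render_config(derive_seed(seed, "shot", stem), image_size)
      smp <- render(spec, sh$t, cfg)
      ip <- file.path(out_dir, "images", paste0(stem, ".png"))
      mp <- file.path(out_dir, "masks", paste0(stem, "_mask.png"))
      ap <- file.path(out_dir, "annotations", paste0(stem, ".xml"))
      write_image(smp$image, ip)
      write_mask(smp$mask, mp)
      write_rolabelimg(smp$boxes, ip, ap)
      rows[[length(rows) + 1L]] <- data.frame(
        image_path = ip, mask_path = mp, annotation_path = ap,
        shark_id = spec$shark_id, life_stage = spec$life_stage,
        series = sh$series, time_marker = sh$marker,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(out_dir, "manifest.csv")
  write_manifest(manifest, mpath)
  mpath
}
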