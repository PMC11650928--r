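# Patch standardization: background masking, rotated-box extraction with
# orientation normalization (box x-axis, i.e. the head direction, maps to
# the patch u-axis), seeded augmentation, and backbone preprocessing.

#' Zero out background pixels using a binary mask
#'
#' @param image `H x W x 3` array.
#' @param mask `H x W` matrix; pixels where `mask == 0` are set to 0 in all
#'   channels.
#' @return Masked image.
#' @export
apply_mask <- function(image, mask) {
  assert_image(image)
  if (!all(dim(image)[1:2] == dim(mask)))
    stopf("image (%d x %d) and mask (%d x %d) shapes differ",
          dim(image)[1], dim(image)[2], nrow(mask), ncol(mask))
  bg <- mask == 0
  for (c in 1:3) {
    pl <- image[, , c]; pl[bg] <- 0; image[, , c] <- pl
  }
  image
}

#' Extract and standardize one rotated patch
#'
#' Samples the axis-aligned `w x h` rectangle in the box's own frame
#' (rotating by `-angle` about the center) and resizes to
#' `out_size x out_size`. The patch u-axis runs along the box x-axis, so the
#' canonical orientation places the head side on a fixed patch edge; at
#' `angle = 0` a box exactly covering a subimage reproduces that subimage.
#' 90-degree-multiple angles are exact pixel remaps; other angles use
#' bilinear interpolation, with out-of-image samples reading as 0.
#'
#' @param image `H x W x 3` array.
#' @param box A `RotatedBox`.
#' @param out_size Output side in pixels (default 380).
#' @param shark_id,source_image_id,time_marker Optional provenance carried
#'   on the patch.
#' @return A `Patch`: list with `patch_type`, `pixels`
#'   (`out_size x out_size x 3`), and provenance fields.
#' @export
extract_patch <- function(image, box, out_size = 380, shark_id = NA_character_,
                          source_image_id = NA_character_, time_marker = "") {
  assert_image(image)
  if (out_size <= 0) stopf("out_size must be positive")
  S <- as.integer(out_size)
  cs <- snap_trig(box$angle); cth <- cs[1]; sth <- cs[2]
  u <- ((0:(S - 1)) + 0.5) / S - 0.5   # fractions of w along the box x-axis
  v <- ((0:(S - 1)) + 0.5) / S - 0.5
  g <- expand.grid(u = u * box$w, v = v * box$h)
  xs <- box$cx + cth * g$u - sth * g$v
  ys <- box$cy + sth * g$u + cth * g$v
  val <- sample_bilinear(image, xs, ys)
  px <- array(0, c(S, S, 3))
  for (c in 1:3) px[, , c] <- matrix(val[, c], S, S, byrow = TRUE)
  structure(list(patch_type = box$patch_type, pixels = px,
                 shark_id = shark_id, source_image_id = source_image_id,
                 time_marker = time_marker),
            class = "Patch")
}

#' Augmentation parameter ranges
#'
#' Defaults follow the standard photo-nuisance recipe: coin-flip X/Y flips,
#' quarter-turn rotations, additive Gaussian noise, Gaussian blur, gamma
#' and linear contrast. `blur_max` is in pixels of the patch being
#' augmented, so configs using small patches should scale it down.
#'
#' @param flip_x_prob,flip_y_prob Flip probabilities in `[0, 1]`.
#' @param rotations Set of allowed quarter-turn angles, degrees.
#' @param noise_max Max additive noise sd on the `[0, 1]` scale.
#' @param blur_max Max Gaussian blur sigma, pixels.
#' @param gamma_range,contrast_range Ranges for gamma and linear contrast.
#' @return An `AugmentParams` list.
#' @export
augment_params <- function(flip_x_prob = 0.5, flip_y_prob = 0.5,
                           rotations = c(0, 90, 180, 270),
                           noise_max = 10 / 255, blur_max = 2,
                           gamma_range = c(0.7, 1.4),
                           contrast_range = c(0.8, 1.2)) {
  if (noise_max < 0 || blur_max < 0)
    stopf("noise_max and blur_max must be >= 0")
  if (gamma_range[1] > gamma_range[2] || gamma_range[1] <= 0)
    stopf("invalid gamma_range")
  if (contrast_range[1] > contrast_range[2])
    stopf("invalid contrast_range")
  if (!all(rotations %in% c(0, 90, 180, 270)))
    stopf("rotations must be quarter-turn multiples")
  structure(list(flip_x_prob = flip_x_prob, flip_y_prob = flip_y_prob,
                 rotations = rotations, noise_max = noise_max,
                 blur_max = blur_max, gamma_range = gamma_range,
                 contrast_range = contrast_range),
            class = "AugmentParams")
}

#' Randomly augment a patch
#'
#' Applies, in fixed order with independently drawn parameters: X flip,
#' Y flip, quarter-turn rotation, additive Gaussian noise, Gaussian blur,
#' gamma contrast, linear contrast about the mean. Shape and patch type are
#' unchanged; the identity configuration returns the input untouched.
#'
#' @param patch A `Patch`.
#' @param params An `AugmentParams`.
#' @param rng Integer seed making the draw reproducible, or `NULL` to use
#'   the current RNG stream.
#' @return Augmented `Patch`.
#' @export
augment <- function(patch, params = augment_params(), rng = NULL) {
  run <- function() {
    px <- patch$pixels
    if (stats::runif(1) < params$flip_x_prob)
      px <- px[, rev(seq_len(dim(px)[2])), , drop = FALSE]
    if (stats::runif(1) < params$flip_y_prob)
      px <- px[rev(seq_len(dim(px)[1])), , , drop = FALSE]
    rot <- params$rotations[sample.int(length(params$rotations), 1L)]
    px <- rot90k(px, rot / 90)
    noise_sd <- stats::runif(1, 0, params$noise_max)
    if (noise_sd > 0)
      px <- px + array(stats::rnorm(length(px), 0, noise_sd), dim(px))
    blur <- stats::runif(1, 0, params$blur_max)
    if (blur > 0) px <- gaussian_blur(px, blur)
    gam <- stats::runif(1, params$gamma_range[1], params$gamma_range[2])
    if (gam != 1) px <- clip01(px)^gam
    alpha <- stats::runif(1, params$contrast_range[1],
                          params$contrast_range[2])
    if (alpha != 1) px <- mean(px) + alpha * (px - mean(px))
    if (noise_sd > 0 || blur > 0 || gam != 1 || alpha != 1) px <- clip01(px)
    patch$pixels <- px
    patch
  }
  if (is.null(rng)) run() else with_seed(rng, run())
}

#' Photometrically standardize a patch
#'
#' Maps the patch to zero-mean/fixed-spread intensities (re-centered at 0.5
#' and clipped to `[0, 1]`), removing most gamma/contrast nuisance so that
#' pattern comparison rests on spot layout rather than lighting. Applied by
#' the pipeline before embedding (training and inference alike).
#'
#' @param patch A `Patch`.
#' @param spread Target intensity spread per standard deviation
#'   (default 0.18).
#' @return Standardized `Patch`.
#' @export
standardize_patch <- function(patch, spread = 0.18) {
  px <- patch$pixels
  s <- stats::sd(px)
  patch$pixels <- clip01(0.5 + (px - mean(px)) / (s + 1e-6) * spread)
  patch
}

#' Prepare a patch for a backbone's declared input contract
#'
#' Resizes to the backbone's declared input side (bilinear) and affinely
#' maps intensities from `[0, 1]` to the declared input range.
#'
#' @param patch A `Patch` (pixels in `[0, 1]`).
#' @param backbone_spec A backbone with `input_side` and `input_range`.
#' @return `Patch` with pixels matching the backbone contract.
#' @export
preprocess_for_backbone <- function(patch, backbone_spec) {
  if (is.null(backbone_spec$input_side) || is.null(backbone_spec$input_range))
    stopf("backbone declares no input spec (input_side/input_range)")
  side <- backbone_spec$input_side
  rng <- backbone_spec$input_range
  px <- resize_bilinear(patch$pixels, side, side)
  patch$pixels <- rng[1] + px * (rng[2] - rng[1])
  patch
}

#' Extract the four standardized patches of one manifest row
#'
#' Reads image, mask and annotation, masks the background, and extracts all
#' four patches.
#'
#' @param row One manifest row (data frame of one row or list).
#' @param out_size Patch side, pixels.
#' @return Named list of four `Patch` in canonical order
#'   (head, pec, FDF, FDB).
#' @export
patches_from_row <- function(row, out_size = 380) {
  img <- read_image(row$image_path)
  msk <- read_mask(row$mask_path)
  boxes <- read_rolabelimg(row$annotation_path)
  img <- apply_mask(img, msk)
  iid <- sub("\\.[a-zA-Z]+$", "", basename(row$image_path))
  out <- lapply(PATCH_TYPES, function(pt) {
    if (is.null(boxes[[pt]]))
      stopf("image %s is missing patch '%s'", iid, pt)
    extract_patch(img, boxes[[pt]], out_size, shark_id = row$shark_id,
                  source_image_id = iid, time_marker = row$time_marker)
  })
  names(out) <- PATCH_TYPES
  out
}
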