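# Feature-extractor backbones.
#
# The twin network treats the backbone as a frozen, pluggable contract:
# a declared input side and intensity range, a forward pass producing a
# spatial feature map, and a fixed feature dimension F (the channel count,
# which average pooling reduces to an F-vector). Two configurations ship:
#
# * `tiny_backbone()` - a small strided convolution stack with seeded random
#   frozen weights. Random convolutional features followed by pooling are a
#   classic cheap descriptor; they exercise the full twin/fusion contract in
#   seconds with no pretrained download.
# * `efficientnet_spec()` - the reference EfficientNet architecture family,
#   constructed layer-by-layer from its published compound-scaling
#   definition. Used here for exact parameter accounting (weights for the
#   forward pass would come from a pretrained release, which this package
#   does not download).

#' Small frozen convolutional test backbone
#'
#' Four stride-2 3x3 convolution + ReLU layers (channels
#' 3 -> 16 -> 32 -> 64 -> F), He-initialized from a seed and frozen.
#'
#' @param seed Integer seed for the frozen random weights.
#' @param input_side Declared input side, pixels (default 64).
#' @param channels Channel progression; last entry is the feature
#'   dimension F.
#' @return A `BackboneSpec` list with `name`, `input_side`, `input_range`,
#'   `feature_dim`, `provenance`, `weights` (list of conv layers) and
#'   `checksum` (digest of the frozen weights).
#' @export
tiny_backbone <- function(seed = 42L, input_side = 64L,
                          channels = c(16L, 32L, 64L, 64L)) {
  chain <- c(3L, channels)
  weights <- with_seed(derive_seed(seed, "tiny_backbone"), {
    lapply(seq_len(length(chain) - 1L), function(i) {
      cin <- chain[i]; cout <- chain[i + 1L]
      sdv <- sqrt(2 / (9 * cin))
      list(w = array(stats::rnorm(9 * cin * cout, 0, sdv),
                     c(3L, 3L, cin, cout)),
           b = stats::rnorm(cout, 0, 0.01),
           stride = 2L)
    })
  })
  bb <- structure(list(name = "tiny_conv4",
                       input_side = as.integer(input_side),
                       input_range = c(0, 1),
                       feature_dim = chain[length(chain)],
                       provenance = "random_frozen_test",
                       weights = weights),
                  class = "BackboneSpec")
  bb$checksum <- backbone_checksum(bb)
  bb
}

#' Digest of a backbone's frozen weights (freeze-contract audit)
#' @param backbone A `BackboneSpec`.
#' @return Character digest.
#' @export
backbone_checksum <- function(backbone) {
  digest::digest(backbone$weights, algo = "sha256")
}

#' Forward pass of a backbone on one preprocessed patch
#'
#' @param backbone A `BackboneSpec` with conv weights.
#' @param pixels `side x side x 3` array already matching the declared
#'   input contract.
#' @return Feature map array `h x w x F`.
#' @export
backbone_features <- function(backbone, pixels) {
  d <- dim(pixels)
  if (d[1] != backbone$input_side || d[2] != backbone$input_side)
    stopf("input is %d x %d but backbone declares side %d",
          d[1], d[2], backbone$input_side)
  x <- pixels
  for (ly in backbone$weights)
    x <- conv2d(x, ly$w, ly$b, stride = ly$stride, relu = TRUE)
  x
}

## ---- reference architecture accounting ------------------------------------

# width rounding rule of the compound-scaling family: scale, snap to the
# nearest multiple of `divisor`, never dropping below 90% of the scaled value
round_filters <- function(filters, width, divisor = 8) {
  f <- filters * width
  new_f <- max(divisor, (trunc(f + divisor / 2) %/% divisor) * divisor)
  if (new_f < 0.9 * f) new_f <- new_f + divisor
  as.integer(new_f)
}

round_repeats <- function(repeats, depth) as.integer(ceiling(depth * repeats))

# per-variant compound-scaling coefficients (width, depth, resolution)
EFFICIENTNET_COEFS <- list(
  B0 = c(1.0, 1.0, 224), B1 = c(1.0, 1.1, 240), B2 = c(1.1, 1.2, 260),
  B3 = c(1.2, 1.4, 300), B4 = c(1.4, 1.8, 380), B5 = c(1.6, 2.2, 456),
  B6 = c(1.8, 2.6, 528), B7 = c(2.0, 3.1, 600)
)

# base (B0) mobile inverted-bottleneck block arguments
EFFICIENTNET_BLOCKS <- data.frame(
  kernel  = c(3L, 3L, 5L, 3L, 5L, 5L, 3L),
  repeats = c(1L, 2L, 2L, 3L, 3L, 4L, 1L),
  f_in    = c(32L, 16L, 24L, 40L, 80L, 112L, 192L),
  f_out   = c(16L, 24L, 40L, 80L, 112L, 192L, 320L),
  expand  = c(1L, 6L, 6L, 6L, 6L, 6L, 6L)
)

#' Layer table of an EfficientNet feature extractor
#'
#' Constructs the published architecture (stem, scaled MBConv stages with
#' squeeze-excitation, top 1x1 convolution; no classification head) and
#' returns one row per layer with its parameter count. Batch-normalization
#' layers contribute 4 parameters per channel (scale, offset, moving mean,
#' moving variance).
#'
#' @param variant `"B0"` .. `"B7"`.
#' @param se_ratio Squeeze-excitation ratio (0.25 in the published family).
#' @return Data frame with columns `layer`, `params`.
#' @export
efficientnet_spec <- function(variant = "B4", se_ratio = 0.25) {
  cf <- EFFICIENTNET_COEFS[[variant]]
  if (is.null(cf)) stopf("unknown EfficientNet variant '%s'", variant)
  width <- cf[1]; depth <- cf[2]
  rows <- list()
  add <- function(layer, params)
    rows[[length(rows) + 1L]] <<- data.frame(layer = layer,
                                             params = as.numeric(params))
  conv_p <- function(k, cin, cout) k * k * cin * cout        # no bias
  bn_p <- function(c) 4 * c

  # input normalization layer: per-channel mean and variance plus the
  # accumulation count, as in the published reference implementation
  add("input_normalization", 3 + 3 + 1)

  stem <- round_filters(32, width)
  add("stem_conv", conv_p(3, 3, stem)); add("stem_bn", bn_p(stem))

  cin <- stem
  for (bi in seq_len(nrow(EFFICIENTNET_BLOCKS))) {
    blk <- EFFICIENTNET_BLOCKS[bi, ]
    f_in <- round_filters(blk$f_in, width)
    f_out <- round_filters(blk$f_out, width)
    reps <- round_repeats(blk$repeats, depth)
    for (r in seq_len(reps)) {
      bin <- if (r == 1) f_in else f_out
      f_exp <- bin * blk$expand
      tag <- sprintf("block%d%s", bi, letters[r])
      if (blk$expand != 1) {
        add(paste0(tag, "_expand_conv"), conv_p(1, bin, f_exp))
        add(paste0(tag, "_expand_bn"), bn_p(f_exp))
      }
      add(paste0(tag, "_dwconv"), blk$kernel^2 * f_exp)
      add(paste0(tag, "_dw_bn"), bn_p(f_exp))
      f_se <- max(1, trunc(bin * se_ratio))
      add(paste0(tag, "_se_reduce"), f_exp * f_se + f_se)    # 1x1, bias
      add(paste0(tag, "_se_expand"), f_se * f_exp + f_exp)
      add(paste0(tag, "_project_conv"), conv_p(1, f_exp, f_out))
      add(paste0(tag, "_project_bn"), bn_p(f_out))
    }
    cin <- f_out
  }
  top <- round_filters(1280, width)
  add("top_conv", conv_p(1, cin, top)); add("top_bn", bn_p(top))
  do.call(rbind, rows)
}

#' Total parameter count of an EfficientNet feature extractor
#'
#' @param variant `"B0"` .. `"B7"`.
#' @return Total number of parameters (trainable + batch-norm statistics)
#'   of the feature extractor without its classification top.
#' @export
efficientnet_param_count <- function(variant = "B4") {
  sum(efficientnet_spec(variant)$params)
}

#' Reference backbone contract (declared input geometry only)
#'
#' The published EfficientNetB4 configuration as a backbone contract:
#' 380-pixel input side, `[0, 255]` input range, feature dimension 1792.
#' Carries no weights (pretrained weights are an external artifact), so it
#' supports preprocessing and parameter accounting but not a forward pass.
#'
#' @return A `BackboneSpec` without weights.
#' @export
reference_backbone <- function() {
  structure(list(name = "EfficientNetB4", input_side = 380L,
                 input_range = c(0, 255), feature_dim = 1792L,
                 provenance = "pretrained_reference", weights = NULL),
            class = "BackboneSpec")
}
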