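# Shared fixtures, built once per test session.
#
# `fixture_dataset()` renders a small population to a session tempdir:
# 3 adults + 1 neonate, 3 baseline replicates, 2 time markers. Reused by
# the annotation/pipeline/cleaning tests so rendering cost is paid once.

.fixture_env <- new.env(parent = emptyenv())

fixture_dataset <- function() {
  if (!is.null(.fixture_env$manifest)) return(.fixture_env)
  dir <- file.path(tempdir(), "patchid_fixture")
  pop <- make_population(3, 0, 1, seed = 7)
  mp <- write_dataset(pop, baseline_replicates = 3, time_steps = 2,
                      out_dir = dir, seed = 5, time_replicates = 1,
                      image_size = c(192, 192))
  .fixture_env$dir <- dir
  .fixture_env$population <- pop
  .fixture_env$manifest_path <- mp
  .fixture_env$manifest <- read_manifest(mp)
  .fixture_env
}

# deterministic RGB test image with distinct pixel values
grid_image <- function(H = 16, W = 16) {
  img <- array(0, c(H, W, 3))
  v1 <- matrix(seq(0, 1, length.out = H * W), H, W, byrow = TRUE)
  v2 <- matrix(seq(1, 0, length.out = H * W), H, W)
  img[, , 1] <- v1
  img[, , 2] <- v2
  img[, , 3] <- (v1 + v2) / 2
  img
}

# a small patch with reproducible content
toy_patch <- function(seed = 1, S = 16, patch_type = "head",
                      shark_id = "A", source_image_id = "img1") {
  px <- patchid:::with_seed(seed, array(stats::runif(S * S * 3), c(S, S, 3)))
  structure(list(patch_type = patch_type, pixels = px, shark_id = shark_id,
                 source_image_id = source_image_id, time_marker = ""),
            class = "Patch")
}

# tiny trained setup shared by evaluation tests: 2 "sharks" that are
# trivially separable at the embedding level
toy_models_and_ensemble <- function() {
  if (!is.null(.fixture_env$toy)) return(.fixture_env$toy)
  bb <- tiny_backbone(3, input_side = 16, channels = c(8L, 8L))
  models <- lapply(patchid:::PATCH_TYPES, function(pt) patch_model(pt, bb, 2))
  names(models) <- patchid:::PATCH_TYPES
  X <- patchid:::with_seed(9, matrix(stats::runif(200 * 4), 200, 4))
  y <- as.numeric(X[, 1] > 0.5)
  ens <- fit_ensemble(X, y, fusion_params(max_trees = 20), rng = 4)
  .fixture_env$toy <- list(models = models, ensemble = ens, backbone = bb)
  .fixture_env$toy
}

# image structure (named 4-patch list) for shark/eval tests
toy_image <- function(seed, shark_id, image_id, S = 16) {
  out <- lapply(patchid:::PATCH_TYPES, function(pt)
    toy_patch(seed = patchid:::derive_seed(seed, pt), S = S, patch_type = pt,
              shark_id = shark_id, source_image_id = image_id))
  names(out) <- patchid:::PATCH_TYPES
  out
}
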