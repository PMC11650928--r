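# Twin network: pooling, forward pass, head training, freeze contract,
# persistence.

test_that("embed average-pools backbone features per channel", {
  # constant-bias stub: zero conv weights, bias c -> feature map == relu(c)
  bb <- tiny_backbone(1, input_side = 16, channels = c(4L, 4L))
  for (i in seq_along(bb$weights)) {
    bb$weights[[i]]$w[] <- 0
    bb$weights[[i]]$b <- rep(0.7, length(bb$weights[[i]]$b))
  }
  m <- patch_model("head", bb)
  e <- embed(m, toy_patch(1, S = 16))
  expect_equal(e, rep(0.7, 4))

  # pooling linearity through a 1x1 identity-style conv on the first
  # channel (non-negative inputs pass relu unchanged)
  bb2 <- tiny_backbone(2, input_side = 8, channels = c(3L))
  bb2$weights[[1]]$w[] <- 0
  bb2$weights[[1]]$b <- rep(0, 3)
  for (c in 1:3) bb2$weights[[1]]$w[2, 2, c, c] <- 1
  bb2$weights[[1]]$stride <- 1L
  m2 <- patch_model("head", bb2)
  pa <- toy_patch(3, S = 8); pb <- toy_patch(4, S = 8)
  pl <- pa; pl$pixels <- 0.25 * pa$pixels + 0.5 * pb$pixels
  expect_equal(embed(m2, pl),
               0.25 * embed(m2, pa) + 0.5 * embed(m2, pb),
               tolerance = 1e-12)
})

test_that("similarity is the documented dense forward pass", {
  bb <- tiny_backbone(5, input_side = 8, channels = c(2L))
  m <- patch_model("FDF", bb, seed = 1)
  # hand-set head with F = 2 and hand-computed expectation
  m$head <- list(W1 = matrix(c(0.5, -0.25, 0.1, 0.3,
                               -0.2, 0.4, 0.6, -0.1), 4, 2),
                 b1 = c(0.05, -0.02),
                 W2 = matrix(c(1.5, -0.7), 2, 1), b2 = 0.1,
                 scale_mu = c(0, 0), scale_sd = c(1, 1))
  pa <- toy_patch(1, S = 8, patch_type = "FDF")
  pb <- toy_patch(2, S = 8, patch_type = "FDF")
  ea <- embed(m, pa); eb <- embed(m, pb)
  x <- c(ea, eb)
  h <- pmax(as.vector(t(m$head$W1) %*% x) + m$head$b1, 0)
  expected <- 1 / (1 + exp(-(sum(h * m$head$W2) + m$head$b2)))
  expect_equal(similarity(m, pa, pb), expected, tolerance = 1e-9)
  expect_true(similarity(m, pa, pb) > 0 && similarity(m, pa, pb) < 1)

  # all-zero output layer gives sigmoid(0) = 0.5 for any inputs
  m0 <- m
  m0$head$W2[] <- 0; m0$head$b2 <- 0
  expect_equal(similarity(m0, pa, pb), 0.5)
  expect_equal(similarity(m0, pb, pa), 0.5)

  expect_error(similarity(m, toy_patch(1, S = 8, patch_type = "pec"), pb),
               "pec")
})

test_that("train_head learns separable toys, freezes backbone, reproduces", {
  bb <- tiny_backbone(7, input_side = 16, channels = c(8L, 8L))
  m <- patch_model("head", bb, seed = 3)
  # two synthetic identities; images = identity template + small noise
  mk <- function(id, im) {
    base <- toy_patch(id * 100, S = 16)
    noise <- patchid:::with_seed(id * 100 + im,
                                 array(rnorm(16 * 16 * 3, 0, 0.02),
                                       c(16, 16, 3)))
    base$pixels <- patchid:::clip01(base$pixels + noise)
    base$source_image_id <- sprintf("id%d_im%d", id, im)
    base$shark_id <- sprintf("id%d", id)
    base
  }
  imgs <- list()
  for (id in 1:2) for (im in 1:4) imgs[[length(imgs) + 1]] <- mk(id, im)
  items <- data.frame(
    shark_id = vapply(imgs, `[[`, "", "shark_id"),
    source_image_id = vapply(imgs, `[[`, "", "source_image_id"))
  prs <- make_pairs(items, "head", n_pairs = NULL)
  pairs <- lapply(seq_len(nrow(prs)), function(i)
    list(patch_a = imgs[[prs$a[i]]], patch_b = imgs[[prs$b[i]]],
         label = prs$label[i]))

  before <- backbone_checksum(m$backbone)
  fit <- train_head(m, pairs, epochs = 50, learning_rate = 5e-3,
                    rng = 2, optimizer = "adam")
  expect_identical(backbone_checksum(fit$model$backbone), before)
  expect_length(fit$loss_history, 50)
  expect_lt(fit$loss_history[50], fit$loss_history[1])
  preds <- vapply(pairs, function(p)
    similarity(fit$model, p$patch_a, p$patch_b), numeric(1))
  labels <- vapply(pairs, `[[`, 0, "label")
  expect_gte(mean((preds > 0.5) == (labels == 1)), 0.95)

  # determinism: identical seed and pairs give identical weights
  fit2 <- train_head(patch_model("head", bb, seed = 3), pairs, epochs = 50,
                     learning_rate = 5e-3, rng = 2, optimizer = "adam")
  expect_identical(fit$model$head, fit2$model$head)

  # all-one-class pairs rejected
  pos_only <- pairs[labels == 1]
  expect_error(train_head(m, pos_only, epochs = 1), "both classes")
})

test_that("save/load round-trips models exactly and guards mismatches", {
  bb <- tiny_backbone(9, input_side = 16, channels = c(6L, 6L))
  m <- patch_model("pec", bb, seed = 4)
  dir <- tempfile()
  save_model(m, dir)
  m2 <- load_model(dir)
  expect_identical(m2$patch_type, "pec")
  pa <- toy_patch(11, S = 16, patch_type = "pec")
  pb <- toy_patch(12, S = 16, patch_type = "pec")
  expect_equal(similarity(m, pa, pb), similarity(m2, pa, pb),
               tolerance = 1e-12)
  expect_identical(backbone_checksum(m$backbone),
                   backbone_checksum(m2$backbone))

  # head-only files are rejected
  file.remove(file.path(dir, "backbone.json"))
  expect_error(load_model(dir), "backbone")

  # cross-patch-type use is guarded at inference
  expect_error(similarity(m, toy_patch(1, S = 16, patch_type = "head"), pb),
               "head")
  expect_error(load_model(tempfile()), "spec.json")
})

test_that("EfficientNet accounting follows the published scaling rules", {
  # width rounding: snaps to multiples of 8, never below 90% of the target
  expect_equal(patchid:::round_filters(32, 1.4), 48L)
  expect_equal(patchid:::round_filters(1280, 1.4), 1792L)
  expect_equal(patchid:::round_repeats(3, 1.8), 6L)
  expect_equal(reference_backbone()$feature_dim, 1792L)
  # B0 at width/depth 1.0 keeps the base block structure
  spec0 <- efficientnet_spec("B0")
  expect_equal(spec0$params[spec0$layer == "stem_conv"], 3 * 3 * 3 * 32)
  expect_error(efficientnet_spec("B9"), "unknown")
})
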