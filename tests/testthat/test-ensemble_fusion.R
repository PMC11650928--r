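# Gradient-boosted fusion: index collection, tree fitting, prediction,
# decision rule.

test_that("collect_indices orders and validates the four indices", {
  toy <- toy_models_and_ensemble()
  img_a <- toy_image(1, "A", "a1")
  img_b <- toy_image(2, "B", "b1")
  X <- collect_indices(toy$models, img_a, img_b)
  expect_length(X, 4)
  expect_true(all(X > 0 & X < 1))
  # equals the four direct similarity calls, in canonical order
  direct <- vapply(c("head", "pec", "FDF", "FDB"), function(pt)
    similarity(toy$models[[pt]], img_a[[pt]], img_b[[pt]]), numeric(1))
  expect_equal(X, unname(direct), tolerance = 1e-12)
  # order is canonical regardless of model argument order
  X2 <- collect_indices(toy$models[c("FDB", "pec", "head", "FDF")],
                        img_a, img_b)
  expect_equal(X2, X)
  # missing patch is named
  img_bad <- img_a; img_bad$pec <- NULL
  expect_error(collect_indices(toy$models, img_bad, img_b), "pec")
  expect_error(collect_indices(toy$models[1:3], img_a, img_b), "four")
})

test_that("fit_ensemble learns a one-feature rule and is deterministic", {
  X <- patchid:::with_seed(2, matrix(runif(400 * 4), 400, 4))
  y <- as.numeric(X[, 1] > 0.5)
  ens <- fit_ensemble(X, y, fusion_params(max_trees = 60), rng = 7)
  pred <- final_similarity(ens, X)
  acc <- mean((decide(pred) == "same") == (y == 1))
  expect_gte(acc, 0.99)

  # determinism
  ens2 <- fit_ensemble(X, y, fusion_params(max_trees = 60), rng = 7)
  expect_equal(final_similarity(ens2, X), pred, tolerance = 0)

  # byte-identical serialization under a fixed seed
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  save_ensemble(ens, f1); save_ensemble(ens2, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(fit_ensemble(X, rep(1, 400)), "single class")
})

test_that("a single stump is a one-coordinate step function", {
  X <- patchid:::with_seed(3, matrix(runif(300 * 4), 300, 4))
  y <- as.numeric(X[, 3] > 0.6)
  ens <- fit_ensemble(X, y, fusion_params(max_trees = 1, depth = 1,
                                          valid_fraction = 0,
                                          subsample = 1), rng = 1)
  expect_length(ens$trees, 1)
  tree <- ens$trees[[1]]
  root <- tree[[1]]
  expect_equal(root$feature, 3)
  # prediction depends only on which side of the threshold coordinate 3 is
  probe <- function(x3) final_similarity(ens, c(0.1, 0.9, x3, 0.5))
  lo <- probe(root$threshold - 0.05); hi <- probe(root$threshold + 0.05)
  expect_false(isTRUE(all.equal(lo, hi)))
  expect_equal(probe(root$threshold - 0.2), lo)
  expect_equal(probe(root$threshold + 0.2), hi)
})

test_that("final_similarity sums shrunken trees, clips, and guards state", {
  # hand-built two-tree ensemble evaluated against a manual sum
  leaf <- function(v) list(feature = NA_integer_, threshold = NA_real_,
                           left = NA_integer_, right = NA_integer_,
                           value = v)
  node <- function(f, t, l, r) list(feature = f, threshold = t,
                                    left = l, right = r, value = 0)
  t1 <- list(node(1, 0.5, 2, 3), leaf(-0.4), leaf(0.8))
  t2 <- list(node(2, 0.3, 2, 3), leaf(0.2), leaf(-0.1))
  ens <- structure(list(base = 0.5, shrinkage = 0.4, trees = list(t1, t2),
                        fitted = TRUE, params = NULL),
                   class = "EnsembleModel")
  x <- c(0.7, 0.1, 0.5, 0.5)     # t1 -> 0.8, t2 -> 0.2
  expect_equal(final_similarity(ens, x), 0.5 + 0.4 * (0.8 + 0.2))
  x2 <- c(0.2, 0.9, 0, 0)        # t1 -> -0.4, t2 -> -0.1
  expect_equal(final_similarity(ens, x2), 0.5 + 0.4 * (-0.5))
  # clipping into [0, 1]
  ens_hot <- ens; ens_hot$shrinkage <- 2
  expect_equal(final_similarity(ens_hot, x), 1)    # raw 2.5
  expect_equal(final_similarity(ens_hot, x2), 0)   # raw -0.5

  # zero trees: the base score identity
  ens0 <- structure(list(base = 0.5, shrinkage = 0.1, trees = list(),
                         fitted = TRUE, params = NULL),
                    class = "EnsembleModel")
  expect_equal(final_similarity(ens0, x), 0.5)

  unfit <- ens; unfit$fitted <- FALSE
  expect_error(final_similarity(unfit, x), "not fitted")
  expect_error(final_similarity(ens, c(0.5, 0.5)), "length 4")
})

test_that("prediction is piecewise constant within a fitted cell", {
  X <- patchid:::with_seed(5, matrix(runif(300 * 4), 300, 4))
  y <- as.numeric(X[, 2] + 0.3 * X[, 4] > 0.7)
  ens <- fit_ensemble(X, y, fusion_params(max_trees = 30), rng = 2)
  # collect every split threshold on every feature, probe inside one cell
  thr <- list(numeric(0), numeric(0), numeric(0), numeric(0))
  for (tr in ens$trees) for (nd in tr)
    if (!is.na(nd$feature))
      thr[[nd$feature]] <- c(thr[[nd$feature]], nd$threshold)
  mid <- vapply(thr, function(t) {
    t <- sort(unique(c(0, t, 1)))
    gaps <- diff(t); i <- which.max(gaps)
    c(t[i] + gaps[i] * 0.25, t[i] + gaps[i] * 0.75)
  }, numeric(2))
  p1 <- final_similarity(ens, mid[1, ])
  p2 <- final_similarity(ens, mid[2, ])
  expect_equal(p1, p2)   # same cell on every feature
})

test_that("decide applies the strict 0.5 rule", {
  expect_equal(decide(0.51), "same")
  expect_equal(decide(0.50), "different")
  expect_equal(decide(0), "different")
  expect_equal(decide(1), "same")
  expect_equal(decide(c(0.2, 0.7)), c("different", "same"))
  expect_error(decide(1.2), "out of")
})

test_that("ensemble JSON round-trips predictions exactly", {
  X <- patchid:::with_seed(8, matrix(runif(200 * 4), 200, 4))
  y <- as.numeric(X[, 1] > X[, 2])
  ens <- fit_ensemble(X, y, fusion_params(max_trees = 25), rng = 3)
  f <- tempfile(fileext = ".json")
  save_ensemble(ens, f)
  back <- load_ensemble(f)
  expect_equal(final_similarity(back, X), final_similarity(ens, X),
               tolerance = 0)
})
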