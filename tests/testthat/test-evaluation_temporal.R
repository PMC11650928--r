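# Metrics, ROC/AUC with oracle, shark-based reduction, temporal analysis.

test_that("confusion_metrics hand counts and the accuracy + MAE identity", {
  m <- confusion_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$precision, 0.5)
  expect_equal(m$mae, 0.25)
  expect_identical(m$accuracy + m$mae, 1)

  all_good <- confusion_metrics(c(1, 0, 1), c(1, 0, 1))
  expect_equal(unlist(all_good[c("accuracy", "precision", "mae")]),
               c(accuracy = 1, precision = 1, mae = 0))

  none_pos <- confusion_metrics(c(0, 0, 0), c(1, 0, 0))
  expect_true(is.nan(none_pos$precision))
  expect_false(none_pos$precision_defined)
  expect_equal(none_pos$accuracy, 2 / 3)
  expect_identical(none_pos$accuracy + none_pos$mae, 1)

  expect_error(confusion_metrics(c(1, 0), c(1)), "equal")
})

test_that("roc_auc matches the O(n^2) concordance oracle, handles ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep_len(0:1, 10))$auc, 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")

  concordance <- function(s, y) {
    sp <- s[y == 1]; sn <- s[y == 0]
    tot <- 0
    for (a in sp) for (b in sn)
      tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(sp) * length(sn))
  }
  for (i in 1:20) {
    n <- patchid:::with_seed(i, sample(10:60, 1))
    s <- patchid:::with_seed(i * 3 + 1,
                             round(runif(n), 2))   # rounded: forces ties
    y <- patchid:::with_seed(i * 3 + 2, rbinom(n, 1, 0.4))
    if (length(unique(y)) < 2) next
    r <- roc_auc(s, y)
    expect_equal(r$auc, concordance(s, y), tolerance = 1e-12)
    expect_equal(r$roc$fpr[1], 0)
    expect_equal(r$roc$tpr[nrow(r$roc)], 1)
  }
})

test_that("label-permutation null keeps AUC near 0.5", {
  s <- patchid:::with_seed(42, runif(600))
  y <- rep_len(0:1, 600)
  y_perm <- patchid:::with_seed(43, sample(y))
  auc <- roc_auc(s, y_perm)$auc
  expect_gte(auc, 0.4); expect_lte(auc, 0.6)
})

test_that("image_based_eval scores pairs through the full chain", {
  toy <- toy_models_and_ensemble()
  imgs <- lapply(1:4, function(i)
    toy_image(i, c("A", "A", "B", "B")[i], sprintf("im%d", i)))
  prs <- list(
    list(image_a = imgs[[1]], image_b = imgs[[2]], label = 1),
    list(image_a = imgs[[1]], image_b = imgs[[3]], label = 0),
    list(image_a = imgs[[2]], image_b = imgs[[4]], label = 0),
    list(image_a = imgs[[3]], image_b = imgs[[4]], label = 1))
  rep1 <- image_based_eval(toy$ensemble, toy$models, prs)
  expect_s3_class(rep1, "EvaluationReport")
  expect_equal(rep1$n_pairs, 4)
  expect_identical(rep1$accuracy + rep1$mae, 1)
  # permutation invariance of the metrics
  rep2 <- image_based_eval(toy$ensemble, toy$models, prs[c(3, 1, 4, 2)])
  expect_equal(rep2$accuracy, rep1$accuracy)
  expect_equal(rep2$auc, rep1$auc)
  expect_error(image_based_eval(toy$ensemble, toy$models, list()), "empty")
})

test_that("shark-based scores equal the brute-force K1 x K2 mean", {
  toy <- toy_models_and_ensemble()
  gA <- shark_group("A", lapply(1:2, function(i)
    toy_image(i, "A", sprintf("a%d", i))))
  gB <- shark_group("B", lapply(1:3, function(i)
    toy_image(10 + i, "B", sprintf("b%d", i))))
  sc <- patchid:::group_pair_score(toy$ensemble, toy$models, gA, gB)
  # oracle: loop over all 2 x 3 = 6 ordered cross pairs
  vals <- c()
  for (a in gA$images) for (b in gB$images)
    vals <- c(vals, final_similarity(toy$ensemble,
                                     collect_indices(toy$models, a, b)))
  expect_length(vals, 6)
  expect_equal(sc, mean(vals), tolerance = 1e-12)
  expect_gte(sc, min(vals)); expect_lte(sc, max(vals))

  # groups of size 1 reduce shark-based to image-based on induced pairs
  g1 <- shark_group("A", gA$images[1])
  g2 <- shark_group("B", gB$images[1])
  g3 <- shark_group("C", list(toy_image(99, "C", "c1")))
  sb <- shark_based_eval(toy$ensemble, toy$models, list(g1, g2, g3),
                         halving = FALSE)
  prs <- list(
    list(image_a = g1$images[[1]], image_b = g2$images[[1]], label = 0),
    list(image_a = g1$images[[1]], image_b = g3$images[[1]], label = 0),
    list(image_a = g2$images[[1]], image_b = g3$images[[1]], label = 0))
  ib <- image_based_eval(toy$ensemble, toy$models, prs)
  expect_equal(sort(sb$scores), sort(ib$scores), tolerance = 1e-12)

  expect_error(shark_group("A", list()), "zero images")
  expect_error(shark_based_eval(toy$ensemble, toy$models, list(gA)),
               ">= 2 groups")
})

test_that("halving adds a positive instance for groups with >= 2 images", {
  toy <- toy_models_and_ensemble()
  gA <- shark_group("A", lapply(1:4, function(i)
    toy_image(i, "A", sprintf("a%d", i))))
  gB <- shark_group("B", list(toy_image(20, "B", "b1")))
  sb <- shark_based_eval(toy$ensemble, toy$models, list(gA, gB))
  # one cross pair (label 0) + one halving positive for gA
  expect_equal(sort(sb$labels), c(0, 1))
  half <- patchid:::group_pair_score(toy$ensemble, toy$models,
                                     shark_group("A", gA$images[1:2]),
                                     shark_group("A", gA$images[3:4]))
  expect_equal(sb$scores[sb$labels == 1], half, tolerance = 1e-12)
})

test_that("temporal_analysis orders markers numerically and reduces", {
  toy <- toy_models_and_ensemble()
  base_g <- shark_group("A", lapply(1:2, function(i)
    toy_image(i, "A", sprintf("a%d", i))))
  tg <- list(
    T2 = shark_group("A", list(toy_image(5, "A", "t2"))),
    T10 = shark_group("A", list(toy_image(6, "A", "t10"))))
  out <- temporal_analysis(toy$ensemble, toy$models, base_g, tg)
  expect_equal(names(out$similarity), c("T2", "T10"))
  expect_identical(out$stable, all(out$similarity > 0.5))

  # baseline against itself (pseudo-marker) equals the self-similarity score
  self <- temporal_analysis(toy$ensemble, toy$models, base_g,
                            list(T0 = base_g))
  direct <- patchid:::group_pair_score(toy$ensemble, toy$models,
                                       base_g, base_g)
  expect_equal(unname(self$similarity["T0"]), direct, tolerance = 1e-12)

  expect_error(temporal_analysis(toy$ensemble, toy$models, base_g,
                                 setNames(tg, c("T2", "bad"))), "malformed")
  expect_error(temporal_analysis(toy$ensemble, toy$models, base_g, list()),
               "no time markers")
})
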