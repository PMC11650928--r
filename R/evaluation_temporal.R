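# Evaluation: image-based (one decision per image pair) and shark-based
# (one decision per group pair, from the mean of all K1 x K2 cross-group
# final indices), plus the temporal pattern-stability analysis that scores
# each time marker against the same shark's baseline photographs.
#
# Metrics follow the verification convention: positive = "same shark";
# MAE is the mean absolute error of the *binarized* decisions against the
# labels, hence accuracy + MAE = 1 exactly.

#' Accuracy, precision and MAE of binary decisions
#'
#' @param decisions Vector in `{0, 1}` (1 = "same shark").
#' @param labels Vector in `{0, 1}`, same length.
#' @return List with `accuracy`, `precision` (`NaN` with
#'   `precision_defined = FALSE` when there are no positive decisions),
#'   `mae`. `accuracy + mae == 1` exactly.
#' @export
confusion_metrics <- function(decisions, labels) {
  if (length(decisions) != length(labels) || !length(labels))
    stopf("decisions and labels must have equal positive length")
  decisions <- as.numeric(decisions); labels <- as.numeric(labels)
  acc <- mean(decisions == labels)
  tp <- sum(decisions == 1 & labels == 1)
  fp <- sum(decisions == 1 & labels == 0)
  prec_def <- (tp + fp) > 0
  list(accuracy = acc,
       precision = if (prec_def) tp / (tp + fp) else NaN,
       precision_defined = prec_def,
       mae = mean(abs(decisions - labels)))
}

#' ROC curve and AUC
#'
#' The ROC is swept over all distinct score thresholds; AUC is computed by
#' the trapezoid rule, which equals the pairwise concordance probability
#' `P(s_pos > s_neg) + 0.5 P(s_pos = s_neg)`.
#'
#' @param scores Numeric scores (larger = more likely same).
#' @param labels Vector in `{0, 1}`.
#' @return List with `roc` (data frame `fpr`, `tpr`, including the (0,0)
#'   and (1,1) endpoints) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0)
    stopf("ROC requires both classes (got %d positives, %d negatives)",
          np, nn)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # collapse tied scores into single threshold steps
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tp[last] / np); fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

make_report <- function(scores, labels) {
  dec <- as.numeric(decide(scores) == "same")
  cm <- confusion_metrics(dec, labels)
  rc <- if (length(unique(labels)) == 2) roc_auc(scores, labels)
        else list(roc = NULL, auc = NA_real_)   # degenerate label set
  structure(list(n_pairs = length(labels), accuracy = cm$accuracy,
                 precision = cm$precision,
                 precision_defined = cm$precision_defined, mae = cm$mae,
                 roc = rc$roc, auc = rc$auc, scores = scores,
                 labels = labels),
            class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat(sprintf(
    "EvaluationReport: %d pairs | accuracy %.1f%% | precision %s | MAE %.3f | AUC %.3f\n",
    x$n_pairs, 100 * x$accuracy,
    if (x$precision_defined) sprintf("%.1f%%", 100 * x$precision)
    else "undefined", x$mae, x$auc))
  invisible(x)
}

#' Image-based evaluation of the fused model
#'
#' Scores every image pair with the ensemble over the four patch indices
#' and decides at 0.5.
#'
#' @param ensemble Fitted `EnsembleModel`.
#' @param patch_models List of 4 `PatchModel`.
#' @param pairs List of pair samples: each a list with `image_a`, `image_b`
#'   (named 4-patch lists) and `label` in `{0, 1}`. Alternatively supply
#'   `scores`/`labels` directly via [score_report()].
#' @return An `EvaluationReport`.
#' @export
image_based_eval <- function(ensemble, patch_models, pairs) {
  if (!length(pairs)) stopf("empty pair set")
  scores <- vapply(pairs, function(p)
    final_similarity(ensemble,
                     collect_indices(patch_models, p$image_a, p$image_b)),
    numeric(1))
  labels <- vapply(pairs, function(p) p$label, numeric(1))
  make_report(scores, labels)
}

#' Build an evaluation report from precomputed scores
#' @param scores Final similarity indices.
#' @param labels Vector in `{0, 1}`.
#' @return An `EvaluationReport`.
#' @export
score_report <- function(scores, labels) make_report(scores, labels)

#' A group of images confidently assigned to one shark
#' @param shark_id Identity label.
#' @param images List of named 4-patch lists (one per image).
#' @return A `SharkGroup`.
#' @export
shark_group <- function(shark_id, images) {
  if (!length(images)) stopf("group for %s has zero images", shark_id)
  structure(list(shark_id = shark_id, images = images, K = length(images)),
            class = "SharkGroup")
}

# mean of all K1 x K2 cross-group final indices
group_pair_score <- function(ensemble, patch_models, g1, g2) {
  s <- vapply(g1$images, function(a)
    vapply(g2$images, function(b)
      final_similarity(ensemble, collect_indices(patch_models, a, b)),
      numeric(1)),
    numeric(g2$K))
  mean(s)
}

#' Shark-based evaluation over image groups
#'
#' Every unordered pair of groups is scored by the mean of its K1 x K2
#' cross-group final similarity indices and decided at 0.5; the pair label
#' is 1 when the two groups carry the same shark id. Additionally, every
#' group with at least 2 images contributes a same-shark instance by
#' halving: its images are split into two halves compared against each
#' other.
#'
#' @param ensemble Fitted `EnsembleModel`.
#' @param patch_models List of 4 `PatchModel`.
#' @param groups List of `SharkGroup` (>= 2).
#' @param halving Include the within-group halving positives
#'   (default TRUE).
#' @return An `EvaluationReport`.
#' @export
shark_based_eval <- function(ensemble, patch_models, groups,
                             halving = TRUE) {
  if (length(groups) < 2) stopf("need >= 2 groups")
  scores <- numeric(0); labels <- numeric(0)
  if (length(groups) >= 2) {
    for (i in seq_len(length(groups) - 1L)) for (j in (i + 1L):length(groups)) {
      scores <- c(scores, group_pair_score(ensemble, patch_models,
                                           groups[[i]], groups[[j]]))
      labels <- c(labels,
                  as.numeric(groups[[i]]$shark_id == groups[[j]]$shark_id))
    }
  }
  if (halving) {
    for (g in groups) {
      if (g$K < 2) next
      h <- g$K %/% 2L
      g1 <- shark_group(g$shark_id, g$images[seq_len(h)])
      g2 <- shark_group(g$shark_id, g$images[(h + 1L):g$K])
      scores <- c(scores, group_pair_score(ensemble, patch_models, g1, g2))
      labels <- c(labels, 1)
    }
  }
  make_report(scores, labels)
}

#' Temporal pattern-stability analysis against baseline
#'
#' For each time marker `Tk`, computes the shark-based score of that
#' marker's group against the same shark's baseline group (mean of all
#' cross indices). The pattern is judged stable when every marker scores
#' strictly above the 0.5 similarity threshold.
#'
#' @param ensemble Fitted `EnsembleModel`.
#' @param patch_models List of 4 `PatchModel`.
#' @param baseline_group `SharkGroup` of baseline images.
#' @param time_groups Named list of `SharkGroup`, names are markers
#'   (`"T1"`, ...). Ordered by numeric marker index in the result.
#' @return List with `similarity` (named numeric, marker order numeric),
#'   `stable` (logical verdict) and `shark_id`.
#' @export
temporal_analysis <- function(ensemble, patch_models, baseline_group,
                              time_groups) {
  if (!length(time_groups)) stopf("no time markers supplied")
  idx <- time_marker_index(names(time_groups))
  ord <- order(idx)
  sims <- vapply(time_groups[ord], function(g)
    group_pair_score(ensemble, patch_models, g, baseline_group),
    numeric(1))
  names(sims) <- names(time_groups)[ord]
  list(shark_id = baseline_group$shark_id, similarity = sims,
       stable = all(sims > 0.5))
}
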