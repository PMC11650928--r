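# Held-out-individual splits, labelled pair generation and batching.
# The verification task is trained and tested on *individuals* never shared
# between the two sides, so the model must match patterns rather than
# memorize photographs.

#' Split a manifest by individual, holding out whole sharks
#'
#' @param rows Manifest data frame.
#' @param n_train Named or positional counts `c(adult, juvenile, neonate)`
#'   of training individuals per life stage.
#' @param seed Integer seed.
#' @return A `SplitPlan`: list with `train_ids`, `test_ids` (disjoint,
#'   covering all ids) and `n_train`.
#' @export
split_by_individual <- function(rows, n_train, seed) {
  stages <- c("adult", "juvenile", "neonate")
  if (is.null(names(n_train))) names(n_train) <- stages
  ids_by_stage <- lapply(stages, function(st)
    sort(unique(rows$shark_id[rows$life_stage == st])))
  names(ids_by_stage) <- stages
  train_ids <- character(0)
  with_seed(derive_seed(seed, "split"), {
    for (st in stages) {
      avail <- ids_by_stage[[st]]
      k <- n_train[[st]]
      if (length(avail) < k)
        stopf("stage '%s' has %d individuals but %d requested for training",
              st, length(avail), k)
      if (k > 0)
        train_ids <- c(train_ids, sample(avail, k))
    }
  })
  all_ids <- sort(unique(rows$shark_id))
  structure(list(train_ids = sort(train_ids),
                 test_ids = setdiff(all_ids, train_ids),
                 n_train = n_train),
            class = "SplitPlan")
}

#' Generate labelled same/different pairs
#'
#' Positives are unordered pairs of *different* source images of the same
#' shark; negatives are unordered cross-shark image pairs. Sampling is
#' without replacement. With `n_pairs = NULL` the full set of positive and
#' negative pairs is returned (exhaustive mode).
#'
#' @param items Data frame with one row per available patch/image instance:
#'   columns `shark_id`, `source_image_id`, plus any payload columns
#'   (e.g. an index into a patch list).
#' @param patch_type Patch type tag carried on the pairs.
#' @param n_pairs Total number of pairs, or `NULL` for exhaustive.
#' @param positive_fraction Fraction of positives
#'   (`round(n_pairs * positive_fraction)` positives are produced).
#' @param rng Integer seed.
#' @return Data frame with columns `a`, `b` (row indices into `items`),
#'   `label` (1 same shark, 0 different) and `patch_type`.
#' @export
make_pairs <- function(items, patch_type = "head", n_pairs = NULL,
                       positive_fraction = 0.5, rng = 1L) {
  if (length(unique(items$shark_id)) < 2)
    stopf("need >= 2 sharks to form pairs")
  idx <- seq_len(nrow(items))
  # all unordered candidate pairs, split by label
  cmb <- utils::combn(idx, 2)
  same <- items$shark_id[cmb[1, ]] == items$shark_id[cmb[2, ]]
  diff_img <- items$source_image_id[cmb[1, ]] != items$source_image_id[cmb[2, ]]
  pos_all <- which(same & diff_img)
  neg_all <- which(!same)
  pick <- function(pool, k, seed_key) {
    if (k > length(pool))
      stopf("requested %d pairs but only %d are available", k, length(pool))
    if (k == length(pool)) pool
    else with_seed(derive_seed(rng, seed_key), sample(pool, k))
  }
  if (is.null(n_pairs)) {
    sel_pos <- pos_all; sel_neg <- neg_all
  } else {
    k_pos <- round(n_pairs * positive_fraction)
    k_neg <- n_pairs - k_pos
    if (k_pos > length(pos_all))
      stopf("requested %d positive pairs but only %d distinct ones exist",
            k_pos, length(pos_all))
    if (k_neg > length(neg_all))
      stopf("requested %d negative pairs but only %d distinct ones exist",
            k_neg, length(neg_all))
    sel_pos <- pick(pos_all, k_pos, "pos")
    sel_neg <- pick(neg_all, k_neg, "neg")
  }
  sel <- c(sel_pos, sel_neg)
  out <- data.frame(a = cmb[1, sel], b = cmb[2, sel],
                    label = rep(c(1L, 0L), c(length(sel_pos),
                                             length(sel_neg))),
                    patch_type = patch_type, stringsAsFactors = FALSE)
  if (is.null(n_pairs)) return(out)
  with_seed(derive_seed(rng, "shuffle"), out[sample.int(nrow(out)), ,
                                             drop = FALSE])
}

#' Split pairs into randomized minibatches
#'
#' One random permutation per call (epoch), then consecutive chunks of
#' `batch_size`; the last batch may be smaller.
#'
#' @param pairs Data frame of pairs.
#' @param batch_size Positive integer (default 16).
#' @param rng Integer seed.
#' @return List of data frames.
#' @export
batches <- function(pairs, batch_size = 16L, rng = 1L) {
  if (batch_size < 1) stopf("batch_size must be >= 1")
  n <- nrow(pairs)
  ord <- with_seed(derive_seed(rng, "epoch"), sample.int(n))
  starts <- seq(1L, n, by = batch_size)
  lapply(starts, function(s)
    pairs[ord[s:min(s + batch_size - 1L, n)], , drop = FALSE])
}

#' Audit that no test individual leaks into a training pair set
#' @param items Instance table used to build the pairs.
#' @param pairs Pair data frame from [make_pairs()].
#' @param plan A `SplitPlan`.
#' @return `TRUE` invisibly; errors naming leaked ids otherwise.
#' @export
audit_no_leakage <- function(items, pairs, plan) {
  used <- unique(items$shark_id[c(pairs$a, pairs$b)])
  leaked <- intersect(used, plan$test_ids)
  if (length(leaked))
    stopf("test individuals leaked into training pairs: %s",
          paste(leaked, collapse = ", "))
  invisible(TRUE)
}
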