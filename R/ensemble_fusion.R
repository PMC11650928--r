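# Gradient-boosted fusion of the four patch similarity indices.
#
# The four per-patch indices are concatenated into the ordered vector
# X = (s_head, s_pec, s_FDF, s_FDB) and regressed onto the pair label by a
# boosted ensemble of shallow regression trees: starting from a base score
# of 0.5, each tree i fits the residual left by its predecessors and enters
# the sum with shrinkage a_i, so the prediction is
# base + sum_i a_i T_i(X | r_{i-1}), r_0 = 0. The number of trees M is
# chosen automatically by early stopping on a held-out fraction of the
# training pairs. The raw boosted prediction is clipped into [0, 1]; the
# decision rule is strict: "same shark" iff the final index exceeds 0.5.

INDEX_ORDER <- PATCH_TYPES  # (head, pec, FDF, FDB)

#' Collect the four patch similarity indices for one image pair
#'
#' @param patch_models List of 4 `PatchModel` (any order; they must cover
#'   the four patch types).
#' @param image_a,image_b Named lists of patches per patch type (as from
#'   [patches_from_row()]).
#' @return Numeric vector `X = (s_head, s_pec, s_FDF, s_FDB)`.
#' @export
collect_indices <- function(patch_models, image_a, image_b) {
  types <- vapply(patch_models, function(m) m$patch_type, character(1))
  if (!setequal(types, INDEX_ORDER) || anyDuplicated(types))
    stopf("patch_models must cover exactly the four patch types")
  names(patch_models) <- types
  X <- vapply(INDEX_ORDER, function(pt) {
    for (side in c("a", "b")) {
      img <- if (side == "a") image_a else image_b
      if (is.null(img[[pt]]))
        stopf("image %s is missing patch '%s'",
              img[[1]]$source_image_id %||% side, pt)
    }
    similarity(patch_models[[pt]], image_a[[pt]], image_b[[pt]])
  }, numeric(1))
  unname(X)
}

## ---- regression trees ----------------------------------------------------

# Fit one depth-limited least-squares regression tree on (X, r).
# Nodes are rows of a data.frame; leaves carry the mean residual.
fit_tree <- function(X, r, depth, min_node = 5L) {
  nodes <- list()
  new_node <- function() length(nodes) + 1L
  grow <- function(rows, d) {
    id <- new_node()
    nodes[[id]] <<- list(feature = NA_integer_, threshold = NA_real_,
                         left = NA_integer_, right = NA_integer_,
                         value = mean(r[rows]))
    if (d >= depth || length(rows) < 2L * min_node) return(id)
    best <- NULL
    base_sse <- sum((r[rows] - mean(r[rows]))^2)
    for (f in seq_len(ncol(X))) {
      xv <- X[rows, f]
      ord <- order(xv)
      xs <- xv[ord]; rs <- r[rows][ord]
      csum <- cumsum(rs); tot <- csum[length(rs)]
      csq <- cumsum(rs^2); totq <- csq[length(rs)]
      n <- length(rs)
      ks <- which(diff(xs) > 0)                 # split between k and k+1
      ks <- ks[ks >= min_node & (n - ks) >= min_node]
      if (!length(ks)) next
      sseL <- csq[ks] - csum[ks]^2 / ks
      sseR <- (totq - csq[ks]) - (tot - csum[ks])^2 / (n - ks)
      gain <- base_sse - (sseL + sseR)
      kbest <- ks[which.max(gain)]
      if (is.null(best) || max(gain) > best$gain)
        best <- list(gain = max(gain), feature = f,
                     threshold = (xs[kbest] + xs[kbest + 1]) / 2)
    }
    if (is.null(best) || best$gain <= 1e-12) return(id)
    go_left <- X[rows, best$feature] <= best$threshold
    l <- grow(rows[go_left], d + 1L)
    rgt <- grow(rows[!go_left], d + 1L)
    nodes[[id]]$feature <<- best$feature
    nodes[[id]]$threshold <<- best$threshold
    nodes[[id]]$left <<- l
    nodes[[id]]$right <<- rgt
    id
  }
  grow(seq_along(r), 0L)
  nodes
}

predict_tree <- function(nodes, X) {
  out <- numeric(nrow(X))
  walk <- function(id, rows) {
    nd <- nodes[[id]]
    if (is.na(nd$feature)) { out[rows] <<- nd$value; return(invisible(NULL)) }
    go_left <- X[rows, nd$feature] <= nd$threshold
    if (any(go_left)) walk(nd$left, rows[go_left])
    if (any(!go_left)) walk(nd$right, rows[!go_left])
    invisible(NULL)
  }
  walk(1L, seq_len(nrow(X)))
  out
}

#' Fusion hyperparameters
#'
#' @param max_trees Cap on the number of boosted trees.
#' @param depth Maximum tree depth.
#' @param shrinkage Per-tree coefficient a_i (learning rate).
#' @param valid_fraction Held-out fraction of the training pairs used to
#'   pick M by early stopping.
#' @param patience Early-stopping patience, rounds.
#' @param min_node Minimum observations per leaf.
#' @param subsample Row fraction drawn (without replacement) per tree;
#'   stochastic boosting diversifies split thresholds, which keeps the
#'   fitted function from collapsing to a few-step staircase when the
#'   fusion pool is cleanly separable.
#' @return Parameter list.
#' @export
fusion_params <- function(max_trees = 200L, depth = 3L, shrinkage = 0.1,
                          valid_fraction = 0.2, patience = 10L,
                          min_node = 5L, subsample = 0.5) {
  list(max_trees = as.integer(max_trees), depth = as.integer(depth),
       shrinkage = shrinkage, valid_fraction = valid_fraction,
       patience = as.integer(patience), min_node = as.integer(min_node),
       subsample = subsample)
}

#' Fit the gradient-boosted fusion ensemble
#'
#' @param X_train Numeric matrix `n x 4` of index vectors (columns in the
#'   fixed order head, pec, FDF, FDB).
#' @param labels Vector in `{0, 1}`.
#' @param params From [fusion_params()].
#' @param rng Integer seed (validation split).
#' @return An `EnsembleModel`: `base` (0.5), `shrinkage`, `trees`
#'   (list of fitted trees; length M), `fitted` flag.
#' @export
fit_ensemble <- function(X_train, labels, params = fusion_params(),
                         rng = 1L) {
  X_train <- as.matrix(X_train)
  if (length(unique(labels)) < 2)
    stopf("labels contain a single class; need both same and different pairs")
  n <- nrow(X_train)
  n_val <- if (params$valid_fraction > 0 && n >= 10)
    max(1L, round(params$valid_fraction * n)) else 0L
  val_idx <- if (n_val > 0)
    with_seed(derive_seed(rng, "fusion_val"), sample.int(n, n_val))
  else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xt <- X_train[tr_idx, , drop = FALSE]; yt <- labels[tr_idx]
  Xv <- X_train[val_idx, , drop = FALSE]; yv <- labels[val_idx]

  base <- 0.5
  pred_t <- rep(base, length(tr_idx))
  pred_v <- rep(base, length(val_idx))
  trees <- list()
  best_m <- 0L; best_err <- Inf; stall <- 0L
  sub_frac <- params$subsample %||% 1
  for (m in seq_len(params$max_trees)) {
    r <- yt - pred_t
    rows_m <- if (sub_frac < 1)
      with_seed(derive_seed(rng, "subsample", m),
                sort(sample.int(length(yt), max(2L * params$min_node,
                                                round(sub_frac * length(yt))))))
    else seq_along(yt)
    tree <- fit_tree(Xt[rows_m, , drop = FALSE], r[rows_m], params$depth,
                     params$min_node)
    trees[[m]] <- tree
    pred_t <- pred_t + params$shrinkage * predict_tree(tree, Xt)
    if (n_val > 0) {
      pred_v <- pred_v + params$shrinkage * predict_tree(tree, Xv)
      err <- mean((yv - pred_v)^2)
      if (err < best_err - 1e-10) {
        best_err <- err; best_m <- m; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= params$patience) break
      }
    } else best_m <- m
  }
  structure(list(base = base, shrinkage = params$shrinkage,
                 trees = trees[seq_len(best_m)], fitted = TRUE,
                 params = params),
            class = "EnsembleModel")
}

#' Final similarity index of an index vector under a fitted ensemble
#'
#' @param ensemble A fitted `EnsembleModel`.
#' @param X Numeric vector of length 4, or an `n x 4` matrix.
#' @return Final similarity index (or vector) clipped into `[0, 1]`.
#' @export
final_similarity <- function(ensemble, X) {
  if (is.null(ensemble$fitted) || !ensemble$fitted)
    stopf("ensemble is not fitted")
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != 4) stopf("index vectors must have length 4")
  pred <- rep(ensemble$base, nrow(X))
  for (tree in ensemble$trees)
    pred <- pred + ensemble$shrinkage * predict_tree(tree, X)
  out <- pmin(pmax(pred, 0), 1)
  if (nrow(X) == 1) out[1] else out
}

#' Same/different decision from a final similarity index
#'
#' @param final_index Value(s) in `[0, 1]`.
#' @return `"same"` iff the index is strictly greater than 0.5, else
#'   `"different"`.
#' @export
decide <- function(final_index) {
  if (any(final_index < 0 | final_index > 1))
    stopf("final index out of [0, 1]")
  ifelse(final_index > 0.5, "same", "different")
}

#' Save / load a fitted ensemble (portable JSON)
#' @param ensemble A fitted `EnsembleModel`.
#' @param path Output JSON path.
#' @export
save_ensemble <- function(ensemble, path) {
  jsonlite::write_json(
    list(format_version = 1L, base = ensemble$base,
         shrinkage = ensemble$shrinkage, params = ensemble$params,
         trees = ensemble$trees),
    path, digits = I(17), auto_unbox = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @rdname save_ensemble
#' @return `load_ensemble()` returns the `EnsembleModel`.
#' @export
load_ensemble <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  trees <- lapply(x$trees, function(tr) lapply(tr, function(nd)
    list(feature = if (is.null(nd$feature)) NA_integer_
                   else as.integer(nd$feature),
         threshold = if (is.null(nd$threshold)) NA_real_
                     else as.numeric(nd$threshold),
         left = if (is.null(nd$left)) NA_integer_ else as.integer(nd$left),
         right = if (is.null(nd$right)) NA_integer_ else as.integer(nd$right),
         value = as.numeric(nd$value))))
  structure(list(base = x$base, shrinkage = x$shrinkage,
                 trees = trees, fitted = TRUE, params = x$params),
            class = "EnsembleModel")
}
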