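# Per-patch twin similarity network.
#
# Both patches pass through the *same* frozen backbone; each feature map is
# average-pooled over all spatial positions to an F-vector, the two vectors
# are concatenated (ordered: the network is not symmetric in its arguments)
# and classified by a small trainable head: a 32-unit ReLU dense layer and
# a 1-unit sigmoid output, the similarity index s in (0, 1) - the modelled
# probability that the two patches show the same individual.
#
# Only the head trains (binary cross-entropy, minibatch gradient descent or
# Adam); the backbone is bit-frozen and audited by checksum. The head also
# carries a per-feature standardization (mean/sd of the training
# embeddings, fitted once before gradient descent, not gradient-trained):
# random frozen features have wildly different scales and the head trains
# poorly on raw ones.

# Difference-oriented initialization: hidden unit pairs start as
# (+r, -r) / (-r, +r) projections of the two embeddings, so unit j
# activates on one-sided random projections of (z_a - z_b) and the output
# starts as "high similarity unless the embeddings differ". Plain random
# init also works but needs many more epochs to discover the difference
# structure; the initialization does not constrain what training can reach.
new_head <- function(F, seed) {
  with_seed(derive_seed(seed, "head_init"), {
    n_hidden <- 32L
    R <- matrix(stats::rnorm(F * (n_hidden / 2)), F) / sqrt(F)
    W1 <- rbind(cbind(R, -R), cbind(-R, R))
    W1 <- W1 + matrix(stats::rnorm(2 * F * n_hidden, 0, 0.01 / sqrt(F)),
                      2 * F, n_hidden)
    list(W1 = W1,
         b1 = rep(0, n_hidden),
         W2 = matrix(-1 / n_hidden, n_hidden, 1),
         b2 = 1,
         scale_mu = rep(0, F), scale_sd = rep(1, F))
  })
}

#' Create an untrained per-patch twin model
#'
#' @param patch_type One of `"head"`, `"pec"`, `"FDF"`, `"FDB"`.
#' @param backbone A `BackboneSpec` with weights (e.g. [tiny_backbone()]);
#'   shared by both branches.
#' @param seed Seed for head initialization.
#' @return A `PatchModel` list (`patch_type`, `backbone`, `head`).
#' @export
patch_model <- function(patch_type, backbone, seed = 1L) {
  if (!patch_type %in% PATCH_TYPES) stopf("invalid patch_type '%s'", patch_type)
  if (is.null(backbone$weights))
    stopf("backbone '%s' carries no weights", backbone$name)
  structure(list(patch_type = patch_type, backbone = backbone,
                 head = new_head(backbone$feature_dim, seed)),
            class = "PatchModel")
}

#' Embed a patch: backbone features, average-pooled per channel
#'
#' @param model A `PatchModel`.
#' @param patch A `Patch`; resized/rescaled to the backbone contract if
#'   needed.
#' @return Numeric vector of length `F` (unstandardized embedding).
#' @export
embed <- function(model, patch) {
  side <- model$backbone$input_side
  if (dim(patch$pixels)[1] != side || dim(patch$pixels)[2] != side)
    patch <- preprocess_for_backbone(patch, model$backbone)
  fm <- backbone_features(model$backbone, patch$pixels)
  apply(fm, 3, mean)
}

head_forward <- function(head, ea, eb) {
  # ea, eb: n x F matrices of raw embeddings
  za <- sweep(sweep(ea, 2, head$scale_mu), 2, head$scale_sd, "/")
  zb <- sweep(sweep(eb, 2, head$scale_mu), 2, head$scale_sd, "/")
  X <- cbind(za, zb)
  H <- X %*% head$W1 + matrix(head$b1, nrow(X), ncol(head$W1), byrow = TRUE)
  H[H < 0] <- 0
  list(p = as.vector(sigmoid(H %*% head$W2 + head$b2)), X = X, H = H)
}

#' Similarity index of two patches under one patch model
#'
#' @param model A `PatchModel`.
#' @param patch_a,patch_b Two patches of `model$patch_type`. Order matters:
#'   the concatenation is ordered, so `similarity(m, a, b)` need not equal
#'   `similarity(m, b, a)`.
#' @return Similarity index in `(0, 1)`.
#' @export
similarity <- function(model, patch_a, patch_b) {
  for (p in list(patch_a, patch_b))
    if (!identical(p$patch_type, model$patch_type))
      stopf("patch of type '%s' fed to a '%s' model", p$patch_type,
            model$patch_type)
  ea <- matrix(embed(model, patch_a), 1)
  eb <- matrix(embed(model, patch_b), 1)
  head_forward(model$head, ea, eb)$p
}

# gradient-descent core on precomputed raw embeddings; used by train_head
# and by the pipeline (which caches embeddings across pairs)
train_head_embedded <- function(model, EA, EB, y, epochs = 50,
                                learning_rate = 1e-3, seed = 1L,
                                batch_size = 16L, optimizer = c("sgd", "adam"),
                                weight_decay = 0) {
  optimizer <- match.arg(optimizer)
  if (length(unique(y)) < 2)
    stopf("training pairs must contain both classes")
  head <- new_head(model$backbone$feature_dim, seed)
  emb <- rbind(EA, EB)
  head$scale_mu <- colMeans(emb)
  # floor relative to the strongest feature: near-dead random channels must
  # not explode into huge z-scores
  sdv <- apply(emb, 2, stats::sd)
  head$scale_sd <- pmax(sdv, 1e-3 * max(sdv) + 1e-12)
  n <- length(y)
  mom <- list(); if (optimizer == "adam") {
    mom <- list(m = lapply(head[c("W1", "b1", "W2", "b2")], function(w) w * 0),
                v = lapply(head[c("W1", "b1", "W2", "b2")], function(w) w * 0),
                t = 0)
  }
  loss_history <- numeric(epochs)
  pair_df <- data.frame(i = seq_len(n))
  for (ep in seq_len(epochs)) {
    bs <- batches(pair_df, batch_size, rng = derive_seed(seed, "epoch", ep))
    for (bt in bs) {
      ii <- bt$i
      fw <- head_forward(head, EA[ii, , drop = FALSE], EB[ii, , drop = FALSE])
      m <- length(ii)
      dz2 <- matrix((fw$p - y[ii]) / m, m, 1)          # dL/dz2, BCE+sigmoid
      gW2 <- t(fw$H) %*% dz2
      gb2 <- sum(dz2)
      dH <- dz2 %*% t(head$W2)
      dH[fw$H <= 0] <- 0
      gW1 <- t(fw$X) %*% dH
      gb1 <- colSums(dH)
      grads <- list(W1 = gW1 + weight_decay * head$W1, b1 = gb1,
                    W2 = gW2 + weight_decay * head$W2, b2 = gb2)
      if (optimizer == "sgd") {
        for (nm in names(grads))
          head[[nm]] <- head[[nm]] - learning_rate * grads[[nm]]
      } else {
        mom$t <- mom$t + 1
        b1m <- 0.9; b2m <- 0.999; epsm <- 1e-8
        for (nm in names(grads)) {
          mom$m[[nm]] <- b1m * mom$m[[nm]] + (1 - b1m) * grads[[nm]]
          mom$v[[nm]] <- b2m * mom$v[[nm]] + (1 - b2m) * grads[[nm]]^2
          mhat <- mom$m[[nm]] / (1 - b1m^mom$t)
          vhat <- mom$v[[nm]] / (1 - b2m^mom$t)
          head[[nm]] <- head[[nm]] - learning_rate * mhat / (sqrt(vhat) + epsm)
        }
      }
    }
    p <- head_forward(head, EA, EB)$p
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    loss_history[ep] <- -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  model$head <- head
  list(model = model, loss_history = loss_history)
}

#' Train the similarity head on labelled pairs
#'
#' Minimizes binary cross-entropy between the similarity index and the pair
#' label by minibatch gradient descent. The backbone never changes
#' (verified by checksum); only the head's dense weights are updated.
#'
#' @param model A `PatchModel`.
#' @param pairs List of pair samples, each a list with `patch_a`, `patch_b`
#'   (of `model$patch_type`) and `label` in `{0, 1}`.
#' @param epochs Training epochs.
#' @param learning_rate Step size.
#' @param rng Integer seed (head init, batch order).
#' @param batch_size Minibatch size (default 16).
#' @param optimizer `"sgd"` (plain minibatch gradient descent, default) or
#'   `"adam"`.
#' @param weight_decay L2 penalty on the dense weights (default 0).
#' @return List with `model` (trained) and `loss_history` (one entry per
#'   epoch).
#' @export
train_head <- function(model, pairs, epochs = 50, learning_rate = 1e-3,
                       rng = 1L, batch_size = 16L, optimizer = "sgd",
                       weight_decay = 0) {
  if (!length(pairs)) stopf("no training pairs")
  y <- vapply(pairs, function(p) p$label, numeric(1))
  if (length(unique(y)) < 2)
    stopf("training pairs must contain both classes (got all label %d)", y[1])
  before <- backbone_checksum(model$backbone)
  EA <- t(vapply(pairs, function(p) embed(model, p$patch_a),
                 numeric(model$backbone$feature_dim)))
  EB <- t(vapply(pairs, function(p) embed(model, p$patch_b),
                 numeric(model$backbone$feature_dim)))
  out <- train_head_embedded(model, EA, EB, y, epochs = epochs,
                             learning_rate = learning_rate, seed = rng,
                             batch_size = batch_size, optimizer = optimizer,
                             weight_decay = weight_decay)
  stopifnot(identical(backbone_checksum(out$model$backbone), before))
  out
}

## ---- persistence ----------------------------------------------------------

# 17 significant digits: doubles survive the JSON round trip bit-exactly
num_json <- function(x, path) {
  jsonlite::write_json(x, path, digits = I(17), auto_unbox = TRUE)
}

#' Save a patch model to a directory
#'
#' Writes a JSON spec (backbone name/provenance, feature dim, patch type)
#' plus all weight arrays in JSON at full precision.
#'
#' @param model A `PatchModel`.
#' @param path Directory (created).
#' @export
save_model <- function(model, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  spec <- list(format_version = 1L, patch_type = model$patch_type,
               backbone = list(name = model$backbone$name,
                               input_side = model$backbone$input_side,
                               input_range = model$backbone$input_range,
                               feature_dim = model$backbone$feature_dim,
                               provenance = model$backbone$provenance))
  num_json(spec, file.path(path, "spec.json"))
  # weight arrays are stored flattened (column-major) plus dims, so the
  # JSON round trip cannot permute axes
  wb <- lapply(model$backbone$weights, function(ly)
    list(w = as.vector(ly$w), dim = dim(ly$w), b = ly$b, stride = ly$stride))
  num_json(wb, file.path(path, "backbone.json"))
  hd <- model$head
  num_json(list(W1 = as.vector(hd$W1), d1 = dim(hd$W1), b1 = hd$b1,
                W2 = as.vector(hd$W2), d2 = dim(hd$W2), b2 = hd$b2,
                scale_mu = hd$scale_mu, scale_sd = hd$scale_sd),
           file.path(path, "head.json"))
  invisible(path)
}

#' Load a patch model saved by [save_model()]
#'
#' @param path Model directory.
#' @return A `PatchModel`.
#' @export
load_model <- function(path) {
  spec_path <- file.path(path, "spec.json")
  if (!file.exists(spec_path)) stopf("no spec.json in %s", path)
  spec <- jsonlite::read_json(spec_path, simplifyVector = TRUE)
  if (!identical(as.integer(spec$format_version), 1L))
    stopf("unsupported model format version in %s", path)
  bb_path <- file.path(path, "backbone.json")
  if (!file.exists(bb_path))
    stopf("model at %s stores a head only: backbone weights/spec missing",
          path)
  wb <- jsonlite::read_json(bb_path, simplifyVector = FALSE)
  weights <- lapply(wb, function(ly)
    list(w = array(as.numeric(unlist(ly$w)), as.integer(unlist(ly$dim))),
         b = as.numeric(unlist(ly$b)),
         stride = as.integer(ly$stride)))
  backbone <- structure(list(name = spec$backbone$name,
                             input_side = as.integer(spec$backbone$input_side),
                             input_range = as.numeric(spec$backbone$input_range),
                             feature_dim = as.integer(spec$backbone$feature_dim),
                             provenance = spec$backbone$provenance,
                             weights = weights),
                        class = "BackboneSpec")
  backbone$checksum <- backbone_checksum(backbone)
  hd <- jsonlite::read_json(file.path(path, "head.json"),
                            simplifyVector = TRUE)
  head <- list(W1 = matrix(unlist(hd$W1), hd$d1[1], hd$d1[2]),
               b1 = as.numeric(hd$b1),
               W2 = matrix(unlist(hd$W2), hd$d2[1], hd$d2[2]),
               b2 = as.numeric(hd$b2),
               scale_mu = as.numeric(hd$scale_mu),
               scale_sd = as.numeric(hd$scale_sd))
  structure(list(patch_type = spec$patch_type, backbone = backbone,
                 head = head),
            class = "PatchModel")
}
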