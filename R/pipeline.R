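# Experiment orchestration: one seeded configuration drives the full
# protocol (simulate -> clean -> patch extraction -> pairs -> four head
# trainings -> boosted fusion -> image-based / shark-based evaluation ->
# temporal analysis), writing every intermediate artifact under the output
# directory. A second run with the same configuration reproduces all
# reports byte-for-byte.

#' Default experiment configuration
#'
#' The defaults describe the benchmark's reference study design: an
#' 8 adult / 4 juvenile / 5 neonate population with drift rates
#' 0 / 0.02 / 0.08 per time step, four same-day baseline replicates, four
#' time markers, held-out-individual split 6/3/4, the 64-pixel frozen
#' random test backbone, and balanced verification pairs.
#'
#' @param ... Overrides for any configuration field.
#' @return Named list of configuration values.
#' @export
experiment_config <- function(...) {
  cfg <- list(
    n_adults = 8L, n_juveniles = 4L, n_neonates = 5L,
    baseline_replicates = 4L, time_steps = 4L, time_replicates = 2L,
    image_size = c(224L, 224L),
    patch_size = 64L,
    min_side = 64L, blur_threshold = 1e-5,
    n_train = c(adult = 6L, juvenile = 3L, neonate = 4L),
    n_augment = 3L,
    # augmentation is photometric-only by default: patch extraction already
    # orientation-normalizes along the body axis, and the frozen random
    # backbone is not rotation-invariant, so geometric augmentation would
    # make genuine positives look like negatives in embedding space
    flip_x_prob = 0, flip_y_prob = 0, rotations = 0,
    noise_max = 10 / 255, blur_max = 0.6,
    gamma_range = c(0.7, 1.4), contrast_range = c(0.8, 1.2),
    standardize_patches = TRUE,
    n_pairs = 1600L, positive_fraction = 0.5,
    # training sharks (per stage) reserved for fitting the fusion: the
    # boosted trees must see indices produced on individuals the heads did
    # not train on, otherwise every index is saturated at 0/1
    fusion_sharks = c(adult = 1L, juvenile = 1L, neonate = 1L),
    n_fusion_pairs = 400L,
    epochs = 150L, learning_rate = 2e-3, optimizer = "adam",
    batch_size = 64L,
    max_trees = 200L, tree_depth = 3L, shrinkage = 0.1,
    valid_fraction = 0.2, patience = 10L,
    regime = "all",           # "all" or "adults_only"
    seed = 1L,
    out_dir = tempfile("patchid_run_")
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Validate an experiment configuration
#'
#' @param config From [experiment_config()].
#' @return Character vector of violations (empty when valid). Never errors.
#' @export
validate_config <- function(config) {
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(all(c(config$n_adults, config$n_juveniles, config$n_neonates) >= 0),
      "population counts must be >= 0")
  chk(config$baseline_replicates >= 1, "baseline_replicates must be >= 1")
  chk(config$patch_size > 0, "patch_size must be positive")
  chk(config$noise_max >= 0 && config$blur_max >= 0,
      "augmentation noise/blur maxima must be >= 0")
  chk(config$positive_fraction >= 0 && config$positive_fraction <= 1,
      "positive_fraction must lie in [0, 1]")
  chk(config$regime %in% c("all", "adults_only"),
      "regime must be 'all' or 'adults_only'")
  counts <- c(adult = config$n_adults, juvenile = config$n_juveniles,
              neonate = config$n_neonates)
  for (st in names(counts))
    if (config$n_train[[st]] > counts[[st]])
      v <- c(v, sprintf(
        "stage '%s': %d training individuals requested but only %d exist",
        st, config$n_train[[st]], counts[[st]]))
  v
}

## ---- cached scoring -------------------------------------------------------

# embed every image's four patches once; returns list per patch type of
# n_images x F matrices (rows follow `images` order)
embed_images <- function(patch_models, images) {
  names(patch_models) <- vapply(patch_models, `[[`, "", "patch_type")
  out <- list()
  for (pt in INDEX_ORDER) {
    F <- patch_models[[pt]]$backbone$feature_dim
    out[[pt]] <- t(vapply(images, function(img)
      embed(patch_models[[pt]], img[[pt]]), numeric(F)))
  }
  out
}

# per-patch similarity indices for index pairs (ia, ib) over cached
# embeddings; returns n x 4 matrix in canonical order
indices_from_cache <- function(patch_models, emb, ia, ib) {
  names(patch_models) <- vapply(patch_models, `[[`, "", "patch_type")
  X <- matrix(0, length(ia), 4)
  for (k in seq_along(INDEX_ORDER)) {
    pt <- INDEX_ORDER[k]
    X[, k] <- head_forward(patch_models[[pt]]$head,
                           emb[[pt]][ia, , drop = FALSE],
                           emb[[pt]][ib, , drop = FALSE])$p
  }
  X
}

## ---- run_experiment -------------------------------------------------------

#' Run the full experiment protocol from one configuration
#'
#' @param config From [experiment_config()].
#' @param keep_images Keep the rendered dataset on disk (default TRUE;
#'   reports and models are always written).
#' @return Results bundle: list with `config`, `manifest_path`, `split`,
#'   `patch_models`, `ensemble`, `reports` (image-based per patch + fused,
#'   shark-based, per-stage AUCs), `temporal`, `paths`.
#' @export
run_experiment <- function(config = experiment_config(), keep_images = TRUE) {
  viol <- validate_config(config)
  if (length(viol)) stopf("invalid config: %s", paste(viol, collapse = "; "))
  seed <- config$seed
  out_dir <- config$out_dir
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", what, conditionMessage(e)))
  }

  ## simulate
  manifest_path <- stage("simulate", {
    pop <- make_population(config$n_adults, config$n_juveniles,
                           config$n_neonates, derive_seed(seed, "population"))
    write_dataset(pop, config$baseline_replicates, config$time_steps,
                  file.path(out_dir, "data"), derive_seed(seed, "dataset"),
                  time_replicates = config$time_replicates,
                  image_size = config$image_size)
  })

  ## clean
  rows <- stage("clean", {
    mf <- read_manifest(manifest_path)
    cl <- clean_dataset(mf, min_side = config$min_side,
                        blur_threshold = config$blur_threshold)
    cl$kept
  })

  ## split by individual
  split <- stage("split", split_by_individual(rows, config$n_train,
                                              derive_seed(seed, "split")))

  ## patches for every image
  all_patches <- stage("prepare", {
    ps <- lapply(seq_len(nrow(rows)), function(i)
      patches_from_row(rows[i, ], config$patch_size))
    names(ps) <- sub("\\.png$", "", basename(rows$image_path))
    ps
  })
  rows$image_id <- names(all_patches)

  ## training instances: baseline images of training sharks
  ## (adults only in the adults_only regime), originals + augmented copies
  train_stage_ids <- if (config$regime == "adults_only")
    unique(rows$shark_id[rows$life_stage == "adult"]) else unique(rows$shark_id)
  tr_rows <- rows[rows$series == "baseline" &
                  rows$shark_id %in% intersect(split$train_ids,
                                               train_stage_ids), ]
  aug <- augment_params(flip_x_prob = config$flip_x_prob,
                        flip_y_prob = config$flip_y_prob,
                        rotations = config$rotations,
                        noise_max = config$noise_max,
                        blur_max = config$blur_max,
                        gamma_range = config$gamma_range,
                        contrast_range = config$contrast_range)
  inst <- list(); meta <- list()
  stage("augment", {
    for (i in seq_len(nrow(tr_rows))) {
      iid <- tr_rows$image_id[i]
      base <- all_patches[[iid]]
      for (a in 0:config$n_augment) {
        cur <- if (a == 0) base else {
          lapply(base, function(p)
            augment(p, aug, rng = derive_seed(seed, "aug", iid, a,
                                              p$patch_type)))
        }
        # standardization is the last preprocessing step before embedding,
        # for training instances and evaluation patches alike
        if (config$standardize_patches)
          cur <- lapply(cur, standardize_patch)
        inst[[length(inst) + 1L]] <- cur
        meta[[length(meta) + 1L]] <- data.frame(
          shark_id = tr_rows$shark_id[i], source_image_id = iid,
          stringsAsFactors = FALSE)
      }
    }
  })
  meta <- do.call(rbind, meta)

  ## split the training sharks into a head pool and a small fusion pool
  ## (shark-disjoint, so the fusion sees realistically noisy indices), then
  ## build one pair plan per pool, shared by all four patch types
  tr_meta <- unique(meta[c("shark_id")])
  tr_meta$stage <- rows$life_stage[match(tr_meta$shark_id, rows$shark_id)]
  fusion_ids <- character(0)
  with_seed(derive_seed(seed, "fusion_sharks"), {
    for (st in names(config$fusion_sharks)) {
      k <- config$fusion_sharks[[st]]
      avail <- tr_meta$shark_id[tr_meta$stage == st]
      if (k > 0 && length(avail) > k)
        fusion_ids <- c(fusion_ids, sample(avail, k))
    }
  })
  # a one-shark fusion pool cannot form negative pairs; fall back to the
  # same-pool fit and return the shark to the head pool
  if (length(fusion_ids) < 2) fusion_ids <- character(0)
  head_meta_sel <- !(meta$shark_id %in% fusion_ids)
  pairs <- stage("pairs", {
    p <- make_pairs(meta[head_meta_sel, ], patch_type = "all",
                    n_pairs = config$n_pairs,
                    positive_fraction = config$positive_fraction,
                    rng = derive_seed(seed, "pairs"))
    # indices back into the full instance table
    p$a <- which(head_meta_sel)[p$a]; p$b <- which(head_meta_sel)[p$b]
    audit_no_leakage(meta, p, split)
    p
  })
  fuse_pairs <- stage("fusion_pairs", if (length(fusion_ids) < 2) {
    pairs   # same-pool fallback
  } else {
    fsel <- meta$shark_id %in% fusion_ids
    sub <- meta[fsel, ]
    # clamp the request to the attainable pair counts in the small pool
    per_shark <- split(sub$source_image_id, sub$shark_id)
    n_inst <- vapply(per_shark, length, 0L)
    pos_avail <- sum(vapply(per_shark, function(s)
      sum(outer(seq_along(s), seq_along(s), function(i, j)
        i < j & s[i] != s[j])), 0))
    neg_avail <- (sum(n_inst)^2 - sum(n_inst^2)) / 2
    k_pos <- min(round(config$n_fusion_pairs * config$positive_fraction),
                 pos_avail)
    k_tot <- min(config$n_fusion_pairs, floor(k_pos / max(
      config$positive_fraction, 1e-9)), k_pos + neg_avail)
    fp <- make_pairs(sub, patch_type = "all", n_pairs = k_tot,
                     positive_fraction = config$positive_fraction,
                     rng = derive_seed(seed, "fusion_pairs"))
    fp$a <- which(fsel)[fp$a]; fp$b <- which(fsel)[fp$b]
    audit_no_leakage(meta, fp, split)
    fp
  })
  head_pairs <- pairs

  ## train the four heads on cached embeddings
  backbone <- tiny_backbone(derive_seed(seed, "backbone"),
                            input_side = config$patch_size)
  patch_models <- list(); losses <- list()
  stage("train", {
    emb_tr <- embed_images(
      lapply(INDEX_ORDER, function(pt) patch_model(pt, backbone)), inst)
    for (pt in INDEX_ORDER) {
      m <- patch_model(pt, backbone, seed = derive_seed(seed, "model", pt))
      fit <- train_head_embedded(
        m, emb_tr[[pt]][head_pairs$a, , drop = FALSE],
        emb_tr[[pt]][head_pairs$b, , drop = FALSE], head_pairs$label,
        epochs = config$epochs, learning_rate = config$learning_rate,
        seed = derive_seed(seed, "train", pt),
        batch_size = config$batch_size, optimizer = config$optimizer)
      patch_models[[pt]] <- fit$model
      losses[[pt]] <- fit$loss_history
    }
    ## fusion pool: indices on the reserved pairs, plus exhaustive
    ## unaugmented pairs over the fusion sharks' full image sets (baseline
    ## and time series), so the ensemble sees the cross-session comparisons
    ## it will face at evaluation time
    X_train <- indices_from_cache(patch_models, emb_tr, fuse_pairs$a,
                                  fuse_pairs$b)
    y_train <- fuse_pairs$label
    if (length(fusion_ids) >= 2) {
      frows <- rows[rows$shark_id %in% fusion_ids, ]
      fimgs <- all_patches[frows$image_id]
      if (config$standardize_patches)
        fimgs <- lapply(fimgs, function(im) lapply(im, standardize_patch))
      femb <- embed_images(patch_models, fimgs)
      fmeta <- data.frame(shark_id = frows$shark_id,
                          source_image_id = frows$image_id,
                          stringsAsFactors = FALSE)
      fx <- make_pairs(fmeta, patch_type = "all", n_pairs = NULL,
                       rng = derive_seed(seed, "fusion_time"))
      X_train <- rbind(X_train,
                       indices_from_cache(patch_models, femb, fx$a, fx$b))
      y_train <- c(y_train, fx$label)
    }
  })
  ensemble <- stage("fuse",
    fit_ensemble(X_train, y_train,
                 fusion_params(max_trees = config$max_trees,
                               depth = config$tree_depth,
                               shrinkage = config$shrinkage,
                               valid_fraction = config$valid_fraction,
                               patience = config$patience),
                 rng = derive_seed(seed, "fusion")))

  ## evaluation on held-out individuals
  ev_rows <- rows[rows$shark_id %in% split$test_ids, ]
  if (config$regime == "adults_only")
    ev_rows <- ev_rows[ev_rows$life_stage == "adult", ]
  ev_images <- all_patches[ev_rows$image_id]
  if (config$standardize_patches)
    ev_images <- lapply(ev_images, function(im)
      lapply(im, standardize_patch))
  emb_ev <- embed_images(patch_models, ev_images)
  n_ev <- nrow(ev_rows)
  cmb <- utils::combn(seq_len(n_ev), 2)
  ia <- cmb[1, ]; ib <- cmb[2, ]
  lab <- as.numeric(ev_rows$shark_id[ia] == ev_rows$shark_id[ib])
  Xev <- indices_from_cache(patch_models, emb_ev, ia, ib)
  fused <- final_similarity(ensemble, Xev)

  reports <- stage("eval", {
    rep_list <- list()
    for (k in seq_along(INDEX_ORDER))
      rep_list[[paste0("image_based_", INDEX_ORDER[k])]] <-
        score_report(Xev[, k], lab)
    rep_list$image_based_fused <- score_report(fused, lab)

    ## per-stage image-pair AUCs (per patch and fused): stages with >= 2
    ## test sharks restrict both pair members to the stage, single-shark
    ## stages take every pair involving that shark
    st_tab <- list()
    for (st in unique(ev_rows$life_stage)) {
      in_st <- ev_rows$life_stage[ia] == st & ev_rows$life_stage[ib] == st
      sharks_st <- unique(ev_rows$shark_id[ev_rows$life_stage == st])
      sel <- if (length(sharks_st) >= 2) in_st
             else (ev_rows$life_stage[ia] == st | ev_rows$life_stage[ib] == st)
      aucs <- c(vapply(seq_along(INDEX_ORDER), function(k)
        roc_auc(Xev[sel, k], lab[sel])$auc, numeric(1)),
        roc_auc(fused[sel], lab[sel])$auc)
      st_tab[[st]] <- stats::setNames(aucs, c(INDEX_ORDER, "fused"))
    }
    rep_list$stage_auc_image_based <- st_tab

    ## shark-based groups: one group per (shark, baseline | time marker)
    gkey <- ifelse(ev_rows$series == "baseline", "B", ev_rows$time_marker)
    gid <- paste(ev_rows$shark_id, gkey)
    groups <- split(seq_len(n_ev), gid)
    gmeta <- data.frame(
      gid = names(groups),
      shark_id = vapply(groups, function(ix) ev_rows$shark_id[ix[1]], ""),
      stage = vapply(groups, function(ix) ev_rows$life_stage[ix[1]], ""),
      stringsAsFactors = FALSE)
    pair_score_lookup <- function(ix1, ix2, scores) {
      # mean score over the cached unordered pairs between two index sets
      sel <- (ia %in% ix1 & ib %in% ix2) | (ia %in% ix2 & ib %in% ix1)
      mean(scores[sel])
    }
    grp_scores <- function(scores) {
      out <- list()
      ng <- length(groups)
      for (i in seq_len(ng - 1L)) for (j in (i + 1L):ng) {
        out[[length(out) + 1L]] <- data.frame(
          g1 = i, g2 = j,
          score = pair_score_lookup(groups[[i]], groups[[j]], scores),
          label = as.numeric(gmeta$shark_id[i] == gmeta$shark_id[j]))
      }
      # halving positives inside groups with >= 2 images
      for (i in seq_len(ng)) {
        ix <- groups[[i]]
        if (length(ix) < 2) next
        h <- length(ix) %/% 2L
        out[[length(out) + 1L]] <- data.frame(
          g1 = i, g2 = i,
          score = pair_score_lookup(ix[seq_len(h)], ix[(h + 1):length(ix)],
                                    scores),
          label = 1)
      }
      do.call(rbind, out)
    }
    gsc <- grp_scores(fused)
    rep_list$shark_based_fused <- score_report(gsc$score, gsc$label)

    ## per-stage shark-based AUC (fused): stages with >= 2 sharks use
    ## within-stage group pairs; single-shark stages add cross-stage
    ## negatives involving that shark. Same-day halving positives are
    ## excluded here: the stage AUC measures re-sighting identifiability,
    ## i.e. cross-session comparisons (halving positives still enter the
    ## overall shark-based report above)
    cross <- gsc$g1 != gsc$g2
    stage_auc <- list()
    for (st in unique(gmeta$stage)) {
      in_st <- which(gmeta$stage == st)
      sharks_st <- unique(gmeta$shark_id[in_st])
      both_in <- cross & gsc$g1 %in% in_st & gsc$g2 %in% in_st
      sel <- if (length(sharks_st) >= 2) both_in
             else cross & (gsc$g1 %in% in_st | gsc$g2 %in% in_st)
      sub <- gsc[sel, ]
      stage_auc[[st]] <- if (length(unique(sub$label)) == 2)
        roc_auc(sub$score, sub$label)$auc else NA_real_
    }
    rep_list$stage_auc_shark_based <- unlist(stage_auc)
    rep_list$groups <- gmeta
    rep_list$group_scores <- gsc
    rep_list
  })

  ## temporal analysis: each test shark's markers vs its baseline
  temporal <- stage("temporal", {
    out <- list()
    for (sid in unique(ev_rows$shark_id)) {
      bl <- which(ev_rows$shark_id == sid & ev_rows$series == "baseline")
      markers <- sort(unique(ev_rows$time_marker[
        ev_rows$shark_id == sid & ev_rows$series == "time"]))
      if (!length(bl) || !length(markers)) next
      markers <- markers[order(time_marker_index(markers))]
      sims <- vapply(markers, function(mk) {
        tg <- which(ev_rows$shark_id == sid & ev_rows$time_marker == mk)
        sel <- (ia %in% bl & ib %in% tg) | (ia %in% tg & ib %in% bl)
        mean(fused[sel])
      }, numeric(1))
      out[[sid]] <- list(shark_id = sid,
                         life_stage = ev_rows$life_stage[bl[1]],
                         similarity = sims, stable = all(sims > 0.5))
    }
    out
  })

  ## persist artifacts
  paths <- stage("write", {
    rep_dir <- file.path(out_dir, "reports")
    mod_dir <- file.path(out_dir, "models")
    dir.create(rep_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(mod_dir, recursive = TRUE, showWarnings = FALSE)
    for (pt in INDEX_ORDER)
      save_model(patch_models[[pt]], file.path(mod_dir, pt))
    save_ensemble(ensemble, file.path(mod_dir, "ensemble.json"))
    summarize <- function(r) list(
      n_pairs = r$n_pairs, accuracy = r$accuracy,
      precision = if (r$precision_defined) r$precision else "undefined",
      mae = r$mae, auc = r$auc)
    summary <- list(
      image_based = lapply(
        reports[paste0("image_based_", c(INDEX_ORDER, "fused"))], summarize),
      shark_based_fused = summarize(reports$shark_based_fused),
      stage_auc_shark_based = as.list(reports$stage_auc_shark_based),
      temporal = lapply(temporal, function(tp)
        list(shark_id = tp$shark_id, life_stage = tp$life_stage,
             similarity = as.list(tp$similarity), stable = tp$stable)))
    jsonlite::write_json(summary, file.path(rep_dir, "summary.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
    utils::write.csv(data.frame(shark_id = c(split$train_ids,
                                             split$test_ids),
                                role = rep(c("train", "test"),
                                           c(length(split$train_ids),
                                             length(split$test_ids)))),
                     file.path(rep_dir, "split.csv"), row.names = FALSE,
                     quote = FALSE)
    if (!keep_images)
      unlink(file.path(out_dir, "data"), recursive = TRUE)
    list(out_dir = out_dir, summary = file.path(rep_dir, "summary.json"),
         models = mod_dir)
  })

  list(config = config, manifest_path = manifest_path, split = split,
       patch_models = patch_models, ensemble = ensemble,
       loss_history = losses, reports = reports, temporal = temporal,
       train_instances = meta, train_pairs = pairs, paths = paths)
}
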