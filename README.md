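# patchid

Patch-based photographic identification (photo-ID) of individually
patterned sharks, built around a four-patch twin-network similarity model
with gradient-boosted decision fusion.

## The problem

Epaulette sharks (*Hemiscyllium ocellatum*) carry an individually unique
spot pattern. Adults keep it for life, which makes non-invasive photo-ID
possible; neonates and juveniles change their pattern as they grow, which
makes them hard or impossible to re-identify. `patchid` re-implements a
verification ("are these two photographs the same shark?") pipeline for
this setting, aimed at researchers who maintain labelled photographic
catalogues of captive or wild populations:

1. **Four skin patches** — head, pectoral/gill area (pec), dorsal ahead of
   the first dorsal fin (FDF), dorsal behind it (FDB) — are annotated as
   rotated boxes aligned to the vertebral line (roLabelImg XML dialect),
   cropped, orientation-normalized and resized (380 px by default).
2. **Per-patch twin network.** Both patches pass through one frozen
   feature-extractor backbone; each feature map is average-pooled to an
   F-vector, the two vectors are concatenated and classified by a
   trainable head (32-unit ReLU dense layer, then a 1-unit sigmoid). The
   output `s ∈ (0,1)` is the *similarity index*. Only the head trains
   (binary cross-entropy, minibatch gradient descent or Adam); the
   backbone is bit-frozen. The reference configuration is EfficientNetB4
   (17,673,823 frozen parameters, F = 1792); tests and the synthetic
   benchmark use a small seeded random-frozen conv stack (F = 64) that
   exercises the identical contract in seconds.
3. **Boosted fusion.** The four indices form `X = (s_head, s_pec, s_FDF,
   s_FDB)`; a gradient-boosted regression-tree ensemble maps X to the
   *final similarity index* `base + Σ_i a_i T_i(X | r_{i-1})`, `r_0 = 0`,
   clipped to [0,1]. Strictly greater than 0.5 ⇒ "same shark".
4. **Evaluation.** Image-based (one decision per image pair) and
   shark-based (mean of all K1×K2 cross-group indices per pair of image
   groups) accuracy / precision / MAE / ROC-AUC, with held-out-individual
   splits; plus a temporal analysis that scores each time marker T1…Tn
   against the same shark's baseline photographs (stable iff every marker
   stays above 0.5).
5. **Synthetic benchmark.** Labelled shark photo catalogues are rarely
   shareable, so the package ships a fully seeded generator of synthetic spot-pattern
   photographs (capsule body, ocellus landmark, per-individual patterns,
   photographic nuisance) with stage-dependent ontogenetic drift: per time
   step each spot takes a Gaussian step of sd `drift_rate × body_length`
   and is reborn elsewhere with probability `drift_rate`
   (adult 0, juvenile 0.02, neonate 0.08).

## Worked example

```r
library(patchid)

res <- run_experiment(experiment_config(seed = 1))
#> 8 adults / 4 juveniles / 5 neonates rendered, cleaned, split 6/3/4 by
#> individual, four heads trained, fusion fitted, held-out evaluation run.

res$reports$image_based_pec
#> EvaluationReport: 1128 pairs | accuracy 74.6% | precision 47.3% | MAE 0.254 | AUC 0.823

round(res$reports$stage_auc_shark_based, 2)
#>    adult juvenile  neonate
#>     1.00     0.33     0.49

round(res$temporal$HO_101$similarity, 2)   # an adult: stable through time
#>   T0   T1   T2   T3
#> 0.84 0.75 0.68 0.84
res$temporal$HO_101$stable
#> [1] TRUE
```

Every report satisfies `accuracy + MAE = 1` exactly (MAE is computed on the
binarized decisions). The stage AUCs reproduce the expected qualitative
ordering: held-out adults are cleanly separable (shark-based AUC 1.00 here),
while the drifting neonate sits near chance (0.49) and the juvenile in
between runs is likewise poorly identifiable. Adults stay above the 0.5
stability threshold at every time marker; neonates fall below it.

Numbers above are from `seed = 1` on this machine's run of the default
configuration; per-stage values vary noticeably across seeds because the
held-out test set contains only 2 adults, 1 juvenile and 1 neonate under
the default 6/3/4 split.

## Command line

```sh
inst/cli/patchid simulate --adults 8 --juveniles 4 --neonates 5 \
    --baseline-reps 4 --time-steps 4 --seed 7 --out data/
inst/cli/patchid clean --manifest data/manifest.csv --min-side 380 --blur-threshold 1e-5
inst/cli/patchid run --seed 1 --out runs/exp1
```

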