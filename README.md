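# ethokit

Behavioral-kinematics analysis of the mouse gap-jumping distance-estimation
task, for researchers who track freely moving animals with markerless pose
estimation and want the full decision-period analysis chain as tested,
reusable R functions.

In this task a mouse on a take-off platform must judge the distance to a
landing platform and jump; the *decision period* runs from occluder removal to
the frame before the jump. The package implements:

- **Pose I/O and preprocessing** — DeepLabCut-dialect CSV reading/writing,
  confidence filtering with bounded gap interpolation, pixel-to-cm calibration
  centered on the take-off-platform edge, median (n = 3) + box (n = 5)
  smoothing, decision-period extraction.
- **Head kinematics and performance** — pitch and yaw from the eye–ear
  segment (`atan2(Δy, Δx)`, negative pitch = downward), distance jumped from
  the top-camera ear at landing, trial duration and eye path length, and
  outcome/landing summaries averaged within animal before across animals.
- **Movement motifs** — segmentation of discrete head movements at vertical
  velocity zero crossings (500 ms windows, ≥ 1 cm vertical amplitude,
  > 250 ms overlap with the last retained movement excluded), PCA embedding of
  the concatenated x/y traces, seeded k-means clustering ordered by trace
  variance, and per-cluster frequency/amplitude/timing statistics.
- **Gaze** — direct least-squares pupil-ellipse fitting, eye-in-head angles
  (theta nasal-positive, phi up-positive), vergence `θ_L + θ_R`, early/late
  epochs (boundary 2 s before the jump), head–eye cross-correlations, and
  pitch–gaze regressions.
- **Latent states and decoding** — a sticky autoregressive HMM
  (`y_t = A_k y_{t-1} + b_k + ε`, self-transitions boosted by a κ
  pseudo-count) fit by EM on nose/eye/ear features, MAP state sequences
  thresholded at posterior 0.8, per-trial transition-probability features, and
  linear-discriminant condition decoding with fold-wise label-shuffle nulls
  (stratified 10-fold, 100 shuffles per fold).
- **A seeded synthetic generator** — pose, eye, and trial data with the
  statistical structure the analyses assume and complete ground-truth
  bookkeeping, so every stage has parameter-recovery tests without animal
  data.

## Worked example

Generate a two-condition synthetic session, segment and cluster head
movements, and compare conditions per animal:

```r
library(ethokit)

cfg <- generator_config(seed = 42, trials_per_condition = 40)
ds  <- generate_dataset(cfg)

sets <- list(); kin <- list()
for (tid in names(ds$tracks)) {
  tr <- ds$trials[ds$trials$trial_id == tid, ]
  sm <- smooth_series(extract_decision_period(
    calibrate(ds$tracks[[tid]]$side, cfg$px_per_cm), tr))
  sets[[tid]] <- detect_movements(sm)
  kin[[tid]] <- data.frame(animal_id = tr$animal_id,
                           condition = tr$ocular_condition,
                           n_mov = n_movements(sets[[tid]]),
                           pitch = mean(head_pitch(sm), na.rm = TRUE))
}

mv <- combine_movements(sets)
mv
#> <movement_set> 232 movements, 500 ms window @ 60 Hz

model <- cluster_movements(embed_movements(mv), k = 3, seed = 1)

df  <- do.call(rbind, kin)
per <- aggregate(cbind(n_mov, pitch) ~ condition + animal_id, df, mean)

pa <- setNames(per[, c("condition", "animal_id", "n_mov")],
               c("condition", "animal_id", "value"))
compare_conditions(pa, "paired", measure = "movements per trial")
#> <comparison> movements per trial [binocular vs monocular]: paired t-test stat=4.951 p=0.001655 adj=0.001655 effect=1.85

pp <- setNames(per[, c("condition", "animal_id", "pitch")],
               c("condition", "animal_id", "value"))
compare_conditions(pp, "paired", measure = "mean head pitch (deg)")
#> <comparison> mean head pitch (deg) [binocular vs monocular]: paired t-test stat=-25.11 p=4.059e-08 adj=4.059e-08 effect=-7.338
```

The generator placed movements at 2 vs 4 per trial and pitch baselines of
−20° vs −27° across the two conditions; the recovered per-animal effects
(+1.85 movements/trial, −7.3° pitch, both significant across 8 animals) are
the pipeline reading that structure back out of the rendered pose tracks.

To run everything (kinematics, motifs, gaze, states, decoding, comparisons) on
a session directory and write CSV/JSON reports:

```r
write_session(ds, "session/")
run_pipeline(pipeline_config(seed = 1), "session/", "out/")
```

A thin command-line wrapper lives at `inst/cli/ethokit.R`
(`simulate` and `run` subcommands); the remaining analysis stages are the
exported functions used above.

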