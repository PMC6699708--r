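# Default end-to-end run: the study-scale synthetic cohort.
# "study" = constants taken from the published experiment design;
# "artifact" = engineering defaults of this implementation.
out_dir: melon_run
seed: 1
stages: [simulate, segment, extract, screen, model]
cohort:
  n_fruits: 134            # study: cohort size
  views_per_fruit: 3       # study: three camera angles per fruit
  image_size: [256, 256]   # artifact: synthetic raster size
  noise_sd: calibrated     # artifact: per-trait noise at generative R2 = 0.9
segmentation:
  polarity: backdrop_high  # artifact: blue backdrop scores high on 2B-R-G
  min_object_frac: 0.005   # artifact
  min_hole_frac: 0.001     # artifact
  opening_radius: 5        # artifact
  white_balance: false     # artifact: gray-world toggle, off by default
  max_side: 1024           # artifact: working resolution bound
glcm:
  levels: 64               # artifact
  distance: 1              # artifact
screening:
  alpha: 0.05              # study: P < 0.05 selection
  aggregate: mean          # artifact: fruit-level analysis (views averaged)
rf:
  ntree: 300               # study
  cv_folds: 10             # study: 10-fold cross-validation
  cv_repeats: 3            # study: three repetitions
  train_fraction: 0.6667   # study: two thirds for model construction
  k_top: 10                # study: top-10 simplified model
  importance_reps: 5       # artifact
  mtry_grid: ~             # study: 1..min(100, p) when unset
traits: [fructose, glucose, sucrose, total_sugar, tss, vitamin_c, chl_a, chl_b, carotenoids]
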