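# End-to-end orchestration: simulate -> segment -> extract -> screen ->
# model/simplify, with a YAML-configurable run and a machine-readable
# manifest (per-stage counts and output hashes) for reproducibility checks.

#' Default run configuration
#'
#' A nested list mirroring the study constants (134 fruits x 3 views,
#' ntree = 300, alpha = 0.05, 10-fold x 3 CV, top-10 simplification) plus
#' the artifact defaults of this implementation (working resolution,
#' cleaning fractions, GLCM settings). Serializable to YAML with
#' [write_run_config()].
#'
#' @param out_dir output directory of the run.
#' @param seed global seed propagated to every stochastic stage.
#' @param n_fruits,views_per_fruit cohort geometry.
#' @param traits traits to model.
#' @param mtry_grid optional explicit mtry grid (NULL = 1..min(100, p)).
#' @return nested configuration list.
#' @export
default_run_config <- function(out_dir = tempfile("melon_run_"), seed = 1L,
                               n_fruits = 134, views_per_fruit = 3,
                               traits = melon_traits()$trait,
                               mtry_grid = NULL) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    stages = c("simulate", "segment", "extract", "screen", "model"),
    cohort = list(n_fruits = n_fruits, views_per_fruit = views_per_fruit,
                  image_size = c(256, 256), noise_sd = "calibrated"),
    segmentation = list(polarity = "backdrop_high", min_object_frac = 0.005,
                        min_hole_frac = 0.001, opening_radius = 5,
                        white_balance = FALSE, max_side = 1024),
    glcm = list(levels = 64, distance = 1),
    screening = list(alpha = 0.05, aggregate = "mean"),
    rf = list(ntree = 300, cv_folds = 10, cv_repeats = 3,
              train_fraction = 2 / 3, k_top = 10, importance_reps = 5,
              mtry_grid = mtry_grid),
    traits = traits
  )
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_run_config`: the configuration list.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' @rdname read_run_config
#' @param config configuration list.
#' @export
write_run_config <- function(config, path) {
  writeLines(yaml::as.yaml(config), path)
  invisible(path)
}

stage_hash <- function(paths) {
  paths <- paths[file.exists(paths)]
  h <- tools::md5sum(paths)
  names(h) <- basename(names(h))
  as.list(h)
}

#' Run the full pipeline
#'
#' Executes the configured stages in order, writing every intermediate
#' artifact under `config$out_dir` (images/, masks/, masks_pred/,
#' features.csv, screen.csv, screen.png, reports/*.json) and returns a run
#' manifest with per-stage record counts, seeds and output-file hashes.
#' A failure stops the run with the failing stage named.
#'
#' @param config list from [default_run_config()] or [read_run_config()].
#' @param quiet suppress progress messages.
#' @return manifest list (also written as manifest.json), invisibly.
#' @export
run_pipeline <- function(config = default_run_config(), quiet = FALSE) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(seed = config$seed, stages = list())
  run_stage <- function(name, fun) {
    say("[%s] running", name)
    res <- tryCatch(fun(), error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    manifest$stages[[name]] <<- res
    res
  }
  seeds <- derive_seeds(config$seed, 8)

  cohort <- NULL
  if ("simulate" %in% config$stages) {
    run_stage("simulate", function() {
      spec <- cohort_spec(n_fruits = config$cohort$n_fruits,
                          views_per_fruit = config$cohort$views_per_fruit,
                          image_size = config$cohort$image_size,
                          noise_sd = config$cohort$noise_sd,
                          seed = seeds[1])
      cohort <<- generate_cohort(spec)
      mf <- write_cohort(cohort, out)
      list(n_images = nrow(mf), n_fruits = spec$n_fruits,
           seed = seeds[1],
           hashes = stage_hash(c(file.path(out, "phenotypes.csv"),
                                 mf$image[seq_len(min(5, nrow(mf)))])))
    })
  }

  scenes_csv <- file.path(out, "scenes.csv")
  if (!file.exists(scenes_csv)) stopf("stage 'segment': no scenes.csv under %s", out)
  scenes <- read.csv(scenes_csv, stringsAsFactors = FALSE)

  if ("segment" %in% config$stages) {
    run_stage("segment", function() {
      dir.create(file.path(out, "masks_pred"), showWarnings = FALSE)
      sc <- config$segmentation
      cp <- cleaning_params(opening_radius = sc$opening_radius,
                            min_object_frac = sc$min_object_frac,
                            min_hole_frac = sc$min_hole_frac)
      thr <- numeric(nrow(scenes))
      for (i in seq_len(nrow(scenes))) {
        img <- read_image(scenes$image[i])
        seg <- segment_image(img, polarity = sc$polarity, cleaning = cp,
                             white_balance = isTRUE(sc$white_balance),
                             max_side = sc$max_side)
        write_mask(seg$mask, file.path(out, "masks_pred",
                                       paste0(scenes$image_id[i], ".png")))
        thr[i] <- seg$threshold
      }
      list(n_images = nrow(scenes), thresholds = range(thr),
           hashes = stage_hash(file.path(out, "masks_pred",
                                         paste0(scenes$image_id[seq_len(min(5, nrow(scenes)))], ".png"))))
    })
  }

  features_csv <- file.path(out, "features.csv")
  if ("extract" %in% config$stages) {
    run_stage("extract", function() {
      gc <- glcm_config(levels = config$glcm$levels,
                        distance = config$glcm$distance)
      rows <- vector("list", nrow(scenes))
      for (i in seq_len(nrow(scenes))) {
        img <- read_image(scenes$image[i])
        mask <- read_mask(file.path(out, "masks_pred",
                                    paste0(scenes$image_id[i], ".png")))
        fv <- extract_features(img, mask, gc)
        rows[[i]] <- data.frame(image_id = scenes$image_id[i],
                                fruit_id = scenes$fruit_id[i],
                                view = scenes$view[i],
                                as.list(fv), check.names = FALSE,
                                stringsAsFactors = FALSE)
      }
      feats <- do.call(rbind, rows)
      write.csv(feats, features_csv, row.names = FALSE)
      list(n_rows = nrow(feats), n_features = length(feature_names()),
           n_values = nrow(feats) * length(feature_names()),
           hashes = stage_hash(features_csv))
    })
  }

  screen_csv <- file.path(out, "screen.csv")
  if ("screen" %in% config$stages) {
    run_stage("screen", function() {
      feats <- read.csv(features_csv, check.names = FALSE,
                        stringsAsFactors = FALSE)
      pheno <- read.csv(file.path(out, "phenotypes.csv"),
                        stringsAsFactors = FALSE)
      fl <- aggregate_views(feats, mode = config$screening$aggregate)
      scr <- pearson_screen(fl, pheno, alpha = config$screening$alpha,
                            traits = intersect(config$traits, names(pheno)))
      write.csv(as.data.frame(scr), screen_csv, row.names = FALSE)
      screening_plot(scr, file.path(out, "screen.png"))
      list(n_pairs = nrow(scr), n_selected = sum(scr$selected),
           alpha = config$screening$alpha, hashes = stage_hash(screen_csv))
    })
  }

  if ("model" %in% config$stages) {
    run_stage("model", function() {
      dir.create(file.path(out, "reports"), showWarnings = FALSE)
      feats <- read.csv(features_csv, check.names = FALSE,
                        stringsAsFactors = FALSE)
      pheno <- read.csv(file.path(out, "phenotypes.csv"),
                        stringsAsFactors = FALSE)
      scr <- read.csv(screen_csv, stringsAsFactors = FALSE)
      fl <- aggregate_views(feats, mode = config$screening$aggregate)
      merged <- merge(fl, pheno, by = "fruit_id")
      counts <- list()
      for (ti in seq_along(config$traits)) {
        tr <- config$traits[[ti]]
        sel <- scr$feature[scr$trait == tr & scr$selected]
        sel <- sel[order(match(sel, feature_names()))]
        if (length(sel) < 1) { counts[[tr]] <- 0L; next }
        cfg <- rf_config(ntree = config$rf$ntree,
                         mtry_grid = config$rf$mtry_grid,
                         cv_folds = config$rf$cv_folds,
                         cv_repeats = config$rf$cv_repeats,
                         train_fraction = config$rf$train_fraction,
                         importance_reps = config$rf$importance_reps,
                         k_top = config$rf$k_top,
                         seed = (seeds[2] %% 1000000007L) + ti)
        Xt <- as.matrix(merged[sel])
        yt <- merged[[tr]]
        full <- tune_fit(Xt, yt, cfg, fruit_ids = merged$fruit_id, trait = tr)
        rk <- rf_importance(full$fit, nrep = cfg$importance_reps,
                            seed = cfg$seed)
        cmp <- simplify(Xt, yt, rk, k = cfg$k_top, config = cfg,
                        fruit_ids = merged$fruit_id, full_report = full)
        report <- list(
          trait = tr, n = full$n, p = full$p,
          chosen_mtry = full$chosen_mtry,
          metrics_validation = as.list(full$metrics_validation),
          metrics_cv = as.list(full$metrics_cv),
          importance = rk,
          retained_top = cmp$retained,
          simplified = list(chosen_mtry = cmp$simplified$chosen_mtry,
                            metrics_validation = as.list(cmp$simplified$metrics_validation),
                            metrics_cv = as.list(cmp$simplified$metrics_cv)),
          r2_decrease_pct = cmp$r2_decrease_pct,
          seconds = full$seconds + cmp$simplified$seconds)
        jsonlite::write_json(report, file.path(out, "reports",
                                               paste0(tr, ".json")),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        write.csv(full$predictions,
                  file.path(out, "reports", paste0(tr, "_predictions.csv")),
                  row.names = FALSE)
        counts[[tr]] <- length(sel)
      }
      list(n_traits = length(config$traits), screened_per_trait = counts,
           hashes = stage_hash(file.path(out, "reports",
                                         paste0(config$traits, ".json"))))
    })
  }

  manifest$finished <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Validate feature / phenotype tables
#'
#' Schema and consistency checks: required columns present and in the fixed
#' numbering order, no missing feature values, no duplicated image ids,
#' every feature fruit matched by a phenotype row, and trait values inside
#' their published envelopes (outside values are warnings, not violations).
#'
#' @param features_path CSV written by the extract stage.
#' @param phenotypes_path CSV of internal phenotypes.
#' @return list with character vectors `violations` and `warnings`; empty
#'   vectors mean a clean pass.
#' @export
validate_io <- function(features_path, phenotypes_path) {
  violations <- character(); warnings <- character()
  feats <- read.csv(features_path, check.names = FALSE,
                    stringsAsFactors = FALSE)
  pheno <- read.csv(phenotypes_path, stringsAsFactors = FALSE)

  need <- c("image_id", "fruit_id", "view", feature_names())
  missing <- setdiff(need, names(feats))
  if (length(missing))
    violations <- c(violations, sprintf("features: missing column '%s'",
                                        missing))
  present <- intersect(feature_names(), names(feats))
  if (!identical(present, intersect(names(feats), feature_names())) ||
      is.unsorted(match(present, feature_names())))
    violations <- c(violations, "features: columns out of numbering order")
  fx <- feats[intersect(feature_names(), names(feats))]
  if (anyNA(fx)) violations <- c(violations, "features: missing values")
  if ("image_id" %in% names(feats) && anyDuplicated(feats$image_id))
    violations <- c(violations, "features: duplicated image ids")

  if (!"fruit_id" %in% names(pheno)) {
    violations <- c(violations, "phenotypes: missing column 'fruit_id'")
  } else if ("fruit_id" %in% names(feats)) {
    orphans <- setdiff(feats$fruit_id, pheno$fruit_id)
    if (length(orphans))
      violations <- c(violations,
                      sprintf("features: fruit '%s' has no phenotype row",
                              orphans))
  }
  env <- melon_trait_envelopes
  for (i in seq_len(nrow(env))) {
    tr <- env$trait[i]
    if (!tr %in% names(pheno)) next
    v <- pheno[[tr]]
    bad <- sum(v < env$min[i] | v > env$max[i], na.rm = TRUE)
    if (bad > 0)
      warnings <- c(warnings,
                    sprintf("phenotypes: %d %s value(s) outside [%g, %g] %s",
                            bad, tr, env$min[i], env$max[i], env$unit[i]))
  }
  list(violations = violations, warnings = warnings)
}
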