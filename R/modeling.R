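# Per-trait random forest modelling: mtry tuning by repeated k-fold CV on a
# 2/3 training split, held-out validation metrics, MSE-based permutation
# importance, and the top-10 simplified model.

#' Random forest modelling configuration
#'
#' Defaults follow the study design: ntree = 300, mtry tuned over
#' 1..min(100, p), 10-fold cross-validation repeated 3 times on a seeded
#' 2/3 training split, top-10 simplification.
#'
#' @param ntree trees per forest.
#' @param mtry_grid integer grid of mtry values; NULL = 1..min(100, p).
#' @param cv_folds folds (>= 2).
#' @param cv_repeats repetitions of the CV.
#' @param train_fraction fraction of fruits in the training split.
#' @param nodesize terminal node size.
#' @param importance_reps permutation repetitions for importance.
#' @param k_top size of the simplified predictor set.
#' @param seed integer seed governing split, folds and fits.
#' @return an object of class `rf_config`.
#' @export
rf_config <- function(ntree = 300, mtry_grid = NULL, cv_folds = 10,
                      cv_repeats = 3, train_fraction = 2 / 3, nodesize = 5,
                      importance_reps = 5, k_top = 10, seed = 1L) {
  if (cv_folds < 2) stopf("cv_folds must be >= 2")
  if (train_fraction <= 0 || train_fraction > 1)
    stopf("train_fraction must be in (0, 1]")
  structure(list(ntree = as.integer(ntree), mtry_grid = mtry_grid,
                 cv_folds = as.integer(cv_folds),
                 cv_repeats = as.integer(cv_repeats),
                 train_fraction = train_fraction,
                 nodesize = as.integer(nodesize),
                 importance_reps = as.integer(importance_reps),
                 k_top = as.integer(k_top), seed = as.integer(seed)),
            class = "rf_config")
}

#' Regression accuracy metrics
#'
#' Returns both R-squared conventions: `r2_paper`, the explained-over-total
#' sum of squares sum((yhat - ybar)^2) / sum((y - ybar)^2), which is not
#' bounded above by 1 for non-least-squares predictors, and
#' `r2_conventional` = 1 - SSres/SStot, plus RMSE and MAE.
#'
#' @param y measured values (non-constant, length >= 2).
#' @param yhat predicted values, same length.
#' @return named numeric vector (r2_paper, r2_conventional, rmse, mae).
#' @export
metrics <- function(y, yhat) {
  if (length(y) != length(yhat)) stopf("y and yhat lengths differ")
  if (length(y) < 2) stopf("need at least two observations")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stopf("constant y: R-squared undefined")
  c(r2_paper = sum((yhat - mean(y))^2) / sst,
    r2_conventional = 1 - sum((y - yhat)^2) / sst,
    rmse = sqrt(mean((y - yhat)^2)),
    mae = mean(abs(y - yhat)))
}

#' Tune and fit the per-trait random forest
#'
#' Splits fruits into a seeded training fraction (views of one fruit never
#' straddle the split), tunes mtry by repeated k-fold CV RMSE on the
#' training rows (fold assignments shared across the grid; ties resolved
#' towards the smallest mtry), refits at the chosen mtry on all training
#' rows, and reports metrics on the held-out validation rows and on the
#' pooled CV predictions.
#'
#' @param X numeric matrix/data.frame of screened predictors (n x p).
#' @param y numeric trait values, length n.
#' @param config an [rf_config()].
#' @param fruit_ids grouping vector (length n) used for splitting and fold
#'   assignment; default one group per row.
#' @param trait optional trait label carried into the report.
#' @return object of class `melon_cv_report`: chosen mtry, CV RMSE per mtry,
#'   validation and CV metrics, per-sample predictions, the final
#'   `melon_rf` fit and timing.
#' @export
tune_fit <- function(X, y, config = rf_config(), fruit_ids = NULL,
                     trait = NULL) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n != length(y)) stopf("X and y sizes differ")
  if (n < 20) stopf("need at least 20 samples, got %d", n)
  if (p < 1) stopf("no predictors")
  if (anyNA(X) || anyNA(y)) stopf("non-finite values in training data")
  fruit_ids <- fruit_ids %||% seq_len(n)
  grid <- sort(unique(as.integer(config$mtry_grid %||% seq_len(min(100L, p)))))
  grid <- grid[grid >= 1 & grid <= p]
  if (!length(grid)) stopf("empty mtry grid after capping at p = %d", p)

  t0 <- proc.time()[["elapsed"]]
  res <- with_seed(config$seed, {
    units <- unique(fruit_ids)
    ntrain <- max(1L, round(config$train_fraction * length(units)))
    train_units <- sample(units, ntrain)
    tr_rows <- which(fruit_ids %in% train_units)
    va_rows <- setdiff(seq_len(n), tr_rows)
    tr_units <- fruit_ids[tr_rows]
    uniq_tr <- unique(tr_units)
    if (length(uniq_tr) < config$cv_folds)
      stopf("too few training fruits (%d) for %d folds", length(uniq_tr),
            config$cv_folds)

    fold_of <- lapply(seq_len(config$cv_repeats), function(r)
      setNames(sample(rep_len(seq_len(config$cv_folds), length(uniq_tr))),
               uniq_tr))

    cv_rmse <- matrix(NA_real_, length(grid), config$cv_repeats,
                      dimnames = list(as.character(grid), NULL))
    cv_pred_chosen <- NULL
    for (gi in seq_along(grid)) {
      for (r in seq_len(config$cv_repeats)) {
        folds <- fold_of[[r]][as.character(tr_units)]
        pred <- rep(NA_real_, length(tr_rows))
        for (f in seq_len(config$cv_folds)) {
          hold <- folds == f
          if (!any(hold) || all(hold)) next
          fit <- cpp_rf_build(X[tr_rows[!hold], , drop = FALSE],
                              y[tr_rows[!hold]], config$ntree, grid[gi],
                              config$nodesize)
          pred[hold] <- cpp_rf_predict(fit, X[tr_rows[hold], , drop = FALSE])
        }
        ok <- !is.na(pred)
        cv_rmse[gi, r] <- sqrt(mean((y[tr_rows][ok] - pred[ok])^2))
      }
    }
    mean_rmse <- rowMeans(cv_rmse)
    chosen <- grid[which.min(mean_rmse)]  # grid ascending: ties -> smallest

    final <- rf_fit(X[tr_rows, , drop = FALSE], y[tr_rows],
                    ntree = config$ntree, mtry = chosen,
                    nodesize = config$nodesize)
    # pooled CV predictions at the chosen mtry, for the CV-flavoured metrics
    ycv <- NULL; pcv <- NULL
    for (r in seq_len(config$cv_repeats)) {
      folds <- fold_of[[r]][as.character(tr_units)]
      pred <- rep(NA_real_, length(tr_rows))
      for (f in seq_len(config$cv_folds)) {
        hold <- folds == f
        if (!any(hold) || all(hold)) next
        fit <- cpp_rf_build(X[tr_rows[!hold], , drop = FALSE],
                            y[tr_rows[!hold]], config$ntree, chosen,
                            config$nodesize)
        pred[hold] <- cpp_rf_predict(fit, X[tr_rows[hold], , drop = FALSE])
      }
      ok <- !is.na(pred)
      ycv <- c(ycv, y[tr_rows][ok]); pcv <- c(pcv, pred[ok])
    }
    list(tr_rows = tr_rows, va_rows = va_rows, cv_rmse = cv_rmse,
         mean_rmse = mean_rmse, chosen = chosen, final = final,
         ycv = ycv, pcv = pcv)
  })

  val_metrics <- NULL
  pred_df <- data.frame(row = res$tr_rows, fruit_id = fruit_ids[res$tr_rows],
                        set = "train", y = y[res$tr_rows],
                        yhat = predict(res$final, X[res$tr_rows, , drop = FALSE]),
                        stringsAsFactors = FALSE)
  if (length(res$va_rows) >= 2) {
    yhat_va <- predict(res$final, X[res$va_rows, , drop = FALSE])
    val_metrics <- metrics(y[res$va_rows], yhat_va)
    pred_df <- rbind(pred_df,
                     data.frame(row = res$va_rows,
                                fruit_id = fruit_ids[res$va_rows],
                                set = "validation", y = y[res$va_rows],
                                yhat = yhat_va, stringsAsFactors = FALSE))
  }
  cv_metrics <- metrics(res$ycv, res$pcv)

  structure(list(trait = trait, n = n, p = p, chosen_mtry = res$chosen,
                 mtry_grid = grid,
                 cv_rmse_by_mtry = setNames(res$mean_rmse, grid),
                 metrics_validation = val_metrics, metrics_cv = cv_metrics,
                 predictions = pred_df, fit = res$final, config = config,
                 seconds = proc.time()[["elapsed"]] - t0),
            class = "melon_cv_report")
}

#' @export
print.melon_cv_report <- function(x, ...) {
  cat(sprintf("random forest report%s: n = %d, p = %d, chosen mtry = %d\n",
              if (is.null(x$trait)) "" else paste0(" [", x$trait, "]"),
              x$n, x$p, x$chosen_mtry))
  if (!is.null(x$metrics_validation)) {
    m <- x$metrics_validation
    cat(sprintf("  validation: R2 = %.3f (paper-form %.3f), RMSE = %.3f, MAE = %.3f\n",
                m["r2_conventional"], m["r2_paper"], m["rmse"], m["mae"]))
  }
  m <- x$metrics_cv
  cat(sprintf("  CV (pooled): R2 = %.3f, RMSE = %.3f\n",
              m["r2_conventional"], m["rmse"]))
  invisible(x)
}

#' Simplify a model to its top-k predictors
#'
#' Retains the `k` highest-ranked features of a permutation-importance
#' ranking (ties already resolved towards the lower parameter number),
#' re-tunes the forest on the reduced matrix with the mtry grid capped at
#' k, and reports the relative decrease of the validation R-squared.
#'
#' @param X,y as in [tune_fit()] (X holds the screened predictors).
#' @param ranking a [rf_importance()] result over X's columns.
#' @param k predictors retained (default 10).
#' @param config an [rf_config()].
#' @param fruit_ids grouping vector, as in [tune_fit()].
#' @param full_report optional precomputed full-model [tune_fit()] report;
#'   refit when NULL.
#' @return object of class `melon_simplified`: `full` and `simplified`
#'   reports, `retained` feature names, `r2_decrease_pct`.
#' @export
simplify <- function(X, y, ranking, k = 10, config = rf_config(),
                     fruit_ids = NULL, full_report = NULL) {
  if (k < 1) stopf("k must be >= 1")
  X <- as.matrix(X)
  kk <- min(k, ncol(X))
  top <- ranking$feature[ranking$rank <= kk]
  retained <- intersect(colnames(X), top)  # keep fixed numbering order
  full <- full_report %||% tune_fit(X, y, config, fruit_ids)
  grid <- config$mtry_grid %||% seq_len(min(100L, ncol(X)))
  cfg2 <- config
  cfg2$mtry_grid <- intersect(as.integer(grid), seq_len(kk))
  if (!length(cfg2$mtry_grid)) cfg2$mtry_grid <- seq_len(kk)
  simp <- tune_fit(X[, retained, drop = FALSE], y, cfg2, fruit_ids,
                   trait = full$trait)
  r2f <- (full$metrics_validation %||% full$metrics_cv)[["r2_conventional"]]
  r2s <- (simp$metrics_validation %||% simp$metrics_cv)[["r2_conventional"]]
  structure(list(full = full, simplified = simp, retained = retained,
                 r2_decrease_pct = (r2f - r2s) / r2f * 100),
            class = "melon_simplified")
}

#' Category make-up of the top-k parameters per trait
#'
#' Counts how many of each trait's top-k important parameters are colour,
#' texture (netting) and morphology parameters; the three counts sum to k
#' whenever at least k predictors were ranked.
#'
#' @param rankings named list (trait -> [rf_importance()] result).
#' @param k top set size (default 10).
#' @return data.frame with columns trait, color, texture, morphology.
#' @export
summarize_importance_categories <- function(rankings, k = 10) {
  cats <- feature_categories()
  rows <- lapply(names(rankings), function(tr) {
    rk <- rankings[[tr]]
    top <- rk$feature[rk$rank <= min(k, nrow(rk))]
    cc <- cats[top]
    data.frame(trait = tr,
               color = sum(cc == "color", na.rm = TRUE),
               texture = sum(cc == "texture", na.rm = TRUE),
               morphology = sum(cc == "morphology", na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
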