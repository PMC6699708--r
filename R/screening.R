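# Pearson screening of external parameters against internal phenotypes.
# Features significant at P < alpha (raw, no multiplicity correction, as in
# the screening-then-model workflow this package implements) enter the
# per-trait models; the -log10 P profile against parameter number is the
# standard visual summary.

#' Aggregate image-level features to fruit level
#'
#' Phenotypes are measured per fruit while features are extracted per view;
#' by default the views of a fruit are averaged. `mode = "per_view"` keeps
#' image-level rows (the fruit's phenotype is then replicated at merge
#' time).
#'
#' @param features data.frame with columns `image_id`, `fruit_id`, `view`
#'   and the 65 feature columns.
#' @param mode "mean" (default) or "per_view".
#' @return data.frame keyed by `fruit_id` (mode "mean") or unchanged.
#' @export
aggregate_views <- function(features, mode = c("mean", "per_view")) {
  mode <- match.arg(mode)
  if (!"fruit_id" %in% names(features))
    stopf("features must carry a fruit_id column")
  if (anyNA(features$fruit_id)) stopf("image with unknown fruit id")
  if (mode == "per_view") return(features)
  fcols <- intersect(feature_names(), names(features))
  if (!length(fcols)) stopf("no feature columns found")
  agg <- aggregate(features[fcols], by = list(fruit_id = features$fruit_id),
                   FUN = mean)
  agg[order(agg$fruit_id), , drop = FALSE]
}

# Two-sided p-value for a Pearson r at sample size n from the exact t
# reference: t = r * sqrt((n-2) / (1-r^2)) on n-2 df.
pearson_p <- function(r, n) {
  if (is.na(r) || n < 3) return(NA_real_)
  if (abs(r) >= 1) return(0)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(t), df = n - 2)
}

#' Pearson screening of features against traits
#'
#' For every (feature, trait) pair with at least `min_n` complete cases and
#' non-constant values, computes the product-moment correlation and its
#' two-sided t-based p-value; pairs with `p < alpha` are selected.
#' Constant or under-sampled pairs are flagged (`usable = FALSE`) and never
#' selected.
#'
#' @param features fruit-level data.frame (`fruit_id` + feature columns).
#' @param phenotypes data.frame (`fruit_id` + trait columns).
#' @param alpha selection threshold on the raw p-value (default 0.05).
#' @param traits traits to screen; default all trait columns present.
#' @param min_n minimum complete cases per pair (default 3).
#' @return object of class `melon_screen`: a data.frame with columns trait,
#'   feature, feature_no, n, r, p, neg_log10_p, usable, selected; attributes
#'   `alpha` and `traits`.
#' @export
pearson_screen <- function(features, phenotypes, alpha = 0.05, traits = NULL,
                           min_n = 3L) {
  if (!"fruit_id" %in% names(features) || !"fruit_id" %in% names(phenotypes))
    stopf("both tables need a fruit_id column")
  traits <- traits %||% intersect(melon_trait_envelopes$trait,
                                  names(phenotypes))
  if (!length(traits)) stopf("no trait columns to screen")
  fcols <- intersect(feature_names(), names(features))
  if (!length(fcols)) stopf("no feature columns to screen")
  merged <- merge(features, phenotypes[c("fruit_id", traits)], by = "fruit_id")
  fno <- match(fcols, feature_names())

  res <- do.call(rbind, lapply(traits, function(tr) {
    y_all <- merged[[tr]]
    rows <- lapply(seq_along(fcols), function(i) {
      x <- merged[[fcols[i]]]
      ok <- stats::complete.cases(x, y_all)
      n <- sum(ok)
      if (n < min_n || sd(x[ok]) == 0 || sd(y_all[ok]) == 0) {
        return(data.frame(trait = tr, feature = fcols[i], feature_no = fno[i],
                          n = n, r = NA_real_, p = NA_real_,
                          neg_log10_p = NA_real_, usable = FALSE,
                          selected = FALSE, stringsAsFactors = FALSE))
      }
      r <- cor(x[ok], y_all[ok])
      p <- pearson_p(r, n)
      data.frame(trait = tr, feature = fcols[i], feature_no = fno[i], n = n,
                 r = r, p = p, neg_log10_p = -log10(p), usable = TRUE,
                 selected = p < alpha, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))
  structure(res, alpha = alpha, traits = traits,
            class = c("melon_screen", "data.frame"))
}

#' Selected features of one trait, in numbering order
#'
#' @param screen a [pearson_screen()] result.
#' @param trait trait name.
#' @return character vector of selected feature names.
#' @export
selected_features <- function(screen, trait) {
  sub <- screen[screen$trait == trait & screen$selected, , drop = FALSE]
  sub$feature[order(sub$feature_no)]
}

#' Significance profile plot of the screen
#'
#' Per trait, -log10(p) against the parameter number 1-65, with a solid
#' horizontal line at -log10(alpha) (1.301 at the default alpha = 0.05);
#' points above the line are the selected parameters.
#'
#' @param screen a [pearson_screen()] result.
#' @param file optional PNG path; when NULL, draws on the active device.
#' @param cap ceiling applied to -log10(p) for display only.
#' @return the file path (or NULL), invisibly.
#' @export
screening_plot <- function(screen, file = NULL, cap = 16) {
  if (!nrow(screen)) stopf("empty screening result")
  traits <- attr(screen, "traits")
  alpha <- attr(screen, "alpha")
  if (!is.null(file)) {
    png(file, width = 1400, height = 220 * length(traits), res = 110,
        type = "cairo")
    on.exit(dev.off(), add = TRUE)
  }
  op <- par(mfrow = c(length(traits), 1), mar = c(2.2, 4, 1.2, 1))
  on.exit(par(op), add = TRUE)
  for (tr in traits) {
    sub <- screen[screen$trait == tr, , drop = FALSE]
    yv <- pmin(sub$neg_log10_p, cap)
    plot(sub$feature_no, yv, pch = 19, cex = 0.6,
         col = ifelse(sub$selected, "#d94801", "#4575b4"),
         xlab = "", ylab = expression(-log[10](P)), main = tr,
         xlim = c(1, 65), ylim = c(0, max(2, yv, na.rm = TRUE)))
    abline(h = -log10(alpha), lwd = 1.5)
  }
  invisible(file)
}
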