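#' Kruskal-Wallis rank test over groups
#'
#' Rank-based test that the groups share one distribution: mid-ranks over the
#' pooled values, the tie-corrected H statistic, and a chi-square upper-tail
#' p-value on `groups - 1` degrees of freedom (via [stats::kruskal.test()]).
#' With two groups it is equivalent to the chi-square-approximated two-sided
#' Wilcoxon rank-sum test.
#'
#' @param groups List (length >= 2) of numeric vectors, each nonempty; at
#'   least 3 values in total.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stopf("need at least two groups")
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stopf("every group must contain at least one value")
  if (sum(sizes) < 3L) stopf("need at least 3 values in total")
  kt <- kruskal.test(groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = unname(kt$p.value))
}

#' Significance band label for a p-value
#'
#' Banding used on the dose-comparison tables and box plots:
#' `p > 0.05` is `"n.s."`, `0.025 < p <= 0.05` is `"*"`,
#' `0.001 < p <= 0.025` is `"**"`, `p <= 0.001` is `"***"`.
#'
#' @param p_value Numeric vector of p-values in `[0, 1]`.
#' @return Character vector of labels.
#' @export
label_significance <- function(p_value) {
  p <- as.numeric(p_value)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  ifelse(p > 0.05, "n.s.",
         ifelse(p > 0.025, "*",
                ifelse(p > 0.001, "**", "***")))
}

#' Pairwise dose-group comparison of Haralick features
#'
#' For every feature and every unordered pair of dose groups, runs a
#' two-group Kruskal-Wallis test on the per-map feature values and attaches
#' the significance label. Maps are treated as independent observations by
#' default (mouse clustering ignored, matching the per-pair alpha = 0.05
#' box-plot comparisons such studies report); `cluster = "mouse_median"`
#' first collapses each mouse to its median feature value. No
#' multiple-testing correction by default; `correction = "holm"` adjusts the
#' p-values within each feature across its dose pairs.
#'
#' @param features Feature table from [features_for_dataset()].
#' @param feature_names Features to compare.
#' @param correction `"none"` (default) or `"holm"`.
#' @param cluster `"none"` (default) or `"mouse_median"`.
#' @param min_group Minimum observations per dose group; pairs with a smaller
#'   group are skipped with a warning.
#' @return A `comparison_table` data frame: `feature`, `dose_a`, `dose_b`,
#'   `statistic`, `df`, `p_value`, `label`.
#' @export
pairwise_dose_tests <- function(features,
                                feature_names = c("H", "Con", "Cor", "E", "LH"),
                                correction = c("none", "holm"),
                                cluster = c("none", "mouse_median"),
                                min_group = 2L) {
  correction <- match.arg(correction)
  cluster <- match.arg(cluster)
  if (!all(feature_names %in% names(features))) {
    stopf("feature table lacks column(s): %s",
          paste(setdiff(feature_names, names(features)), collapse = ", "))
  }
  doses <- sort(unique(features$dose_gy))
  if (length(doses) < 2L) stopf("need at least two dose levels")
  pairs <- utils::combn(doses, 2L)
  rows <- list()
  for (feat in feature_names) {
    df_feat <- features[, c("dose_gy", "mouse_id", feat)]
    if (cluster == "mouse_median") {
      df_feat <- aggregate(df_feat[[feat]],
                           by = list(dose_gy = df_feat$dose_gy,
                                     mouse_id = df_feat$mouse_id),
                           FUN = median)
      names(df_feat)[3L] <- feat
    }
    for (k in seq_len(ncol(pairs))) {
      da <- pairs[1L, k]; db <- pairs[2L, k]
      ga <- df_feat[[feat]][df_feat$dose_gy == da]
      gb <- df_feat[[feat]][df_feat$dose_gy == db]
      if (length(ga) < min_group || length(gb) < min_group) {
        warning(sprintf("dose pair %g vs %g skipped for %s: group too small",
                        da, db, feat), call. = FALSE)
        next
      }
      kw <- kruskal_wallis(list(ga, gb))
      rows[[length(rows) + 1L]] <- data.frame(
        feature = feat, dose_a = da, dose_b = db,
        statistic = kw$statistic, df = kw$df, p_value = kw$p_value,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (correction == "holm") {
    for (feat in unique(out$feature)) {
      i <- out$feature == feat
      out$p_value[i] <- stats::p.adjust(out$p_value[i], method = "holm")
    }
  }
  out$label <- label_significance(out$p_value)
  rownames(out) <- NULL
  class(out) <- c("comparison_table", class(out))
  out
}

#' Box plots of Haralick features by dose group
#'
#' One panel per feature: per-map feature values grouped by dose, coloured by
#' mouse, the standard presentation for dose-response texture studies.
#'
#' @param features Feature table from [features_for_dataset()].
#' @param feature_names Features to plot.
#' @return A named list of ggplot objects, one per feature.
#' @export
plot_feature_boxplots <- function(features,
                                  feature_names = c("H", "Con", "Cor", "E", "LH")) {
  long_names <- c(H = "homogeneity", Con = "contrast", Cor = "correlation",
                  E = "entropy", LH = "local homogeneity")
  lapply(setNames(feature_names, feature_names), function(feat) {
    df <- data.frame(dose = factor(features$dose_gy),
                     value = features[[feat]],
                     mouse = factor(features$mouse_id))
    ggplot2::ggplot(df, ggplot2::aes(x = dose, y = value)) +
      ggplot2::geom_boxplot(outlier.shape = NA) +
      ggplot2::geom_jitter(ggplot2::aes(colour = mouse),
                           width = 0.15, height = 0, size = 1.5) +
      ggplot2::labs(x = "dose (Gy)", y = feat,
                    title = sprintf("%s (%s) by dose", feat,
                                    long_names[[feat]] %||% feat)) +
      ggplot2::theme_minimal()
  })
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
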