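#' Aggregate contrast maps into an ROI value table
#'
#' For each subject, region and pool, the ROI value is the mean AUC over
#' the region's converged voxels. The whole-brain region is the union of
#' all labeled voxels and is always appended. Regions with zero
#' converged voxels yield a row marked excluded with a reason.
#'
#' @param contrast_by_subject named list (by subject id) of
#'   `contrast_maps` from [fit_stack()].
#' @param label_map a [roi_label_map()].
#' @param design data frame with `subject_id`, `group`.
#' @param regions region names to aggregate (default: all in the legend
#'   plus `whole_brain`).
#' @return `roi_value_table` data frame: `subject_id`, `group`,
#'   `region`, `pool`, `value`, `n_voxels`, `n_dropped`, `excluded`,
#'   `reason`.
#' @export
aggregate_roi <- function(contrast_by_subject, label_map, design,
                          regions = NULL) {
  stopifnot(inherits(label_map, "roi_label_map"))
  if (is.null(regions))
    regions <- c(unname(label_map$legend), "whole_brain")
  if (!"whole_brain" %in% regions) regions <- c(regions, "whole_brain")
  missing_subj <- setdiff(design$subject_id, names(contrast_by_subject))
  if (length(missing_subj))
    stop("no contrast maps for subject(s): ",
         paste(missing_subj, collapse = ", "))
  rows <- list()
  for (s in design$subject_id) {
    cm <- contrast_by_subject[[s]]
    grp <- design$group[match(s, design$subject_id)]
    for (r in regions) {
      vox <- region_voxels(label_map, r)
      for (p in names(cm$auc)) {
        vals <- cm$auc[[p]][vox]
        fin <- is.finite(vals)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = s, group = grp, region = r, pool = p,
          value = if (any(fin)) mean(vals[fin]) else NA_real_,
          n_voxels = sum(fin), n_dropped = sum(!fin),
          excluded = !any(fin),
          reason = if (any(fin)) NA_character_ else "no converged voxels",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("roi_value_table", class(out))
  out
}

#' Tukey-fence outlier flags (1.5 x IQR rule)
#'
#' Flags values outside `[Q1 - k*IQR, Q3 + k*IQR]`. Quartiles use linear
#' interpolation between order statistics ([stats::quantile()] type 7 by
#' default); the convention matters for small groups and is therefore
#' configurable. When the IQR is zero the rule would excise every
#' differing value, so exclusion is skipped with a warning in that case.
#' Groups of fewer than 3 values are never flagged.
#'
#' @param values numeric vector (one group's values).
#' @param k fence multiplier (default 1.5, the "150% IQR" rule).
#' @param qtype quantile type passed to [stats::quantile()].
#' @return logical vector, TRUE where the value is an outlier.
#' @export
flag_outliers_iqr <- function(values, k = 1.5, qtype = 7) {
  out <- rep(FALSE, length(values))
  fin <- is.finite(values)
  if (sum(fin) < 3L) return(out)
  q <- stats::quantile(values[fin], c(0.25, 0.75), type = qtype, names = FALSE)
  iqr <- q[2] - q[1]
  if (iqr == 0) {
    if (any(values[fin] != stats::median(values[fin])))
      warning("IQR is zero but values differ; skipping outlier exclusion")
    return(out)
  }
  out[fin] <- values[fin] < q[1] - k * iqr | values[fin] > q[2] + k * iqr
  out
}

#' Ordinary one-way ANOVA
#'
#' Classical fixed-effects one-way ANOVA via [stats::aov()]:
#' F = MS(between)/MS(within) on (k-1, N-k) degrees of freedom. Groups
#' with fewer than 2 values are skipped with a message; NA is returned
#' when fewer than 2 usable groups remain.
#'
#' @param groups list of numeric vectors, one per group.
#' @return list with `F`, `p`, `df1`, `df2`, `n_groups`.
#' @export
one_way_anova <- function(groups) {
  groups <- lapply(groups, function(x) x[is.finite(x)])
  keep <- vapply(groups, length, 0L) >= 2L
  if (any(!keep))
    message(sprintf("one_way_anova: skipping %d group(s) with < 2 values",
                    sum(!keep)))
  groups <- groups[keep]
  if (length(groups) < 2L)
    return(list(F = NA_real_, p = NA_real_, df1 = NA_integer_,
                df2 = NA_integer_, n_groups = length(groups)))
  d <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(seq_along(groups), vapply(groups, length, 0L))))
  s <- summary(stats::aov(value ~ group, data = d))[[1]]
  F <- s[["F value"]][1]; p <- s[["Pr(>F)"]][1]
  if (!is.finite(F)) {
    # degenerate: zero within-group variance
    means <- vapply(groups, mean, 0)
    if (max(means) - min(means) == 0) { F <- 0; p <- 1 } else { F <- Inf; p <- 0 }
  }
  list(F = F, p = p, df1 = s[["Df"]][1], df2 = s[["Df"]][2],
       n_groups = length(groups))
}

#' Two-tailed pairwise t-tests
#'
#' Student (pooled-variance) two-tailed t-test for each requested pair
#' of groups, via [stats::t.test()] with `var.equal = TRUE` (Welch
#' available with `var_equal = FALSE`). No multiple-comparison
#' adjustment is applied by default; Holm is available via `p_adjust`.
#' Degenerate pairs with zero pooled variance give p = 1 when the means
#' agree and p = 0 (with a warning) when they differ.
#'
#' @param groups named list of numeric vectors.
#' @param comparisons data frame with columns `group1`, `group2`, or a
#'   list of length-2 character vectors.
#' @param var_equal pooled-variance t (TRUE, default) or Welch.
#' @param p_adjust `"none"` (default) or any [stats::p.adjust()] method.
#' @return data frame: `group1`, `group2`, `t`, `df`, `p`, `p_adj`.
#' @export
pairwise_ttests <- function(groups, comparisons, var_equal = TRUE,
                            p_adjust = "none") {
  if (is.data.frame(comparisons)) {
    comparisons <- Map(c, comparisons$group1, comparisons$group2)
  }
  if (length(comparisons) == 0L)
    return(data.frame(group1 = character(), group2 = character(),
                      t = numeric(), df = numeric(), p = numeric(),
                      p_adj = numeric(), stringsAsFactors = FALSE))
  rows <- lapply(comparisons, function(cmp) {
    g1 <- cmp[1]; g2 <- cmp[2]
    if (!all(c(g1, g2) %in% names(groups)))
      stop("comparison names unknown group: ", g1, " vs ", g2)
    x <- groups[[g1]][is.finite(groups[[g1]])]
    y <- groups[[g2]][is.finite(groups[[g2]])]
    if (length(x) < 2L || length(y) < 2L)
      return(data.frame(group1 = g1, group2 = g2, t = NA_real_,
                        df = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    tt <- tryCatch(
      stats::t.test(x, y, var.equal = var_equal),
      error = function(e) NULL)
    if (is.null(tt)) {  # essentially constant data
      if (isTRUE(all.equal(mean(x), mean(y)))) {
        t <- 0; p <- 1
      } else {
        warning(sprintf("zero pooled variance with unequal means (%s vs %s); p = 0",
                        g1, g2))
        t <- sign(mean(x) - mean(y)) * Inf; p <- 0
      }
      df <- length(x) + length(y) - 2
    } else {
      t <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
    }
    data.frame(group1 = g1, group2 = g2, t = t, df = df, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = p_adjust)
  out
}

#' Significance flag for a p-value
#'
#' `"*"` for p < 0.05 (significant), `"#"` for 0.05 < p < 0.1
#' (trend), empty otherwise. Vectorized; NA propagates.
#'
#' @param p numeric vector of p-values.
#' @return character vector of flags.
#' @export
p_flag <- function(p) {
  out <- rep(NA_character_, length(p))
  ok <- !is.na(p)
  out[ok] <- ifelse(p[ok] < 0.05, "*",
                    ifelse(p[ok] > 0.05 & p[ok] < 0.1, "#", ""))
  out
}

#' Default group comparisons
#'
#' Each treatment against vehicle, plus co-treatment against each single
#' treatment.
#' @return data frame with `group1`, `group2`.
#' @export
default_comparisons <- function() {
  data.frame(
    group1 = c("ART", "nicotine", "cotreat", "cotreat", "cotreat"),
    group2 = c("vehicle", "vehicle", "vehicle", "ART", "nicotine"),
    stringsAsFactors = FALSE
  )
}

#' Summarize an ROI value table into the group-statistics surface
#'
#' Per (region, pool): applies the Tukey-fence outlier exclusion within
#' each group, then computes group means and SEMs (sd/sqrt(n) with n
#' after exclusion), the one-way ANOVA, and the requested pairwise
#' two-tailed t-tests with `*`/`#` flags.
#'
#' @param roi_table a [aggregate_roi()] table (or any data frame with
#'   `subject_id`, `group`, `region`, `pool`, `value`).
#' @param comparisons data frame `group1`/`group2`
#'   (default [default_comparisons()], restricted to groups present).
#' @param outlier_k Tukey fence multiplier; NULL disables exclusion.
#' @param qtype quartile convention for the fence.
#' @param var_equal pooled-variance (TRUE) or Welch t-tests.
#' @param p_adjust multiple-testing adjustment (default `"none"`).
#' @return a `stats_table`: list with `summary` (region, pool, group, n,
#'   mean, sem), `anova` (region, pool, F, df1, df2, p, flag), `tests`
#'   (region, pool, group1, group2, t, df, p, p_adj, flag) and
#'   `exclusions` (rows removed by the fence rule).
#' @export
summarize_roi_stats <- function(roi_table, comparisons = NULL,
                                outlier_k = 1.5, qtype = 7,
                                var_equal = TRUE, p_adjust = "none") {
  need <- c("subject_id", "group", "region", "pool", "value")
  stopifnot(all(need %in% names(roi_table)))
  tab <- as.data.frame(roi_table)
  if (!"excluded" %in% names(tab)) tab$excluded <- FALSE
  tab <- tab[!tab$excluded & is.finite(tab$value), ]
  groups_present <- unique(tab$group)
  if (is.null(comparisons)) {
    comparisons <- default_comparisons()
    comparisons <- comparisons[comparisons$group1 %in% groups_present &
                                 comparisons$group2 %in% groups_present, ]
    if (nrow(comparisons) == 0L && length(groups_present) >= 2L)
      comparisons <- data.frame(group1 = groups_present[-1],
                                group2 = groups_present[1])
  }
  cells <- unique(tab[, c("region", "pool")])
  summary_rows <- list(); anova_rows <- list(); test_rows <- list()
  excl_rows <- list()
  for (i in seq_len(nrow(cells))) {
    r <- cells$region[i]; p <- cells$pool[i]
    cell <- tab[tab$region == r & tab$pool == p, ]
    if (!is.null(outlier_k)) {
      for (g in unique(cell$group)) {
        sel <- cell$group == g
        out <- flag_outliers_iqr(cell$value[sel], k = outlier_k, qtype = qtype)
        if (any(out)) {
          ex <- cell[sel, ][out, ]
          ex$reason <- "iqr_outlier"
          excl_rows[[length(excl_rows) + 1L]] <- ex
          cell <- cell[!(rownames(cell) %in% rownames(ex)), ]
        }
      }
    }
    by_group <- split(cell$value, factor(cell$group, levels = groups_present))
    for (g in names(by_group)) {
      v <- by_group[[g]]
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        region = r, pool = p, group = g, n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        sem = if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_,
        stringsAsFactors = FALSE)
    }
    an <- suppressMessages(one_way_anova(by_group))
    anova_rows[[length(anova_rows) + 1L]] <- data.frame(
      region = r, pool = p, F = an$F, df1 = an$df1, df2 = an$df2,
      p = an$p, flag = p_flag(an$p), stringsAsFactors = FALSE)
    tt <- pairwise_ttests(by_group, comparisons, var_equal = var_equal,
                          p_adjust = p_adjust)
    if (nrow(tt)) {
      tt$flag <- p_flag(tt$p_adj)
      tt <- cbind(data.frame(region = r, pool = p, stringsAsFactors = FALSE), tt)
      test_rows[[length(test_rows) + 1L]] <- tt
    }
  }
  structure(list(
    summary = do.call(rbind, summary_rows),
    anova = do.call(rbind, anova_rows),
    tests = do.call(rbind, test_rows),
    exclusions = if (length(excl_rows)) do.call(rbind, excl_rows) else
      data.frame()
  ), class = "stats_table")
}

#' Write a stats table to CSV and JSON
#'
#' @param stats a `stats_table` from [summarize_roi_stats()].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_stats_table <- function(stats, dir, prefix = "stats") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    file.path(dir, paste0(prefix, "_summary.csv")),
    file.path(dir, paste0(prefix, "_anova.csv")),
    file.path(dir, paste0(prefix, "_tests.csv")),
    file.path(dir, paste0(prefix, ".json")))
  utils::write.csv(stats$summary, paths[1], row.names = FALSE)
  utils::write.csv(stats$anova, paths[2], row.names = FALSE)
  utils::write.csv(stats$tests, paths[3], row.names = FALSE)
  jsonlite::write_json(
    list(summary = stats$summary, anova = stats$anova, tests = stats$tests),
    paths[4], dataframe = "rows", digits = NA, na = "null")
  invisible(paths)
}
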