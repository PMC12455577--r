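test_that("Tukey fence with interpolated quartiles excludes exactly the planted outlier", {
  out <- flag_outliers_iqr(c(1, 2, 3, 4, 100))
  # hand computation, type-7 quartiles: Q1 = 2, Q3 = 4, fences [-1, 7]
  expect_identical(out, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_false(any(flag_outliers_iqr(c(1, 2, 3, 4))))   # fences [-0.5, 5.5]
  expect_false(any(flag_outliers_iqr(c(5, 5, 5, 5))))   # IQR = 0 guard
  expect_warning(res <- flag_outliers_iqr(c(5, 5, 5, 5, 5, 9)), "IQR is zero")
  expect_false(any(res))
  expect_false(any(flag_outliers_iqr(c(1, 100))))       # < 3 values: never flag
})

test_that("outlier exclusion is idempotent on the retained set", {
  set.seed(8)
  for (i in 1:20) {
    x <- c(stats::rnorm(8), stats::rnorm(2, sd = 12))
    out <- flag_outliers_iqr(x)
    kept <- x[!out]
    q <- stats::quantile(x[is.finite(x)], c(0.25, 0.75), type = 7, names = FALSE)
    fences <- c(q[1] - 1.5 * diff(q), q[2] + 1.5 * diff(q))
    # single-pass semantics: retained values all sit inside the original fences
    expect_true(all(kept >= fences[1] & kept <= fences[2]))
  }
})

test_that("one-way ANOVA reproduces hand-computed F and its degenerate limits", {
  an <- one_way_anova(list(c(3, 4, 5), c(6, 7, 8)))
  expect_equal(an$F, 13.5)          # MSb = 13.5, MSw = 1
  expect_equal(an$df1, 1L)
  expect_equal(an$df2, 4L)
  z <- one_way_anova(list(c(1, 3), c(2, 2), c(3, 1)))  # equal means
  expect_equal(z$F, 0)
  expect_equal(z$p, 1)
  msg <- capture.output(
    sk <- one_way_anova(list(c(1, 2, 3), c(5))), type = "message")
  expect_match(paste(msg, collapse = " "), "skipping")
  expect_true(is.na(sk$F))
})

test_that("F equals t squared for two groups", {
  set.seed(13)
  for (i in 1:25) {
    g1 <- stats::rnorm(4 + i %% 3); g2 <- stats::rnorm(5, mean = 0.5)
    an <- one_way_anova(list(g1, g2))
    tt <- pairwise_ttests(list(a = g1, b = g2), list(c("a", "b")))
    expect_lt(abs(an$F - tt$t^2), 1e-12)
    expect_lt(abs(an$p - tt$p), 1e-12)
  }
})

test_that("pairwise t-tests reproduce hand computations and degenerate rules", {
  tt <- pairwise_ttests(list(a = c(3, 4, 5), b = c(6, 7, 8)),
                        list(c("a", "b")))
  expect_equal(tt$t, -3.674235, tolerance = 1e-6)  # pooled sd 1, se 0.8165
  expect_equal(tt$df, 4)
  expect_equal(tt$p, 0.02131164, tolerance = 1e-6)
  same <- pairwise_ttests(list(a = c(1, 2, 3), b = c(1, 2, 3)),
                          list(c("a", "b")))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  const_eq <- pairwise_ttests(list(a = c(2, 2), b = c(2, 2)),
                              list(c("a", "b")))
  expect_equal(const_eq$p, 1)
  expect_warning(
    const_ne <- pairwise_ttests(list(a = c(2, 2), b = c(3, 3)),
                                list(c("a", "b"))),
    "zero pooled variance")
  expect_equal(const_ne$p, 0)
})

test_that("significance flags follow the * and # rules strictly", {
  expect_identical(p_flag(c(0.027, 0.089, 0.11, 0.05, 0.1)),
                   c("*", "#", "", "", ""))
  expect_identical(p_flag(c(0.049999, NA)), c("*", NA))
})

test_that("SEM times sqrt(n) equals the sample standard deviation", {
  tab <- data.frame(
    subject_id = sprintf("s%d", 1:4), group = "vehicle",
    region = "thalamus", pool = "GLU", value = c(2, 4, 6, 8))
  st <- summarize_roi_stats(tab, comparisons = data.frame(group1 = character(),
                                                          group2 = character()))
  expect_equal(st$summary$mean, 5)
  expect_equal(st$summary$sem, 2.581989 / sqrt(4), tolerance = 1e-6)
  expect_equal(st$summary$sem * sqrt(st$summary$n), stats::sd(c(2, 4, 6, 8)))
})

test_that("the full statistics surface: exclusion, ANOVA, pairwise tests and flags", {
  groups <- c("vehicle", "ART", "nicotine", "cotreat")
  tab <- expand.grid(subject_id = sprintf("s%d", 1:16), region = "thalamus",
                     pool = "GLU", stringsAsFactors = FALSE)
  tab$group <- rep(groups, each = 4)
  tab$value <- c(0.046, 0.047, 0.0475, 0.048,    # vehicle
                 0.032, 0.033, 0.0335, 0.034,    # ART: clearly lower
                 0.046, 0.30, 0.047, 0.048,      # nicotine with one outlier
                 0.046, 0.0465, 0.047, 0.048)    # cotreat
  tab$value[tab$subject_id == "s10"] <- 0.30  # blatant nicotine outlier
  st <- summarize_roi_stats(tab)
  expect_equal(nrow(st$exclusions), 1L)
  expect_equal(st$exclusions$subject_id, "s10")
  expect_equal(st$summary$n[st$summary$group == "nicotine"], 3L)
  art <- st$tests[st$tests$group1 == "ART" & st$tests$group2 == "vehicle", ]
  expect_lt(art$p, 0.05)
  expect_identical(art$flag, "*")
  expect_lt(st$anova$p, 0.05)
  # ART mean clearly below vehicle's
  ms <- st$summary
  expect_lt(ms$mean[ms$group == "ART"], ms$mean[ms$group == "vehicle"])
})

test_that("aggregate_roi averages converged voxels and records exclusions", {
  lay <- roi_label_map(matrix(c(1L, 1L, 2L, 2L), 2, 2),
                       c("1" = "cortex", "2" = "thalamus"))
  auc <- matrix(c(3, 5, NA, NA), 2, 2)
  cm <- list(auc = list(GLU = auc), converged = !is.na(auc))
  design <- data.frame(subject_id = "s1", group = "vehicle")
  tab <- aggregate_roi(list(s1 = cm), lay, design)
  ctx <- tab[tab$region == "cortex", ]
  expect_equal(ctx$value, 4)           # mean of the converged voxels
  expect_equal(ctx$n_voxels, 2L)
  th <- tab[tab$region == "thalamus", ]
  expect_true(th$excluded)
  expect_match(th$reason, "no converged")
  wb <- tab[tab$region == "whole_brain", ]
  expect_equal(wb$value, 4)            # union sees only the converged two
  expect_equal(wb$n_dropped, 2L)
})

test_that("null group data reject at close to the nominal alpha", {
  set.seed(77)
  n_sim <- 400L
  rej <- vapply(seq_len(n_sim), function(i) {
    g <- replicate(2, stats::rnorm(4), simplify = FALSE)
    names(g) <- c("a", "b")
    pairwise_ttests(g, list(c("a", "b")))$p < 0.05
  }, NA)
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})
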