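test_that("repeatability CV matches hand computation and its invariances", {
  tab <- data.frame(subject_id = c(1, 1), location = "Gwan",
                    rep = 1:2, pdi_mm = c(4, 6))
  expect_equal(unname(repeatability_cv(tab, "pdi_mm")["Gwan"]),
               100 * sqrt(2) / 5)

  # identical repeats: zero CV
  tab0 <- data.frame(subject_id = rep(1:5, each = 2),
                     location = "Chon", rep = rep(1:2, 5),
                     pdi_mm = rep(c(3, 4, 5, 6, 7), each = 2))
  expect_equal(unname(repeatability_cv(tab0, "pdi_mm")["Chon"]), 0)

  # scale invariance
  tabx <- data.frame(subject_id = rep(1:4, each = 2), location = "Cheok",
                     rep = rep(1:2, 4), pdi_mm = rnorm(8, 5, 0.5))
  taby <- tabx; taby$pdi_mm <- 10 * tabx$pdi_mm
  expect_equal(repeatability_cv(tabx, "pdi_mm"),
               repeatability_cv(taby, "pdi_mm"))

  # zero-mean subject excluded with a message
  tabz <- data.frame(subject_id = rep(1:2, each = 2), location = "Gwan",
                     rep = rep(1:2, 2), pdi_mm = c(1, -1, 4, 6))
  expect_message(cv <- repeatability_cv(tabz, "pdi_mm"), "excluded")
  expect_equal(unname(cv["Gwan"]), 100 * sqrt(2) / 5)

  # pooled mode is the RMS of the subject CVs
  cvs <- vapply(split(tabx$pdi_mm, tabx$subject_id),
                function(v) 100 * sd(v) / mean(v), numeric(1))
  expect_equal(unname(repeatability_cv(tabx, "pdi_mm", mode = "pooled")["Cheok"]),
               sqrt(mean(cvs^2)))
})

test_that("one-way ANOVA reproduces hand-computed statistics and handles degeneracy", {
  r <- one_way_anova(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(r$f_stat, 13.5)
  expect_equal(r$p_value, pf(13.5, 1, 4, lower.tail = FALSE))

  same <- one_way_anova(list(a = c(2, 2), b = c(2, 2), c = c(2, 2)))
  expect_identical(same$f_stat, 0)
  expect_identical(same$p_value, 1)

  # permutation of group labels of identical data leaves F unchanged
  g <- list(a = c(1, 3, 2), b = c(2, 1, 3), c = c(3, 2, 1))
  f1 <- one_way_anova(g)$f_stat
  f2 <- one_way_anova(g[c(2, 3, 1)])$f_stat
  expect_equal(f1, f2)

  expect_error(one_way_anova(list(a = 1:3)), "2 groups")
  expect_error(one_way_anova(list(a = 1, b = 1:3)), ">= 2 values")
})

test_that("Duncan's test merges identical groups and matches the two-group closed form", {
  same <- duncan_posthoc(list(Chon = c(2, 2), Gwan = c(2, 2),
                              Cheok = c(2, 2)))
  expect_identical(length(same$homogeneous_subsets), 1L)
  expect_setequal(same$homogeneous_subsets[[1]], c("Chon", "Gwan", "Cheok"))

  # two groups: decision equals the single studentized-range test
  set.seed(8)
  for (shift in c(0.1, 0.5, 1, 2)) {
    g1 <- rnorm(9)
    g2 <- rnorm(9) + shift
    r <- duncan_posthoc(list(a = g1, b = g2), alpha = 0.05)
    av <- one_way_anova(list(a = g1, b = g2))
    crit <- qtukey(0.95, 2, av$df_within) * sqrt(av$ms_within / 9)
    separated <- abs(mean(g1) - mean(g2)) > crit
    expect_identical(length(r$homogeneous_subsets) == 2L, separated)
  }
})

test_that("Duncan subsets respect the ordering containment property", {
  set.seed(21)
  for (i in 1:25) {
    g <- list(a = rnorm(8, 0), b = rnorm(8, runif(1, 0, 2)),
              c = rnorm(8, runif(1, 0, 3)), d = rnorm(8, runif(1, 0, 4)))
    r <- duncan_posthoc(g, alpha = 0.05)
    means <- r$group_means
    for (s in r$homogeneous_subsets) {
      lo <- min(means[s]); hi <- max(means[s])
      inside <- names(means)[means >= lo & means <= hi]
      expect_true(all(inside %in% s))
    }
    # every group appears in at least one subset
    expect_setequal(unique(unlist(r$homogeneous_subsets)), names(g))
  }
})

test_that("a deeper Cheok separates in the simulated cohort design", {
  lp <- default_location_params()
  lp$Chon$depth_mean_mm <- 3.7
  lp$Gwan$depth_mean_mm <- 3.7
  lp$Cheok$depth_mean_mm <- 5.0
  hits <- 0
  n_rep <- 40
  for (s in seq_len(n_rep)) {
    coh <- simulate_cohort(18, n_repeats = 2, seed = 7000 + s,
                           location_params = lp, signals = FALSE)
    tt <- coh$truth_table
    groups <- lapply(split(tt, tt$location),
                     function(d) tapply(d$true_pdi_mm, d$subject_id, mean))
    r <- duncan_posthoc(groups, alpha = 0.01)
    subs <- r$homogeneous_subsets
    sep <- any(vapply(subs, function(x) setequal(x, c("Chon", "Gwan")),
                      logical(1))) &&
      any(vapply(subs, function(x) identical(x, "Cheok"), logical(1)))
    hits <- hits + sep
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("squared correlation matches hand computation and its contracts", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlation_r2(x, 2 * x + 1), 1)

  # orthogonal alternating pattern
  expect_equal(correlation_r2(c(1, -1, 1, -1), c(1, 1, -1, -1)), 0)

  y <- c(2.3, 4.1, 5.8, 8.4, 9.9)
  r2_hand <- (sum((x - mean(x)) * (y - mean(y))))^2 /
    (sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(correlation_r2(x, y), r2_hand, tolerance = 1e-12)

  expect_error(correlation_r2(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(correlation_r2(1:3, 1:4), "equal length")
})

test_that("cohort summary aggregates indices and runs the post hoc comparison", {
  coh <- simulate_cohort(6, n_repeats = 2, seed = 31, signals = FALSE)
  tt <- coh$truth_table
  tt$pdi_mm <- tt$true_pdi_mm
  tt$ocp_mmHg <- 100 + 10 * tt$true_pdi_mm
  tt$cfs_pad <- pmin(1, pmax(0, tt$true_pdi_mm / 8))
  s <- cohort_summary(tt)
  expect_identical(nrow(s$summary), 9L)  # 3 locations x 3 indices
  expect_s3_class(s$posthoc, "posthoc_result")
  expect_true(all(is.finite(s$summary$cv_pct)))
})
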