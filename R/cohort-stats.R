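#' Test-retest coefficient of variation
#'
#' Per subject and location the CV of the repeated measures is
#' `100 * sd(repeats) / mean(repeats)` (sample SD, n-1); the per-location
#' CV is the mean of the subject CVs (`mode = "mean"`, the default) or
#' the root-mean-square of the subject CVs (`mode = "pooled"`). Subjects
#' whose repeat mean is zero are excluded with a message.
#'
#' @param table cohort data frame with columns `subject_id`, `location`,
#'   `rep`, and the index column `index_name`.
#' @param index_name name of the index column (e.g. `"pdi_mm"`).
#' @param mode aggregation across subjects: `"mean"` or `"pooled"`.
#' @return named numeric vector: CV (%) per location.
#' @examples
#' tab <- data.frame(subject_id = c(1, 1), location = "Gwan",
#'                   rep = 1:2, pdi_mm = c(4, 6))
#' repeatability_cv(tab, "pdi_mm")  # 100*sqrt(2)/5
#' @export
repeatability_cv <- function(table, index_name, mode = c("mean", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(all(c("subject_id", "location", "rep", index_name) %in% names(table)))
  locs <- unique(table$location)
  out <- vapply(locs, function(loc) {
    sub <- table[table$location == loc, ]
    cvs <- vapply(unique(sub$subject_id), function(s) {
      v <- sub[[index_name]][sub$subject_id == s]
      if (length(v) < 2) return(NA_real_)
      m <- mean(v)
      if (m == 0) {
        message(sprintf("subject %s at %s: zero repeat mean, excluded from CV", s, loc))
        return(NA_real_)
      }
      100 * sd(v) / m
    }, numeric(1))
    cvs <- cvs[!is.na(cvs)]
    if (!length(cvs)) return(NA_real_)
    if (mode == "mean") mean(cvs) else sqrt(mean(cvs^2))
  }, numeric(1))
  names(out) <- locs
  out
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA via [stats::lm()]. Degenerate
#' inputs are given an explicit contract: if both the between- and
#' within-group variances are zero (all values identical) the F
#' statistic is defined as 0 with p = 1.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each >= 2
#'   values).
#' @return list with `f_stat`, `p_value`, `df_between`, `df_within`,
#'   `ms_within`, `group_means`, `group_n`.
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(4, 5, 6)))$f_stat  # 13.5
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2)) stop("each group needs >= 2 values")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  value <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 1L)),
              levels = names(groups))
  k <- length(groups)
  n <- length(value)

  if (var(value) < .Machine$double.eps * max(1, mean(value)^2)) {
    return(list(f_stat = 0, p_value = 1, df_between = k - 1,
                df_within = n - k, ms_within = 0,
                group_means = vapply(groups, mean, numeric(1)),
                group_n = vapply(groups, length, 1L)))
  }

  fit <- lm(value ~ g)
  a <- anova(fit)
  ms_within <- a$`Mean Sq`[2]
  f_stat <- a$`F value`[1]
  p_value <- a$`Pr(>F)`[1]
  if (!is.finite(f_stat)) {  # zero within-group variance, means differ
    f_stat <- Inf
    p_value <- 0
  }
  list(f_stat = f_stat, p_value = p_value,
       df_between = k - 1, df_within = n - k, ms_within = ms_within,
       group_means = vapply(groups, mean, numeric(1)),
       group_n = vapply(groups, length, 1L))
}

#' Duncan's multiple range test
#'
#' Stepwise post hoc grouping of means into homogeneous subsets. Means
#' are ranked; a stretch of `p` ordered means is declared heterogeneous
#' when its range exceeds the critical value
#' `R_p = q(1 - alpha_p, p, df_within) * sqrt(MS_within / n_h)`, with
#' the progressive protection level `alpha_p = 1 - (1 - alpha)^(p - 1)`
#' (studentized-range quantiles via [stats::qtukey()]) and `n_h` the
#' harmonic mean group size. Non-significant stretches merge into
#' homogeneous subsets reported as letter groups; by the containment
#' property of range tests a mean lying between two members of a subset
#' belongs to that subset.
#'
#' @param groups named list of numeric vectors.
#' @param alpha significance level.
#' @return An object of class `posthoc_result`: list with
#'   `group_means` (sorted ascending), `f_stat`, `p_value`,
#'   `homogeneous_subsets` (list of character vectors),
#'   `letters` (named letter codes per group), `alpha`,
#'   `critical_ranges`.
#' @examples
#' r <- duncan_posthoc(list(a = c(1, 1.1), b = c(1.05, 0.95),
#'                          c = c(5, 5.2)), alpha = 0.05)
#' r$homogeneous_subsets
#' @export
duncan_posthoc <- function(groups, alpha = 0.05) {
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  aov_res <- one_way_anova(groups)
  k <- length(groups)
  means <- sort(vapply(groups, mean, numeric(1)))
  n_h <- k / sum(1 / aov_res$group_n)  # harmonic mean for imbalance
  df <- aov_res$df_within
  se <- sqrt(aov_res$ms_within / n_h)

  crit <- vapply(2:max(2, k), function(p) {
    alpha_p <- 1 - (1 - alpha)^(p - 1)
    qtukey(1 - alpha_p, p, df) * se
  }, numeric(1))
  names(crit) <- paste0("p", 2:max(2, k))

  # recursive range testing: a stretch is homogeneous when its range is
  # below the critical range for its span; otherwise split
  subsets <- list()
  explore <- function(i, j) {
    if (i >= j) {
      subsets[[length(subsets) + 1]] <<- names(means)[i]
      return(invisible())
    }
    p <- j - i + 1
    if (means[j] - means[i] <= crit[p - 1] + 1e-12) {
      subsets[[length(subsets) + 1]] <<- names(means)[i:j]
    } else {
      explore(i, j - 1)
      explore(i + 1, j)
    }
  }
  if (k == 1) {
    subsets <- list(names(means))
  } else {
    explore(1, k)
  }
  # drop duplicates first (a subset can be reached along two recursion
  # paths), then subsets strictly contained in another
  subsets <- unique(subsets)
  keep <- !vapply(seq_along(subsets), function(a) {
    any(vapply(seq_along(subsets), function(b) {
      a != b && all(subsets[[a]] %in% subsets[[b]])
    }, logical(1)))
  }, logical(1))
  subsets <- subsets[keep]

  letters_vec <- setNames(rep("", k), names(means))
  for (s in seq_along(subsets)) {
    lab <- letters[s]
    for (g in subsets[[s]]) letters_vec[g] <- paste0(letters_vec[g], lab)
  }

  structure(
    list(group_means = means, f_stat = aov_res$f_stat,
         p_value = aov_res$p_value, homogeneous_subsets = subsets,
         letters = letters_vec, alpha = alpha, critical_ranges = crit,
         df_within = df, ms_within = aov_res$ms_within),
    class = "posthoc_result"
  )
}

#' @export
print.posthoc_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.3f, p = %.4g\n", x$f_stat, x$p_value))
  cat(sprintf("Duncan's multiple range test (alpha = %g):\n", x$alpha))
  for (g in names(x$group_means)) {
    cat(sprintf("  %-8s %8.3f  %s\n", g, x$group_means[g], x$letters[g]))
  }
  invisible(x)
}

#' Squared correlation coefficient
#'
#' The coefficient of determination of the simple linear fit of `y` on
#' `x`, i.e. the squared Pearson correlation.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return `r2` in \\[0, 1\\].
#' @export
correlation_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (var(x) == 0 || var(y) == 0) stop("zero variance: correlation undefined")
  unname(cor(x, y)^2)
}

#' Cohort summary in the style of a repeated-measures table
#'
#' Mean, SD and test-retest CV of each index per location, plus the
#' ANOVA/Duncan comparison of a chosen index across locations.
#'
#' @param table cohort data frame (see [cohort_table()]).
#' @param indices index columns to summarise.
#' @param posthoc_index index used for the ANOVA/Duncan comparison
#'   (subject-level means across repeats).
#' @param alpha significance level for the post hoc test.
#' @return list with `summary` (data frame location x index of
#'   `mean`, `sd`, `cv_pct`) and `posthoc` (a `posthoc_result`).
#' @export
cohort_summary <- function(table,
                           indices = c("ocp_mmHg", "cfs_pad", "pdi_mm"),
                           posthoc_index = "pdi_mm", alpha = 0.05) {
  locs <- unique(table$location)
  rows <- list()
  for (loc in locs) {
    sub <- table[table$location == loc, ]
    for (ind in indices) {
      cv <- repeatability_cv(table, ind)[[loc]]
      rows[[length(rows) + 1]] <- data.frame(
        location = loc, index = ind,
        mean = mean(sub[[ind]]), sd = sd(sub[[ind]]), cv_pct = cv
      )
    }
  }
  groups <- lapply(locs, function(loc) {
    sub <- table[table$location == loc, ]
    vapply(split(sub[[posthoc_index]], sub$subject_id), mean, numeric(1))
  })
  names(groups) <- locs
  list(summary = do.call(rbind, rows),
       posthoc = duncan_posthoc(groups, alpha))
}
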