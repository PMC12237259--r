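#' T-maze choice index
#'
#' Difference between the fly counts in the two arms divided by their sum,
#' signed so that avoidance of the conditioned odor (CS+) is positive: 1
#' means complete learning (all flies avoided the CS+), 0 means a 50:50
#' distribution (no learning).
#'
#' @param n_avoid flies in the CS- arm (avoided the conditioned odor).
#' @param n_approach flies in the CS+ arm.
#' @return index in `[-1, 1]`.
#' @export
choice_index <- function(n_avoid, n_approach) {
  tot <- n_avoid + n_approach
  if (any(tot <= 0)) stop("at least one fly is required")
  (n_avoid - n_approach) / tot
}

#' Performance index from a reciprocal pair of runs
#'
#' Arithmetic mean of the two reciprocal choice indices (odor roles
#' swapped), so a fixed additive arm bias cancels.
#'
#' @param index_run1,index_run2 choice indices of the reciprocal runs.
#' @return performance index.
#' @export
performance_index <- function(index_run1, index_run2) {
  if (any(is.na(c(index_run1, index_run2)))) stop("both runs are required")
  (index_run1 + index_run2) / 2
}

#' Performance index straight from a counts table
#'
#' @param counts data.frame as from [make_tmaze_counts()] (columns
#'   `n_arm_cs_plus`, `n_arm_cs_minus`, two rows).
#' @return performance index.
#' @export
performance_index_from_counts <- function(counts) {
  stopifnot(nrow(counts) == 2)
  ci <- choice_index(counts$n_arm_cs_minus, counts$n_arm_cs_plus)
  performance_index(ci[1], ci[2])
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness and kurtosis z-scores into
#' `K2 = Zg1^2 + Zg2^2`, referred to a chi-squared distribution with 2
#' degrees of freedom. Requires `n >= 8` for the kurtosis approximation.
#'
#' @param values numeric sample.
#' @return list `K2`, `p_value`, `n`, `z_skewness`, `z_kurtosis`.
#' @export
dagostino_pearson <- function(values) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson omnibus test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2
  # skewness z (D'Agostino 1970)
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  z1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  # kurtosis z (Anscombe & Glynn 1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - Eb2) / sqrt(Vb2)
  beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
  z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  K2 <- z1^2 + z2^2
  list(K2 = K2, p_value = 1 - pchisq(K2, df = 2), n = n,
       z_skewness = z1, z_kurtosis = z2)
}

#' Statistical decision tree for group comparisons
#'
#' Every group is screened with the D'Agostino-Pearson omnibus test; the
#' data count as normal only if all groups pass at `alpha`. Two normal
#' groups: unpaired two-tailed t test. More than two normal groups: one-way
#' ANOVA with Tukey's post-hoc test. Two non-normal groups: Mann-Whitney U
#' test. More than two non-normal groups: Kruskal-Wallis (fallback route).
#' Groups too small for the normality test (`n < 8`) route to the
#' nonparametric branch.
#'
#' @param groups named list of numeric vectors (>= 2 groups, none empty).
#' @param alpha normality significance level (default 0.05).
#' @param var_equal logical passed to [t.test()] (classic unpaired t test).
#' @return list of class `stat_report`: `test_name`, `statistic`, `p_value`,
#'   `n_per_group`, `normality_p`, `normal`, and `posthoc` (Tukey table,
#'   when applicable).
#' @export
choose_and_run_test <- function(groups, alpha = 0.05, var_equal = TRUE) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(!vapply(groups, length, 1L))) stop("empty group")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  norm_p <- vapply(groups, function(g) {
    if (length(g) < 8) return(NA_real_)
    dagostino_pearson(g)$p_value
  }, numeric(1))
  normal <- all(!is.na(norm_p)) && all(norm_p > alpha)
  k <- length(groups)
  posthoc <- NULL
  if (normal && k == 2) {
    tt <- t.test(groups[[1]], groups[[2]], var.equal = var_equal)
    res <- list("unpaired t test", unname(tt$statistic), tt$p.value)
  } else if (normal && k > 2) {
    df <- data.frame(value = unlist(groups),
                     group = factor(rep(names(groups),
                                        vapply(groups, length, 1L))))
    fit <- aov(value ~ group, data = df)
    an <- summary(fit)[[1]]
    posthoc <- TukeyHSD(fit)$group
    res <- list("one-way ANOVA + Tukey HSD", an[["F value"]][1],
                an[["Pr(>F)"]][1])
  } else if (!normal && k == 2) {
    wt <- wilcox.test(groups[[1]], groups[[2]], exact = FALSE)
    res <- list("Mann-Whitney U test", unname(wt$statistic), wt$p.value)
  } else {
    kw <- kruskal.test(groups)
    res <- list("Kruskal-Wallis", unname(kw$statistic), kw$p.value)
  }
  structure(list(test_name = res[[1]], statistic = res[[2]],
                 p_value = res[[3]],
                 n_per_group = vapply(groups, length, 1L),
                 normality_p = norm_p, normal = normal, posthoc = posthoc),
            class = "stat_report")
}

#' Iterated two-sided Grubbs outlier screening
#'
#' Repeatedly applies the single-outlier two-sided Grubbs test at `alpha`,
#' removing at most one point per iteration (the most extreme), until no
#' point is significant. The critical value is the classic
#' `((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` with
#' `t = qt(1 - alpha/(2n), n - 2)`.
#'
#' @param values numeric sample with `n >= 3`.
#' @param alpha significance level (default 0.05).
#' @return list `clean` (retained values) and `removed` (outliers, in
#'   removal order).
#' @export
grubbs_outliers <- function(values, alpha = 0.05) {
  x <- values
  if (length(x) < 3) stop("Grubbs test requires n >= 3")
  removed <- numeric(0)
  repeat {
    n <- length(x)
    if (n < 3) break
    s <- sd(x)
    if (s == 0) break
    dev <- abs(x - mean(x))
    G <- max(dev) / s
    tcrit <- qt(1 - alpha / (2 * n), n - 2)
    Gcrit <- (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
    if (G > Gcrit) {
      i <- which.max(dev)
      removed <- c(removed, x[i])
      x <- x[-i]
    } else break
  }
  list(clean = x, removed = removed)
}
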