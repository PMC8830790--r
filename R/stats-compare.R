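#' D'Agostino-Pearson omnibus normality test
#'
#' Combines transformed skewness and kurtosis z-scores into the omnibus
#' statistic K2 = Z(g1)^2 + Z(b2)^2, referred to a chi-squared distribution
#' with 2 degrees of freedom. This is the default normality test of common
#' figure-statistics software. Requires n >= 8 (the kurtosis
#' transformation is unstable below that); use [shapiro_fallback()] /
#' [normality_check()] for smaller samples.
#'
#' @param x Numeric vector, n >= 8, nonzero variance.
#' @return A list: `statistic` (K2), `p_value`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson test requires n >= 8", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero-variance sample", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)

  # skewness: D'Agostino (1970) transformation of g1 to normality
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z_skew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis: Anscombe & Glynn (1983) transformation of b2
  b2 <- m4 / m2^2
  e_b2 <- 3 * (n - 1) / (n + 1)
  var_b2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - e_b2) / sqrt(var_b2)
  sqrt_b1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrt_b1 * (2 / sqrt_b1 + sqrt(1 + 4 / sqrt_b1^2))
  z_kurt <- ((1 - 2 / (9 * a)) -
               ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z_skew^2 + z_kurt^2
  list(statistic = k2, p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z_skew, z_kurt = z_kurt, n = n)
}

# Shapiro-Wilk used below n = 8 where the omnibus test is unreliable.
shapiro_fallback <- function(x) {
  sw <- stats::shapiro.test(x)
  list(statistic = unname(sw$statistic), p_value = sw$p.value,
       n = length(x))
}

#' Joint normality check across sample groups
#'
#' Tests each group for normality and returns `TRUE` only if every group
#' passes at `alpha` (one failing group sends the downstream comparison to
#' its nonparametric branch). Groups with n >= 8 use the
#' D'Agostino-Pearson omnibus test; smaller groups use Shapiro-Wilk.
#' Constant (zero-variance) groups are treated as failing. With
#' `scope = "pooled"` the residuals of all groups about their group means
#' are tested as one sample instead.
#'
#' @param groups A list of numeric vectors (each n >= 3), or a single
#'   numeric vector.
#' @param alpha Significance level for rejecting normality (default 0.05).
#' @param scope `"per_group"` (default) or `"pooled"`.
#' @return Logical; attributes `tests` (per-group tibble) and `scope`.
#' @export
normality_check <- function(groups, alpha = 0.05,
                            scope = c("per_group", "pooled")) {
  scope <- match.arg(scope)
  if (is.numeric(groups)) groups <- list(groups)
  for (g in groups) {
    if (length(g) < 3) stop("each group needs n >= 3 for a normality test",
                            call. = FALSE)
    if (any(!is.finite(g))) stop("groups must contain finite values",
                                 call. = FALSE)
  }
  run_one <- function(x) {
    if (stats::sd(x) == 0) {
      return(tibble::tibble(test = "degenerate", statistic = NA_real_,
                            p_value = 0, n = length(x), normal = FALSE))
    }
    res <- if (length(x) >= 8) c(dagostino_pearson(x), test = "dagostino_pearson")
    else c(shapiro_fallback(x), test = "shapiro_wilk")
    tibble::tibble(test = res$test, statistic = res$statistic,
                   p_value = res$p_value, n = length(x),
                   normal = res$p_value >= alpha)
  }
  tests <- if (scope == "pooled") {
    run_one(unlist(lapply(groups, function(g) g - mean(g))))
  } else {
    dplyr::bind_rows(lapply(groups, run_one))
  }
  structure(all(tests$normal), tests = tests, scope = scope)
}

#' Significance stars for a p-value
#'
#' Standard figure-legend star annotation with strict thresholds:
#' `"****"` p < 0.0001, `"***"` p < 0.001, `"**"` p < 0.01, `"*"` p < 0.05,
#' `"ns"` otherwise.
#'
#' @param p P-value(s) in \[0, 1\].
#' @return Character vector of stars.
#' @export
#' @examples
#' star_annotation(c(0.02, 0.05, 5e-5))  # "*", "ns", "****"
star_annotation <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  vapply(p, function(pi) {
    if (pi < 0.0001) "****"
    else if (pi < 0.001) "***"
    else if (pi < 0.01) "**"
    else if (pi < 0.05) "*"
    else "ns"
  }, character(1))
}

#' Two-group comparison with normality branching
#'
#' The two-group arm of the figure-statistics procedure: if both samples
#' pass the normality check, a two-tailed unpaired Student's t-test;
#' otherwise a two-tailed Mann-Whitney (Wilcoxon rank-sum) test.
#'
#' @param a,b Numeric vectors (each n >= 3).
#' @param alpha_normality Level for the normality pre-test.
#' @param scope Normality scope, see [normality_check()].
#' @return One-row tibble: `comparison`, `test`, `branch`, `statistic`,
#'   `p`, `adjusted`, `stars`.
#' @export
compare_two <- function(a, b, alpha_normality = 0.05,
                        scope = "per_group") {
  for (g in list(a, b)) {
    if (length(g) < 3) stop("each group needs n >= 3", call. = FALSE)
    if (any(!is.finite(g))) stop("groups must be finite", call. = FALSE)
  }
  if (stats::sd(c(a, b)) == 0) {
    stop("degenerate comparison: all values identical", call. = FALSE)
  }
  normal <- isTRUE(normality_check(list(a, b), alpha = alpha_normality,
                                   scope = scope))
  if (normal) {
    ht <- stats::t.test(a, b, var.equal = TRUE, alternative = "two.sided")
    test <- "unpaired t-test"
    branch <- "parametric"
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided"))
    test <- "Mann-Whitney"
    branch <- "nonparametric"
  }
  tibble::tibble(
    comparison = "a vs b", test = test, branch = branch,
    statistic = unname(ht$statistic), p = ht$p.value, adjusted = FALSE,
    stars = star_annotation(ht$p.value)
  )
}

# Dunn's post-hoc z test vs control on Kruskal-Wallis ranks, with tie
# correction; two-sided p, Bonferroni family-wise adjustment over the
# vs-control comparisons.
dunn_vs_control <- function(values, group, control_label) {
  n_tot <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  labs <- unique(group)
  mean_rank <- vapply(labs, function(l) mean(r[group == l]), numeric(1))
  n_g <- vapply(labs, function(l) sum(group == l), numeric(1))
  names(mean_rank) <- names(n_g) <- labs
  others <- setdiff(labs, control_label)
  z <- vapply(others, function(l) {
    se <- sqrt((n_tot * (n_tot + 1) / 12 - tie_term) *
                 (1 / n_g[[l]] + 1 / n_g[[control_label]]))
    (mean_rank[[l]] - mean_rank[[control_label]]) / se
  }, numeric(1))
  p_raw <- 2 * stats::pnorm(-abs(z))
  tibble::tibble(comparison = paste(others, "vs", control_label),
                 statistic = unname(z),
                 p = pmin(1, p_raw * length(others)))
}

#' Many-vs-control comparison with normality branching
#'
#' The multi-group arm of the figure-statistics procedure: if every group
#' passes the normality check, one-way ANOVA followed by Dunnett's multiple
#' comparisons test against the control; otherwise Kruskal-Wallis followed
#' by Dunn's multiple comparisons test against the control. All reported
#' p-values are adjusted for the family of vs-control comparisons.
#'
#' @param groups Named list of numeric vectors (>= 3 groups), or a data
#'   frame with columns `group` and `value`.
#' @param control_label Name of the control group (exactly one).
#' @param alpha_normality Level for the normality pre-test.
#' @param scope Normality scope, see [normality_check()].
#' @return Tibble, one row per non-control group: `comparison`, `test`,
#'   `branch`, `statistic`, `p` (adjusted), `adjusted`, `stars`.
#' @export
compare_many_vs_control <- function(groups, control_label,
                                    alpha_normality = 0.05,
                                    scope = "per_group") {
  if (is.data.frame(groups)) {
    stopifnot(all(c("group", "value") %in% names(groups)))
    groups <- split(groups$value, groups$group)
  }
  if (length(groups) < 3) {
    stop("need at least 3 groups for a many-vs-control comparison",
         call. = FALSE)
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("groups must be named", call. = FALSE)
  }
  if (sum(names(groups) == control_label) != 1) {
    stop("exactly one group must match the control label '",
         control_label, "'", call. = FALSE)
  }
  for (g in groups) {
    if (length(g) < 3) stop("each group needs n >= 3", call. = FALSE)
  }
  normal <- isTRUE(normality_check(groups, alpha = alpha_normality,
                                   scope = scope))
  values <- unlist(groups, use.names = FALSE)
  group <- rep(names(groups), lengths(groups))
  if (normal) {
    # Dunnett's test: control must be the reference (first) factor level.
    dat <- data.frame(value = values,
                      group = stats::relevel(factor(group),
                                             ref = control_label))
    fit <- stats::aov(value ~ group, data = dat)
    glht_fit <- multcomp::glht(fit,
                               linfct = multcomp::mcp(group = "Dunnett"))
    # mvtnorm's adjusted p-values are quasi-Monte-Carlo; fix the stream
    # locally so results are reproducible, then restore it.
    rng_state <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(rng_state))
        assign(".Random.seed", rng_state, envir = globalenv())
    }, add = TRUE)
    set.seed(20200524L)
    sm <- summary(glht_fit)
    res <- tibble::tibble(
      comparison = names(sm$test$coefficients),
      statistic = unname(sm$test$tstat),
      # quasi-Monte-Carlo p-values can stray marginally outside [0, 1]
      p = pmin(1, pmax(0, unname(as.numeric(sm$test$pvalues))))
    )
    res$comparison <- sub(" - ", " vs ", res$comparison)
    test <- "one-way ANOVA + Dunnett"
    branch <- "parametric"
  } else {
    res <- dunn_vs_control(values, group, control_label)
    test <- "Kruskal-Wallis + Dunn"
    branch <- "nonparametric"
  }
  tibble::tibble(
    comparison = res$comparison, test = test, branch = branch,
    statistic = res$statistic, p = res$p, adjusted = TRUE,
    stars = star_annotation(res$p)
  )
}
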