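#' Group-study container
#'
#' Bundles per-group penetration (or thickness) measurements with the
#' per-group counts of delaminated specimens and complete-penetration
#' specimens, for the statistical workflow.
#'
#' @param groups Named list of numeric vectors, one per specimen group.
#' @param delaminated_counts,complete_penetration_counts Optional named
#'   integer vectors (default 0 per group).
#' @return An object of class `group_study`.
#' @examples
#' gs <- group_study(list(printed = c(1, 2, 3), milled = c(4, 5, 6)))
#' @export
group_study <- function(groups, delaminated_counts = NULL,
                        complete_penetration_counts = NULL) {
  if (!is.list(groups) || length(groups) < 1L)
    stop("groups must be a non-empty named list of numeric vectors")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("every group must be named")
  if (any(!vapply(groups, is.numeric, logical(1))) ||
      any(vapply(groups, length, integer(1)) < 1L))
    stop("every group must be a numeric vector with at least one value")
  fill <- function(x) {
    out <- stats::setNames(rep(0L, length(groups)), names(groups))
    if (!is.null(x)) out[names(x)] <- as.integer(x)
    if (any(out < 0)) stop("counts must be non-negative")
    out
  }
  structure(list(groups = lapply(groups, as.numeric),
                 delaminated_counts = fill(delaminated_counts),
                 complete_penetration_counts = fill(complete_penetration_counts)),
            class = "group_study")
}

#' @export
print.group_study <- function(x, ...) {
  cat(sprintf("<group_study: %d groups (%s), n = %s>\n",
              length(x$groups), paste(names(x$groups), collapse = ", "),
              paste(vapply(x$groups, length, integer(1)), collapse = "/")))
  invisible(x)
}

#' A-priori sample size for a one-way fixed-effects comparison
#'
#' Returns the smallest balanced total sample size N (divisible by `k`) for
#' which a one-way fixed-effects test of `k` group means, with effect size
#' expressed as Cohen's f, reaches the target power at significance level
#' `alpha`. Power is computed from the noncentral F distribution with
#' noncentrality \eqn{\lambda = f^2 N} and degrees of freedom
#' \eqn{(k - 1, N - k)}.
#'
#' @param effect_size_f Cohen's f (> 0).
#' @param alpha Significance level in (0, 1).
#' @param power Target power in (0, 1).
#' @param k Number of groups (>= 2).
#' @return Total sample size N (integer, divisible by `k`).
#' @examples
#' sample_size_oneway(0.5, 0.05, 0.8, 3)  # 42
#' @export
sample_size_oneway <- function(effect_size_f, alpha = 0.05, power = 0.8, k) {
  stopifnot(effect_size_f > 0, alpha > 0, alpha < 1, power > 0, power < 1,
            k >= 2)
  N <- 2L * as.integer(k)                  # smallest balanced N with N - k >= k
  repeat {
    achieved <- oneway_power(N, effect_size_f, k, alpha)
    if (achieved >= power) return(N)
    N <- N + as.integer(k)
    if (N > 1e6) stop("target power not reachable within N <= 1e6")
  }
}

# Power of the one-way fixed-effects F test at total N.
oneway_power <- function(N, f, k, alpha) {
  df1 <- k - 1
  df2 <- N - k
  if (df2 < 1) return(0)
  crit <- stats::qf(1 - alpha, df1, df2)
  1 - stats::pf(crit, df1, df2, ncp = f^2 * N)
}

#' Shapiro-Wilk normality gate
#'
#' Tests each group for normality and flags whether the study should take
#' the nonparametric path: the flag is `TRUE` iff any group's Shapiro-Wilk
#' p-value falls below `alpha`. A zero-variance group (realistic for
#' cap-saturated microleakage data) cannot be tested and is treated as
#' non-normal with a warning; its p-value is reported as `NA`.
#'
#' @param study A [group_study()]; every group must have at least 3 values.
#' @param alpha Gate level (default 0.05).
#' @return A list with `p_values` (named per group) and `nonparametric`
#'   (logical flag).
#' @export
shapiro_gate <- function(study, alpha = 0.05) {
  stopifnot(inherits(study, "group_study"), alpha > 0, alpha < 1)
  sizes <- vapply(study$groups, length, integer(1))
  if (any(sizes < 3L))
    stop("Shapiro-Wilk requires at least 3 values per group")
  p <- vapply(study$groups, function(g) {
    if (stats::var(g) == 0) {
      warning("zero-variance group treated as non-normal", call. = FALSE)
      return(NA_real_)
    }
    stats::shapiro.test(g)$p.value
  }, numeric(1))
  list(p_values = p,
       nonparametric = any(is.na(p) | p < alpha))
}

#' Kruskal-Wallis omnibus test on a group study
#'
#' Rank-based omnibus comparison of all groups: H is computed on midranks
#' with the tie correction, and the p-value comes from the chi-square
#' approximation with k - 1 degrees of freedom. When every observation in
#' the study is identical the test is degenerate and H = 0, p = 1 is
#' returned.
#'
#' @param study A [group_study()] with at least 2 groups and total N >= 5.
#' @return A list with `statistic` (H), `df` and `p_value`.
#' @examples
#' kruskal_wallis(group_study(list(a = 1:3, b = 4:6, c = 7:9)))$statistic
#' @export
kruskal_wallis <- function(study) {
  stopifnot(inherits(study, "group_study"))
  if (length(study$groups) < 2L) stop("need at least 2 groups")
  values <- unlist(study$groups, use.names = FALSE)
  if (length(values) < 5L) stop("need total N >= 5")
  if (length(unique(values)) == 1L)
    return(list(statistic = 0, df = length(study$groups) - 1L, p_value = 1))
  kt <- stats::kruskal.test(study$groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Dunn pairwise comparisons with Bonferroni correction
#'
#' Post-hoc pairwise z-tests on the joint midranks (Dunn's test) with the
#' standard tie correction, following a Kruskal-Wallis omnibus test. Raw
#' two-sided p-values are multiplied by the number of pairs
#' \eqn{k(k-1)/2} and clipped at 1.
#'
#' @param study A [group_study()] with at least 2 groups.
#' @return A data frame with one row per group pair: `group1`, `group2`,
#'   `z`, `p_raw`, `p_adjusted`.
#' @export
dunn_bonferroni <- function(study) {
  stopifnot(inherits(study, "group_study"))
  k <- length(study$groups)
  if (k < 2L) stop("need at least 2 groups")
  values <- unlist(study$groups, use.names = FALSE)
  gsize <- vapply(study$groups, length, integer(1))
  N <- length(values)
  rk <- rank(values)                       # midranks
  grp <- rep(names(study$groups), gsize)
  rbar <- tapply(rk, factor(grp, levels = names(study$groups)), mean)

  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  var0 <- N * (N + 1) / 12 - tie_term

  pairs <- utils::combn(names(study$groups), 2L)
  n_pairs <- ncol(pairs)
  z <- numeric(n_pairs)
  for (j in seq_len(n_pairs)) {
    g1 <- pairs[1L, j]; g2 <- pairs[2L, j]
    se <- sqrt(var0 * (1 / gsize[[g1]] + 1 / gsize[[g2]]))
    z[j] <- if (se == 0) 0 else (rbar[[g1]] - rbar[[g2]]) / se
  }
  p_raw <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
             z = z, p_raw = p_raw,
             p_adjusted = pmin(1, p_raw * n_pairs),
             row.names = NULL)
}

#' Per-group summaries
#'
#' Mean, sample standard deviation (n - 1 denominator) and size per group,
#' alongside the delamination and complete-penetration counts carried by
#' the study.
#'
#' @param study A [group_study()].
#' @return A data frame with one row per group: `group`, `n`, `mean`, `sd`,
#'   `delaminated`, `complete_penetration`.
#' @export
summarize_groups <- function(study) {
  stopifnot(inherits(study, "group_study"))
  data.frame(
    group = names(study$groups),
    n = vapply(study$groups, length, integer(1)),
    mean = vapply(study$groups, mean, numeric(1)),
    sd = vapply(study$groups, function(g)
      if (length(g) > 1L) stats::sd(g) else NA_real_, numeric(1)),
    delaminated = as.integer(study$delaminated_counts),
    complete_penetration = as.integer(study$complete_penetration_counts),
    row.names = NULL)
}

#' Full statistical report for a study
#'
#' Runs the complete inferential workflow on a [group_study()]: Shapiro-Wilk
#' gate, Kruskal-Wallis omnibus test, Dunn-Bonferroni pairwise comparisons
#' and per-group summaries.
#'
#' @param study A [group_study()] with >= 2 groups.
#' @param alpha Significance level for the normality gate.
#' @return A list of class `test_report` with elements `shapiro_p`,
#'   `nonparametric`, `omnibus` (H, df, p), `pairwise` (data frame) and
#'   `summary` (data frame).
#' @export
study_report <- function(study, alpha = 0.05) {
  gate <- shapiro_gate(study, alpha = alpha)
  omni <- kruskal_wallis(study)
  structure(
    list(shapiro_p = gate$p_values,
         nonparametric = gate$nonparametric,
         omnibus = omni,
         pairwise = dunn_bonferroni(study),
         summary = summarize_groups(study)),
    class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("<test_report: H = %.4g (df %d), p = %.4g; %d pairwise comparisons>\n",
              x$omnibus$statistic, x$omnibus$df, x$omnibus$p_value,
              nrow(x$pairwise)))
  invisible(x)
}
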