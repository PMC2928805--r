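# Group summaries and hypothesis tests for metric tables:
# mean +/- s.e.m., unpaired two-tailed t-test, one-way ANOVA, Dunnett's
# multiple comparison (Monte-Carlo adjusted p).

as_group_table <- function(table) {
  stopifnot(is.data.frame(table), all(c("group", "value") %in% names(table)))
  table <- table[is.finite(table$value), , drop = FALSE]
  table$group <- as.character(table$group)
  table
}

#' Per-group n, mean and s.e.m.
#'
#' The s.e.m. is the sample standard deviation (n - 1 denominator) divided by
#' the square root of n; it is `NA` for groups of one observation.
#'
#' @param table Long-format data frame with columns `group` and `value`
#'   (an optional `id` column is carried along by convention).
#' @return Data frame `group`, `n`, `mean`, `sd`, `sem`.
#' @examples
#' group_summary(data.frame(group = "a", value = c(2, 4, 6)))  # sem = 2/sqrt(3)
#' @export
group_summary <- function(table) {
  table <- as_group_table(table)
  groups <- unique(table$group)
  out <- lapply(groups, function(g) {
    v <- table$value[table$group == g]
    n <- length(v)
    s <- if (n >= 2) stats::sd(v) else NA_real_
    data.frame(group = g, n = n, mean = mean(v), sd = s,
               sem = if (n >= 2) s / sqrt(n) else NA_real_)
  })
  do.call(rbind, out)
}

sig_marker <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Unpaired two-tailed t-test
#'
#' Welch's unequal-variance t-test by default (it coincides with the pooled
#' test for equal group sizes and variances, and is the safer default);
#' `var_equal = TRUE` selects the classic pooled test. When both groups have
#' zero variance and equal means the statistic is undefined; the test then
#' reports t = 0, p = 1 with a flag.
#'
#' @param a,b Numeric vectors of the two groups (each n >= 2).
#' @param var_equal Use the pooled-variance test (default `FALSE` = Welch).
#' @return A `comparison_result` data frame with one row: `group_a`,
#'   `group_b`, `statistic`, `df`, `p`, `significance`, `flag`.
#' @export
t_test_unpaired <- function(a, b, var_equal = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 observations", call. = FALSE)
  flag <- ""
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      tt <- list(statistic = c(t = 0), parameter = c(df = length(a) + length(b) - 2),
                 p.value = 1)
      flag <- "zero_variance"
    } else {
      tt <- list(statistic = c(t = sign(mean(a) - mean(b)) * Inf),
                 parameter = c(df = length(a) + length(b) - 2), p.value = 0)
      flag <- "zero_variance"
    }
  } else {
    tt <- stats::t.test(a, b, var.equal = var_equal, alternative = "two.sided")
  }
  structure(data.frame(group_a = "a", group_b = "b",
                       statistic = unname(tt$statistic), df = unname(tt$parameter),
                       p = tt$p.value, significance = sig_marker(tt$p.value),
                       flag = flag),
            class = c("comparison_result", "data.frame"),
            test = if (var_equal) "pooled t-test (two-tailed)" else "Welch t-test (two-tailed)")
}

#' One-way ANOVA
#'
#' Standard between/within sum-of-squares decomposition via `anova(lm())`.
#'
#' @param table Long-format data frame with `group` and `value`.
#' @return List `F`, `df_between`, `df_within`, `p`.
#' @examples
#' d <- data.frame(group = rep(c("a", "b", "c"), each = 3),
#'                 value = c(1, 2, 3, 2, 3, 4, 3, 4, 5))
#' one_way_anova(d)$F  # 3
#' @export
one_way_anova <- function(table) {
  table <- as_group_table(table)
  k <- length(unique(table$group))
  if (k < 2) stop("need >= 2 groups", call. = FALSE)
  if (nrow(table) <= k) stop("within-group degrees of freedom are zero", call. = FALSE)
  a <- stats::anova(stats::lm(value ~ factor(group), data = table))
  list(F = a[1, "F value"], df_between = a[1, "Df"], df_within = a[2, "Df"],
       p = a[1, "Pr(>F)"])
}

#' Dunnett's multiple comparison against a control
#'
#' Each treatment group is compared with the control using the pooled-error t
#' statistic (pooled across all groups, df = N - k). Familywise-adjusted
#' p-values come from the joint null distribution of the maximum absolute
#' statistic over the family, obtained by seeded Monte Carlo: group means are
#' drawn as independent normals scaled by 1/sqrt(n), the pooled sd as
#' sqrt(chi-squared_df / df), giving draws of the correlated t-vector whose
#' max-|T| tail probability at each observed statistic is the adjusted p.
#' Adjusted p-values are additionally floored at the raw p (the familywise
#' p can never be smaller; the floor removes Monte-Carlo jitter in the
#' single-comparison case).
#'
#' @param table Long-format data frame with `group` and `value`.
#' @param control Name of the control group (n >= 2 required).
#' @param alpha Familywise significance level used for the `significant`
#'   column (default 0.05).
#' @param n_mc Number of Monte-Carlo draws (default 1e5).
#' @param seed Seed for the Monte-Carlo draws (default 1; the draw stream is
#'   private and does not disturb the caller's RNG).
#' @return A `comparison_result` data frame: one row per treatment group with
#'   `statistic`, `df`, `p` (raw, two-sided), `p_adjusted`, `significant`,
#'   `significance` markers at 0.05/0.01/0.001.
#' @export
dunnett <- function(table, control, alpha = 0.05, n_mc = 1e5, seed = 1L) {
  table <- as_group_table(table)
  groups <- unique(table$group)
  if (!control %in% groups) stop(sprintf("control group '%s' not in table", control), call. = FALSE)
  treats <- setdiff(groups, control)
  if (length(treats) < 1) stop("need at least one treatment group", call. = FALSE)
  vals <- split(table$value, table$group)
  n <- vapply(vals, length, integer(1))
  if (n[[control]] < 2) stop("control group needs >= 2 observations", call. = FALSE)
  if (any(n < 1)) stop("empty group", call. = FALSE)
  N <- sum(n); k <- length(groups)
  df <- N - k
  if (df < 1) stop("no residual degrees of freedom", call. = FALSE)
  ss <- sum(vapply(vals, function(v) sum((v - mean(v))^2), numeric(1)))
  s2 <- ss / df
  m0 <- mean(vals[[control]]); n0 <- n[[control]]
  tstat <- vapply(treats, function(g) {
    (mean(vals[[g]]) - m0) / sqrt(s2 * (1 / n[[g]] + 1 / n0))
  }, numeric(1))
  p_raw <- 2 * stats::pt(-abs(tstat), df)

  # Monte-Carlo null of the max-|T| statistic for this design
  nt <- n[treats]
  maxT <- with_seed(seed, {
    z0 <- stats::rnorm(n_mc, 0, sqrt(1 / n0))
    s_mc <- sqrt(stats::rchisq(n_mc, df) / df)
    mx <- rep(0, n_mc)
    for (j in seq_along(treats)) {
      zj <- stats::rnorm(n_mc, 0, sqrt(1 / nt[j]))
      Tj <- abs(zj - z0) / (s_mc * sqrt(1 / nt[j] + 1 / n0))
      mx <- pmax(mx, Tj)
    }
    mx
  })
  p_adj <- vapply(abs(tstat), function(t0) mean(maxT >= t0), numeric(1))
  p_adj <- pmax(p_adj, p_raw)

  structure(data.frame(group = treats, control = control,
                       statistic = tstat, df = df,
                       p = p_raw, p_adjusted = p_adj,
                       significant = p_adj < alpha,
                       significance = sig_marker(p_adj),
                       row.names = NULL),
            class = c("comparison_result", "data.frame"),
            test = sprintf("Dunnett (Monte Carlo, %d draws)", as.integer(n_mc)),
            alpha = alpha)
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s\n", attr(x, "test") %||% "comparison"))
  print.data.frame(x, digits = 4)
  invisible(x)
}
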