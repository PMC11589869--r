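# Group comparison workflow: normality gate, omnibus test, post hoc pairs.

sig_tier <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
    ifelse(p < 0.05, "*", "ns")))
}

# internal: one-sample KS normality check on standardized values.
# Lilliefors-style caveat: parameters are estimated from the sample, which
# makes the test conservative; adequate as a branch gate.
ks_normality_p <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(0)   # degenerate: treat as non-normal
  z <- (x - mean(x)) / s
  suppressWarnings(stats::ks.test(z, "pnorm")$p.value)
}

# internal: Dunn's post hoc test (rank sums, tie-corrected z statistics)
dunn_test <- function(values, groups, adjust = "bonferroni") {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  z <- p <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    sigma <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[a] + 1 / ns[b]))
    if (!is.finite(sigma) || sigma <= 0) {   # all observations tied
      z[i] <- 0; p[i] <- 1
    } else {
      z[i] <- (rbar[a] - rbar[b]) / sigma
      p[i] <- 2 * stats::pnorm(-abs(z[i]))
    }
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
             p_adj = stats::p.adjust(p, method = adjust))
}

#' Compare a readout across experimental groups
#'
#' Reproduces the conventional secretion-statistics workflow: each group is
#' checked for normality (one-sample Kolmogorov-Smirnov test on
#' standardized values against the standard normal); if every group passes
#' at `alpha`, a one-way ANOVA with Tukey-Kramer post hoc comparisons is
#' run, otherwise Kruskal-Wallis with Dunn's post hoc test
#' (Bonferroni-adjusted by default). Pairwise significance is tiered as
#' `*` p<0.05, `**` p<0.01, `***` p<0.001.
#'
#' @param samples named list: one numeric vector of per-cell values per
#'   group (>= 3 observations each).
#' @param alpha significance level for the normality gate and tiers.
#' @param adjust multiplicity adjustment for Dunn's test (see
#'   [stats::p.adjust()]).
#' @param normality `"ks"` (default) or `"none"` to force the parametric
#'   branch.
#' @return Object of class `"group_comparison"`: per-group summaries,
#'   normality p-values, selected `branch`, omnibus test result and the
#'   pairwise table with adjusted p-values and tiers.
#' @examples
#' set.seed(1)
#' compare_groups(list(ko = rnorm(15, 200, 40), wt = rnorm(15, 420, 40)))
#' @export
compare_groups <- function(samples, alpha = 0.05, adjust = "bonferroni",
                           normality = c("ks", "none")) {
  normality <- match.arg(normality)
  if (!is.list(samples) || length(samples) < 2L || is.null(names(samples)))
    stop("samples must be a named list of at least 2 groups", call. = FALSE)
  ns <- vapply(samples, length, 0L)
  if (any(ns < 3L))
    stop("insufficient data: every group needs at least 3 observations",
         call. = FALSE)
  labels <- names(samples)
  values <- unlist(samples, use.names = FALSE)
  groups <- factor(rep(labels, ns), levels = labels)

  summaries <- data.frame(
    group = labels, n = as.integer(ns),
    mean = vapply(samples, mean, 0),
    sem = vapply(samples, function(x) stats::sd(x) / sqrt(length(x)), 0))

  normality_p <- vapply(samples, ks_normality_p, 0)
  zero_var <- vapply(samples, function(x) stats::sd(x) == 0, TRUE)
  branch <- if (normality == "none") "parametric" else
    if (any(normality_p < alpha)) "nonparametric" else "parametric"
  if (any(zero_var)) {
    warning("zero-variance group: using the nonparametric branch",
            call. = FALSE)
    branch <- "nonparametric"
  }

  if (branch == "parametric") {
    fit <- stats::aov(values ~ groups)
    a <- summary(fit)[[1]]
    omnibus <- list(test = "one-way ANOVA", statistic = a[["F value"]][1],
                    p = a[["Pr(>F)"]][1])
    tk <- stats::TukeyHSD(fit)$groups
    pr <- strsplit(rownames(tk), "-", fixed = TRUE)
    pairwise <- data.frame(group1 = vapply(pr, `[`, "", 2),
                           group2 = vapply(pr, `[`, "", 1),
                           estimate = tk[, "diff"], p_adj = tk[, "p adj"])
  } else {
    kw <- stats::kruskal.test(values, groups)
    kp <- kw$p.value
    if (!is.finite(kp)) kp <- 1   # every observation tied
    omnibus <- list(test = "Kruskal-Wallis",
                    statistic = unname(kw$statistic), p = kp)
    pairwise <- dunn_test(values, groups, adjust = adjust)
  }
  pairwise$tier <- sig_tier(pairwise$p_adj)
  rownames(pairwise) <- NULL
  structure(list(groups = summaries, normality_p = normality_p,
                 branch = branch, omnibus = omnibus, pairwise = pairwise,
                 alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison (", x$branch, " branch)\n", sep = "")
  print(x$groups, row.names = FALSE, digits = 4)
  cat(sprintf("%s: statistic = %.3g, p = %.3g\n", x$omnibus$test,
              x$omnibus$statistic, x$omnibus$p))
  print(x$pairwise, row.names = FALSE, digits = 3)
  invisible(x)
}
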