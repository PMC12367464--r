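#' Normality-gated statistical testing
#'
#' These functions implement a deterministic decision tree used
#' throughout the package's group comparisons: Shapiro-Wilk normality
#' checks (and Levene's variance-homogeneity check for k >= 3 groups)
#' decide between parametric and non-parametric branches. Shapiro-Wilk
#' and Levene are delegated to established routines
#' ([stats::shapiro.test()], [car::leveneTest()] with mean centering);
#' the contribution here is the gating logic, which is seed-free and
#' fully reproducible.
#'
#' @name stats_gate
NULL

# Shapiro-Wilk P, with constant input treated as a (flagged) gate failure
shapiro_p <- function(x) {
  if (length(unique(x)) == 1 || length(x) < 3 || length(x) > 5000)
    return(NA_real_)
  stats::shapiro.test(x)$p.value
}

#' Gated two-group comparison
#'
#' Shapiro-Wilk on each group; if both P > `normality_alpha` an
#' independent two-sample (Student) t-test is used, otherwise the
#' two-sided Mann-Whitney U test. A constant group fails the gate.
#'
#' @param x,y Numeric vectors, each of length >= 3.
#' @param normality_alpha Gate threshold on the Shapiro-Wilk P value
#'   (default 0.05).
#' @return An object of class `gate_decision`: list with `normality_p`
#'   (length-2), `chosen_test` (`"t_test"` or `"mann_whitney"`),
#'   `statistic`, `p_value`, and `posthoc = NULL`.
#' @examples
#' compare_two_groups(c(1, 2, 3, 4, 5), c(6, 7, 8, 9, 10))
#' @export
compare_two_groups <- function(x, y, normality_alpha = 0.05) {
  if (length(x) < 3 || length(y) < 3)
    sq_stop("each group needs n >= 3")
  sw <- c(x = shapiro_p(x), y = shapiro_p(y))
  normal <- !anyNA(sw) && all(sw > normality_alpha)
  if (normal) {
    ht <- stats::t.test(x, y, var.equal = TRUE)
    chosen <- "t_test"
    stat <- unname(ht$statistic); p <- ht$p.value
  } else {
    ht <- wilcoxon_rank_sum(x, y)
    chosen <- "mann_whitney"
    stat <- ht$U; p <- ht$p_value
  }
  structure(list(normality_p = sw, variance_homogeneity_p = NA_real_,
                 chosen_test = chosen,
                 statistic = stat, p_value = p,
                 posthoc = NULL),
            class = "gate_decision")
}

#' Gated k-group comparison (k >= 3)
#'
#' Shapiro-Wilk per group plus Levene's test (mean-centered) across
#' groups. When every gate passes, the parametric branch runs in the
#' requested flavor: classic one-way ANOVA with Tukey HSD
#' (`posthoc_family = "tukey"`) or Welch's ANOVA with Games-Howell
#' pairwise tests (`"games_howell"`, the default used for
#' method-comparison analyses). If any gate fails, the Kruskal-Wallis
#' test is used (no post hoc table).
#'
#' @param groups Named list of numeric vectors (k >= 3, each n >= 3).
#' @param posthoc_family `"games_howell"` (Welch branch) or `"tukey"`
#'   (classic branch).
#' @param normality_alpha Gate threshold (default 0.05), applied to both
#'   Shapiro-Wilk and Levene P values.
#' @return A `gate_decision` with `variance_homogeneity_p` filled in and,
#'   for parametric branches, a `posthoc` data frame of pairwise
#'   comparisons.
#' @export
compare_k_groups <- function(groups, posthoc_family = c("games_howell", "tukey"),
                             normality_alpha = 0.05) {
  posthoc_family <- match.arg(posthoc_family)
  if (length(groups) < 3)
    sq_stop("compare_k_groups needs k >= 3 groups (use compare_two_groups)")
  if (any(vapply(groups, length, 0L) < 3))
    sq_stop("each group needs n >= 3")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  sw <- vapply(groups, shapiro_p, 0)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 0L)))
  lev <- car::leveneTest(y, g, center = mean)
  lev_p <- lev[["Pr(>F)"]][1]
  pass <- !anyNA(sw) && all(sw > normality_alpha) && lev_p > normality_alpha
  posthoc <- NULL
  if (pass && posthoc_family == "tukey") {
    fit <- stats::aov(y ~ g)
    an <- summary(fit)[[1]]
    stat <- an[["F value"]][1]
    p <- an[["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$g
    posthoc <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                          p_value = tk[, "p adj"], row.names = NULL,
                          stringsAsFactors = FALSE)
    chosen <- "anova_tukey"
  } else if (pass) {
    wt <- stats::oneway.test(y ~ g, var.equal = FALSE)
    stat <- unname(wt$statistic)
    p <- wt$p.value
    posthoc <- games_howell(groups)
    chosen <- "welch_anova_games_howell"
  } else {
    kw <- stats::kruskal.test(groups)
    stat <- unname(kw$statistic)
    p <- kw$p.value
    chosen <- "kruskal_wallis"
  }
  structure(list(normality_p = sw, variance_homogeneity_p = lev_p,
                 chosen_test = chosen, statistic = stat, p_value = p,
                 posthoc = posthoc),
            class = "gate_decision")
}

#' Games-Howell pairwise comparisons
#'
#' Pairwise tests for unequal variances and sizes: for groups i, j the
#' statistic is t = (m_i - m_j) / sqrt(s_i^2/n_i + s_j^2/n_j) with
#' Welch-Satterthwaite degrees of freedom, referred to the studentized
#' range distribution with k groups (q = |t| * sqrt(2)).
#'
#' @param groups Named list of numeric vectors.
#' @return A `data.frame`: `comparison`, `diff`, `se`, `t`, `df`,
#'   `p_value`.
#' @export
games_howell <- function(groups) {
  k <- length(groups)
  m <- vapply(groups, mean, 0)
  v <- vapply(groups, stats::var, 0)
  n <- vapply(groups, length, 0L)
  pairs <- utils::combn(k, 2)
  out <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se2 <- unname(v[i] / n[i] + v[j] / n[j])
    tstat <- unname(m[i] - m[j]) / sqrt(se2)
    df <- se2^2 / unname((v[i] / n[i])^2 / (n[i] - 1) +
                           (v[j] / n[j])^2 / (n[j] - 1))
    p <- stats::ptukey(abs(tstat) * sqrt(2), nmeans = k, df = df,
                       lower.tail = FALSE)
    c(diff = unname(m[i] - m[j]), se = sqrt(se2), t = tstat, df = df,
      p_value = p)
  })
  data.frame(comparison = apply(pairs, 2, function(ij)
               paste(names(groups)[ij[2]], names(groups)[ij[1]], sep = "-")),
             t(out), row.names = NULL, stringsAsFactors = FALSE)
}

#' Gated correlation
#'
#' Shapiro-Wilk on each variable; both P > `normality_alpha` selects
#' Pearson's correlation, otherwise Spearman's (two-sided P throughout).
#' A constant vector yields an undefined coefficient with a flag.
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @param normality_alpha Gate threshold (default 0.05).
#' @return List: `method` (`"pearson"`/`"spearman"`/`NA`), `estimate`,
#'   `p_value`, `normality_p`, `flag` (`"ok"` or `"constant_input"`).
#' @export
gated_correlation <- function(x, y, normality_alpha = 0.05) {
  if (length(x) != length(y)) sq_stop("x and y must be paired")
  if (length(x) < 3) sq_stop("need n >= 3 pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    return(list(method = NA_character_, estimate = NA_real_,
                p_value = NA_real_,
                normality_p = c(x = shapiro_p(x), y = shapiro_p(y)),
                flag = "constant_input"))
  sw <- c(x = shapiro_p(x), y = shapiro_p(y))
  method <- if (!anyNA(sw) && all(sw > normality_alpha)) "pearson"
            else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  list(method = method, estimate = unname(ct$estimate),
       p_value = ct$p.value, normality_p = sw, flag = "ok")
}

#' Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Two-sided rank-sum test built for small-sample exactness: when the
#' combined sample size is <= 10 and there are no ties, the permutation
#' distribution of U is enumerated exhaustively over all C(n, n1) rank
#' assignments; otherwise the normal approximation with tie and
#' continuity corrections is used.
#'
#' @param x,y Numeric vectors, each n >= 3.
#' @param exact_max Combined-size limit for exhaustive enumeration
#'   (default 10).
#' @return List: `U` (statistic for `x`), `p_value`, `method`
#'   (`"exact"`/`"normal_approx"`).
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))  # exact P = 0.1
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 10) {
  if (length(x) < 3 || length(y) < 3) sq_stop("each group needs n >= 3")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  comb <- c(x, y)
  r <- rank(comb)
  ties <- anyDuplicated(comb) > 0
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n <= exact_max && !ties) {
    sets <- utils::combn(n, n1)
    Us <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- 2 * min(mean(Us <= U), mean(Us >= U))
    return(list(U = U, p_value = min(1, p), method = "exact"))
  }
  mu <- n1 * n2 / 2
  tie_tab <- table(comb)
  sigma2 <- n1 * n2 / 12 * (n + 1 - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 == 0) return(list(U = U, p_value = 1, method = "normal_approx"))
  dev <- U - mu
  z <- (dev - sign(dev) * 0.5) / sqrt(sigma2)
  list(U = U, p_value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal_approx")
}

#' @export
print.gate_decision <- function(x, ...) {
  cat("gate_decision:", x$chosen_test, "\n")
  cat("  normality P:", paste(sprintf("%.4g", x$normality_p), collapse = ", "),
      "\n")
  if (!is.na(x$variance_homogeneity_p))
    cat("  Levene P:", sprintf("%.4g", x$variance_homogeneity_p), "\n")
  cat(sprintf("  statistic = %.6g, P = %.4g\n", x$statistic, x$p_value))
  if (!is.null(x$posthoc)) {
    cat("  post hoc:\n")
    print(x$posthoc, digits = 4)
  }
  invisible(x)
}
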