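#' Shannon diversity of one sample
#'
#' `-sum(p_i log p_i)` in nats over nonzero proportions (delegated to
#' [vegan::diversity()]). Invariant to any per-sample rescaling, so
#' relative and spike-in absolute bases give identical values.
#'
#' @param x Non-negative abundance vector with total > 0.
#' @return Shannon index in nats.
#' @examples
#' shannon(rep(25, 4))  # log(4)
#' @export
shannon <- function(x) {
  if (any(x < 0) || !any(x > 0)) sq_stop("need non-negative values, total > 0")
  unname(vegan::diversity(x, index = "shannon"))
}

#' Chao1 richness estimate of one sample
#'
#' Nonparametric richness from singleton (F1) and doubleton (F2) counts.
#' Bias-corrected form (default, defined for F2 = 0):
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`; classic form:
#' `S_obs + F1^2 / (2 F2)`. Requires raw integer read counts — scaled
#' (copies/g) values make singletons meaningless, so non-integer input is
#' an error.
#'
#' @param x Integer count vector.
#' @param bias_corrected Use the bias-corrected form (default `TRUE`).
#' @return Estimated richness (>= observed richness).
#' @export
chao1 <- function(x, bias_corrected = TRUE) {
  if (any(x < 0) || any(!is_whole(x)))
    sq_stop("Chao1 requires raw integer counts (not scaled abundances)")
  s_obs <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (bias_corrected) return(s_obs + f1 * (f1 - 1) / (2 * (f2 + 1)))
  if (f2 == 0) {
    if (f1 == 0) return(s_obs)
    sq_warn("no doubletons; classic Chao1 undefined, returning bias-corrected")
    return(s_obs + f1 * (f1 - 1) / 2)
  }
  s_obs + f1^2 / (2 * f2)
}

#' Alpha diversity table for a cohort
#'
#' Shannon and Chao1 per sample on spike-excluded raw reads. Spike rows
#' are always removed first: the calibrant is not part of the community.
#'
#' @param cm A [count_matrix()].
#' @param bias_corrected Passed to [chao1()].
#' @return `data.frame`: `sample_id`, `shannon`, `chao1`.
#' @export
alpha_diversity <- function(cm, bias_corrected = TRUE) {
  endo <- endogenous_counts(cm)
  data.frame(sample_id = colnames(endo),
             shannon = apply(endo, 2, shannon),
             chao1 = apply(endo, 2, chao1, bias_corrected = bias_corrected),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(u, v) = sum |u_i - v_i| / sum (u_i + v_i)` over taxa (delegated to
#' [vegan::vegdist()]). Applied to per-sample proportions for the
#' relative basis or copies/g for the absolute basis — the absolute basis
#' is deliberately not re-normalized, so load differences contribute to
#' dissimilarity.
#'
#' @param x Values matrix (taxa x samples) or object coercible as in
#'   [top_taxa()].
#' @return A `dist` object over samples.
#' @export
bray_curtis <- function(x) {
  mat <- as_value_matrix(x)
  if (any(mat < 0, na.rm = TRUE)) sq_stop("negative values in abundance matrix")
  zero <- colSums(mat, na.rm = TRUE) == 0
  if (sum(zero) >= 2)
    sq_stop("Bray-Curtis undefined between all-zero samples: ",
            paste(colnames(mat)[zero], collapse = ", "))
  vegan::vegdist(t(mat), method = "bray")
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centered Gram eigendecomposition of a distance matrix
#' (delegated to [stats::cmdscale()]). Axes are sorted by eigenvalue;
#' negative eigenvalues (non-Euclidean distances such as Bray-Curtis)
#' are reported and, by default, excluded from the explained-variance
#' denominator.
#'
#' @param d A `dist` or symmetric zero-diagonal matrix.
#' @param k Number of axes to return (default all positive ones).
#' @param exclude_negative Drop negative eigenvalues from the
#'   explained-variance denominator (default `TRUE`).
#' @return Object of class `pcoa_result`: `points` (samples x axes),
#'   `eig` (all eigenvalues), `explained` (proportion per returned axis).
#' @export
pcoa <- function(d, k = NULL, exclude_negative = TRUE) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d), tol = 1e-8))
      sq_stop("distance matrix must be symmetric")
    if (any(abs(diag(d)) > 1e-12))
      sq_stop("distance matrix must have a zero diagonal")
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  # k = n-1 requested; cmdscale warns when some of those axes are
  # degenerate, but the eigenvalues are screened below anyway
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- sum(eig > 1e-8 * max(abs(eig)))
  if (is.null(k)) k <- max(pos, 1)
  k <- min(k, ncol(fit$points))
  pts <- fit$points[, seq_len(k), drop = FALSE]
  colnames(pts) <- paste0("PC", seq_len(k))
  denom <- if (exclude_negative) sum(eig[eig > 0]) else sum(abs(eig))
  structure(list(points = pts, eig = eig,
                 explained = pmax(eig[seq_len(k)], 0) / denom),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("pcoa_result: %d samples, %d axes\n", nrow(x$points),
              ncol(x$points)))
  cat("  explained:", paste(sprintf("%.1f%%", 100 * x$explained),
                            collapse = ", "), "\n")
  if (any(x$eig < 0))
    cat(sprintf("  %d negative eigenvalue(s), min %.3g\n",
                sum(x$eig < 0), min(x$eig)))
  invisible(x)
}

#' PERMANOVA (permutational multivariate ANOVA) on a distance matrix
#'
#' Pseudo-F from among/within-group sums of squared distances
#' (Gower-centered partition) with a label-permutation P value:
#' `P = (1 + #(F_perm >= F_obs)) / (1 + n_perm)`. The permutation stream
#' is isolated under `seed` and does not disturb the caller's RNG.
#'
#' @param d A `dist` or symmetric zero-diagonal matrix.
#' @param groups Group labels, one per sample; >= 2 groups, each n >= 2.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Integer seed for the permutations (required for
#'   reproducibility in scripted runs; `NULL` uses the current RNG).
#' @return List: `pseudo_F`, `p_value`, `n_perm`, `df` (between, within),
#'   `permuted_F` (the permutation distribution).
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d), tol = 1e-8))
      sq_stop("distance matrix must be symmetric")
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  groups <- as.character(groups)
  if (length(groups) != n) sq_stop("one group label per sample required")
  tab <- table(groups)
  if (length(tab) < 2) sq_stop("need >= 2 groups")
  if (any(tab < 2)) sq_stop("every group needs n >= 2 samples")
  d2 <- as.matrix(d)^2
  k <- length(tab)
  f_stat <- function(g) {
    ss_total <- sum(d2[upper.tri(d2)]) / n
    ss_within <- 0
    for (lv in unique(g)) {
      idx <- which(g == lv)
      sub <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
    ss_among <- ss_total - ss_within
    (ss_among / (k - 1)) / (ss_within / (n - k))
  }
  f_obs <- f_stat(groups)
  perm_f <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) f_stat(sample(groups)), 0)
  })
  list(pseudo_F = f_obs,
       p_value = (1 + sum(perm_f >= f_obs)) / (1 + n_perm),
       n_perm = n_perm, df = c(between = k - 1, within = n - k),
       permuted_F = perm_f)
}
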