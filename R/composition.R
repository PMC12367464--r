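#' Per-sample relative abundance (spike-excluded proportions)
#'
#' @param cm A [count_matrix()].
#' @return Matrix of proportions (endogenous taxa x samples); columns
#'   sum to 1 (all-zero samples yield `NaN`).
#' @export
relative_abundance <- function(cm) {
  endo <- endogenous_counts(cm)
  sweep(endo, 2, colSums(endo), `/`)
}

# coerce a count_matrix / abs_abund / plain matrix to a value matrix
as_value_matrix <- function(x) {
  if (inherits(x, "count_matrix")) return(endogenous_counts(x))
  if (inherits(x, "abs_abund")) return(x$abundance)
  as.matrix(x)
}

#' Top-N taxa by summed abundance
#'
#' Ranks taxa by the sum of their values over the selected samples,
#' either pooled over the whole cohort or within one group. Ties are
#' broken deterministically: value descending, then taxon label
#' lexicographic.
#'
#' @param x A values matrix (taxa x samples), [count_matrix()] (uses
#'   endogenous reads) or [absolute_abundance()] fit (uses copies/g).
#' @param n Number of taxa to report (truncated with a warning if larger
#'   than the number of taxa).
#' @param scope `"pooled"` or a group label present in `groups`.
#' @param groups Character vector of group labels, one per sample
#'   (required when `scope` is a group label).
#' @return `data.frame`: `rank`, `taxon`, `value` (summed over the
#'   scope's samples), with attributes `scope`.
#' @export
top_taxa <- function(x, n = 10, scope = "pooled", groups = NULL) {
  mat <- as_value_matrix(x)
  if (!identical(scope, "pooled")) {
    if (is.null(groups)) sq_stop("groups required for per-group scope")
    if (length(groups) != ncol(mat))
      sq_stop("groups must have one label per sample")
    keep <- groups == scope
    if (!any(keep)) sq_stop("no samples in group '", scope, "'")
    mat <- mat[, keep, drop = FALSE]
  }
  tot <- rowSums(mat, na.rm = TRUE)
  ord <- order(-tot, names(tot))
  if (n > length(tot)) {
    sq_warn("n exceeds the number of taxa; truncating to ", length(tot))
    n <- length(tot)
  }
  out <- data.frame(rank = seq_len(n), taxon = names(tot)[ord][seq_len(n)],
                    value = unname(tot[ord])[seq_len(n)],
                    stringsAsFactors = FALSE)
  attr(out, "scope") <- scope
  out
}

#' Rank shifts between relative and absolute bases
#'
#' Compares the full taxon rankings under two bases (typically relative
#' proportions vs spike-in copies/g) and reports, for the union of both
#' top-N sets, each taxon's rank under both bases and whether it entered
#' or left the top N when moving from the relative to the absolute basis.
#'
#' @param relative,absolute Value matrices (or objects coercible via
#'   the same rules as [top_taxa()]) sharing taxa.
#' @param n Top-N cutoff (default 10).
#' @param scope,groups As in [top_taxa()].
#' @return `data.frame`: `taxon`, `rank_relative`, `rank_absolute`,
#'   `in_top_relative`, `in_top_absolute`, `entered`, `left`.
#' @export
rank_shift <- function(relative, absolute, n = 10, scope = "pooled",
                       groups = NULL) {
  rmat <- as_value_matrix(relative)
  amat <- as_value_matrix(absolute)
  common <- intersect(rownames(rmat), rownames(amat))
  if (!length(common)) sq_stop("no shared taxa between bases")
  full_rank <- function(mat) {
    r <- top_taxa(mat[common, , drop = FALSE], n = length(common),
                  scope = scope, groups = groups)
    stats::setNames(r$rank, r$taxon)
  }
  rr <- full_rank(rmat)
  ra <- full_rank(amat)
  keep <- union(names(rr)[rr <= n], names(ra)[ra <= n])
  keep <- keep[order(pmin(rr[keep], ra[keep]))]
  data.frame(taxon = keep,
             rank_relative = unname(rr[keep]),
             rank_absolute = unname(ra[keep]),
             in_top_relative = unname(rr[keep] <= n),
             in_top_absolute = unname(ra[keep] <= n),
             entered = unname(rr[keep] > n & ra[keep] <= n),
             left = unname(rr[keep] <= n & ra[keep] > n),
             stringsAsFactors = FALSE)
}

#' Per-taxon two-group differential abundance
#'
#' Runs the two-sided Wilcoxon rank-sum test ([wilcoxon_rank_sum()]) on
#' each taxon across two groups, on whatever basis the input matrix
#' carries (per-sample proportions for the relative basis, copies/g for
#' the absolute basis). P values are reported unadjusted with
#' significance stars at P < 0.05 / 0.01 / 0.001; Benjamini-Hochberg
#' adjusted values are added when `bh = TRUE`.
#'
#' @param x Values matrix / [count_matrix()] / [absolute_abundance()].
#'   For the relative basis pass `relative_abundance(cm)`.
#' @param groups Character vector, one label per sample; exactly two
#'   distinct labels, each with n >= 3 samples.
#' @param bh Add a BH-adjusted P column (default `FALSE`).
#' @return `data.frame`: `taxon`, `statistic` (U), `p_value`,
#'   `direction` (group with the higher median), `stars`, and optionally
#'   `p_bh`.
#' @export
diff_abundance <- function(x, groups, bh = FALSE) {
  mat <- as_value_matrix(x)
  groups <- as.character(groups)
  if (length(groups) != ncol(mat))
    sq_stop("groups must have one label per sample")
  lv <- unique(groups)
  if (length(lv) != 2) sq_stop("exactly two groups required")
  if (any(table(groups) < 3)) sq_stop("each group needs n >= 3 samples")
  a <- mat[, groups == lv[1], drop = FALSE]
  b <- mat[, groups == lv[2], drop = FALSE]
  res <- lapply(rownames(mat), function(t) {
    w <- wilcoxon_rank_sum(a[t, ], b[t, ])
    med <- c(stats::median(a[t, ]), stats::median(b[t, ]))
    data.frame(taxon = t, statistic = w$U, p_value = w$p_value,
               direction = if (med[1] == med[2]) "none"
                           else lv[which.max(med)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$stars <- cut(out$p_value, c(-Inf, 0.001, 0.01, 0.05, Inf),
                   labels = c("***", "**", "*", ""))
  out$stars <- as.character(out$stars)
  if (bh) out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  out
}
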