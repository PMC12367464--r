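#' Spike-read fraction quality control
#'
#' Computes, per sample, the fraction of total reads assigned to spike-in
#' taxa and flags samples outside the recommended calibration window
#' (0.1%-10% of reads by default). Samples with zero spike reads get a
#' dedicated flag since no scale factor can be derived for them.
#'
#' @param cm A [count_matrix()] with at least one spike taxon.
#' @param low,high Window bounds on the spike read fraction
#'   (defaults 0.001 and 0.10).
#' @return A `data.frame` with columns `sample_id`, `spike_reads`,
#'   `total_reads`, `spike_fraction`, `qc_flag`
#'   (`pass`/`fail_low`/`fail_high`/`no_spike_reads`).
#' @export
spike_fraction_qc <- function(cm, low = 0.001, high = 0.10) {
  stopifnot(inherits(cm, "count_matrix"))
  if (!length(cm$spike_taxa))
    sq_stop("no spike taxa flagged in the count matrix")
  total <- colSums(cm$counts)
  if (any(total == 0))
    sq_stop("sample(s) with zero total reads: ",
            paste(colnames(cm$counts)[total == 0], collapse = ", "))
  spike <- colSums(cm$counts[cm$spike_taxa, , drop = FALSE])
  frac <- spike / total
  flag <- ifelse(spike == 0, "no_spike_reads",
          ifelse(frac < low, "fail_low",
          ifelse(frac > high, "fail_high", "pass")))
  data.frame(sample_id = colnames(cm$counts),
             spike_reads = as.integer(spike),
             total_reads = as.integer(total),
             spike_fraction = frac, qc_flag = flag,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Back-normalize read counts to absolute copies per gram
#'
#' The core estimator. For each sample `s`, the spike-in taxa with known
#' molecule doses act as internal calibrants: with pooled spike reads
#' `r_s` and pooled spike copies `C_s`, the per-sample back-normalization
#' factor is
#'
#'   scale_factor(s) = (C_s / r_s) x (elution_volume / spiked_aliquot_volume)
#'                     / feces_mass
#'
#' and every endogenous taxon's absolute abundance is
#' `reads(t, s) x scale_factor(s)` in 16S gene copies per gram of feces.
#' The aliquot term scales copies observed in the spiked aliquot up to the
#' whole eluate (copies are conserved in a homogeneous eluate); dividing
#' by wet mass puts the load on a per-gram basis. No pseudocounts are
#' used anywhere: zero reads map to zero copies and samples without spike
#' reads are flagged, never imputed.
#'
#' @param cm A [count_matrix()] containing the spike rows.
#' @param meta A [sample_meta()] data frame covering every sample.
#' @param doses List of [spike_dose()] objects (one per spike strain), or
#'   a spike-config list as returned by [read_spike_config()].
#' @param pooling How to combine multiple spike strains: `"sum"` (default;
#'   pooled reads and pooled copies, robust to a low-count strain) or
#'   `"mean"` (average of per-strain copies-per-read ratios).
#' @param qc_low,qc_high Spike-fraction QC window passed to
#'   [spike_fraction_qc()].
#' @return An object of class `abs_abund` with elements:
#'   `abundance` (endogenous taxa x samples, copies/g; `NA` columns for
#'   samples flagged `no_spike_reads`), `scale_factor` (copies per read,
#'   per gram), `qc` (the QC table), `spike_reads` (strain x sample
#'   matrix), `doses`, `pooling`, `meta`, and (after [gcn_correct()])
#'   `cells`.
#' @examples
#' cm <- count_matrix(matrix(c(500L, 300L, 100L), ncol = 1,
#'        dimnames = list(c("Blautia", "Bifidobacterium", "Planococcus"), "S1")),
#'        spike_taxa = "Planococcus")
#' meta <- sample_meta("S1", "mother", feces_mass = 0.2,
#'                     elution_volume = 200, spiked_aliquot_volume = 20)
#' st <- spike_strain("Planococcus sp.", "Planococcus", 1, 1, 1000)
#' d <- spike_dose(st)            # 9.12e8 copies
#' fit <- absolute_abundance(cm, meta, list(d))
#' fit
#' coef(fit)                      # per-sample scale factors
#' @export
absolute_abundance <- function(cm, meta, doses, pooling = c("sum", "mean"),
                               qc_low = 0.001, qc_high = 0.10) {
  stopifnot(inherits(cm, "count_matrix"))
  pooling <- match.arg(pooling)
  if (!is.null(doses$doses)) doses <- doses$doses  # accept a config list
  if (inherits(doses, "spike_dose")) doses <- list(doses)
  validate_sample_meta(meta)
  strain_taxa <- vapply(doses, function(d) d$strain$taxon_label, "")
  missing <- setdiff(strain_taxa, cm$spike_taxa)
  if (length(missing))
    sq_stop("dose strain(s) not flagged as spike taxa: ",
            paste(missing, collapse = ", "))
  if (!setequal(strain_taxa, cm$spike_taxa))
    sq_warn("spike taxa without a dose are excluded from calibration: ",
            paste(setdiff(cm$spike_taxa, strain_taxa), collapse = ", "))
  samples <- colnames(cm$counts)
  missing_meta <- setdiff(samples, meta$sample_id)
  if (length(missing_meta))
    sq_stop("metadata missing for sample(s): ",
            paste(missing_meta, collapse = ", "))
  meta <- meta[match(samples, meta$sample_id), , drop = FALSE]

  qc <- spike_fraction_qc(cm, low = qc_low, high = qc_high)
  spike_reads <- cm$counts[strain_taxa, , drop = FALSE]
  rownames(spike_reads) <- vapply(doses, function(d) d$strain$name, "")
  copies <- vapply(doses, function(d) d$copies_added, 0)

  ratio <- vapply(seq_along(samples), function(j) {
    r <- spike_reads[, j]
    if (pooling == "sum") {
      if (sum(r) == 0) return(NA_real_)
      sum(copies) / sum(r)
    } else {
      ok <- r > 0
      if (!any(ok)) return(NA_real_)
      mean(copies[ok] / r[ok])
    }
  }, 0)
  scale_factor <- ratio * (meta$elution_volume / meta$spiked_aliquot_volume) /
    meta$feces_mass
  names(scale_factor) <- samples

  qc$qc_flag[is.na(scale_factor)] <- "no_spike_reads"
  endo <- endogenous_counts(cm)
  abundance <- sweep(endo, 2, scale_factor, `*`)

  structure(list(abundance = abundance, scale_factor = scale_factor,
                 qc = qc, spike_reads = spike_reads, doses = doses,
                 pooling = pooling, meta = meta, cells = NULL,
                 gcn_flags = NULL),
            class = "abs_abund")
}

#' @export
print.abs_abund <- function(x, ...) {
  n_fail <- sum(x$qc$qc_flag != "pass")
  cat(sprintf("abs_abund: %d endogenous taxa x %d samples (copies/g feces)\n",
              nrow(x$abundance), ncol(x$abundance)))
  cat(sprintf("  spike strains: %s; pooling: %s\n",
              paste(rownames(x$spike_reads), collapse = ", "), x$pooling))
  tl <- total_load(x)
  cat(sprintf("  total load range: %.3g - %.3g copies/g\n",
              min(tl, na.rm = TRUE), max(tl, na.rm = TRUE)))
  if (n_fail) cat(sprintf("  QC: %d sample(s) flagged (%s)\n", n_fail,
                          paste(unique(x$qc$qc_flag[x$qc$qc_flag != "pass"]),
                                collapse = ", ")))
  else cat("  QC: all samples pass\n")
  if (!is.null(x$cells)) cat("  cells/g layer present (GCN-corrected)\n")
  invisible(x)
}

#' @export
summary.abs_abund <- function(object, ...) {
  tl <- total_load(object)
  out <- data.frame(sample_id = object$meta$sample_id,
                    group = object$meta$group,
                    scale_factor = object$scale_factor,
                    spike_fraction = object$qc$spike_fraction,
                    qc_flag = object$qc$qc_flag,
                    total_copies_per_g = tl,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("summary.abs_abund", "data.frame")
  out
}

#' @export
coef.abs_abund <- function(object, ...) object$scale_factor

#' @export
as.matrix.abs_abund <- function(x, layer = c("copies", "cells"), ...) {
  layer <- match.arg(layer)
  if (layer == "cells") {
    if (is.null(x$cells)) sq_stop("no cells layer; run gcn_correct() first")
    return(x$cells)
  }
  x$abundance
}

#' @export
plot.abs_abund <- function(x, log = TRUE, ...) {
  tl <- total_load(x)
  y <- if (log) log10(tl) else tl
  grp <- factor(x$meta$group)
  graphics::barplot(y, names.arg = x$meta$sample_id, las = 2,
                    col = grDevices::hcl.colors(nlevels(grp), "Dark 2")[grp],
                    ylab = if (log) "log10 copies/g" else "copies/g", ...)
  graphics::legend("topright", legend = levels(grp), bty = "n",
                   fill = grDevices::hcl.colors(nlevels(grp), "Dark 2"))
  invisible(x)
}

#' Total microbial load per sample
#'
#' @param aam An [absolute_abundance()] fit.
#' @param layer `"copies"` (16S copies/g) or `"cells"` (requires
#'   [gcn_correct()]).
#' @return Named numeric vector, one value per sample (`NA` where the
#'   sample failed spike calibration).
#' @export
total_load <- function(aam, layer = c("copies", "cells")) {
  colSums(as.matrix(aam, layer = match.arg(layer)))
}

#' Correct gene-copy loads to cell counts
#'
#' Divides each taxon's copies/g by its 16S rRNA gene copy number
#' (GCN, e.g. rrnDB genus means), adding a cells/g layer to the fit.
#' Taxa absent from the table use `default` and are flagged.
#'
#' @param aam An [absolute_abundance()] fit.
#' @param gcn_table Named numeric vector: taxon -> copies per genome
#'   (all > 0).
#' @param default GCN for taxa missing from the table (default 1).
#' @return The fit with `cells` (matrix) and `gcn_flags` (logical vector,
#'   `TRUE` where the default was used) filled in.
#' @export
gcn_correct <- function(aam, gcn_table, default = 1) {
  stopifnot(inherits(aam, "abs_abund"))
  if (any(gcn_table <= 0) || default <= 0)
    sq_stop("GCN values must be > 0")
  tax <- rownames(aam$abundance)
  gcn <- ifelse(tax %in% names(gcn_table), gcn_table[tax], default)
  names(gcn) <- tax
  aam$cells <- aam$abundance / gcn
  aam$gcn_flags <- !(tax %in% names(gcn_table))
  names(aam$gcn_flags) <- tax
  aam
}

#' Per-strain agreement diagnostic for multi-spike pooling
#'
#' With two or more spike strains, each strain independently implies a
#' total endogenous copy estimate per sample (aliquot scale:
#' total endogenous reads x strain copies / strain reads). Their log
#' ratio ("discordance", first strain vs second) should be 0 when the
#' calibrants agree; systematic departures indicate strain-specific
#' amplification bias.
#'
#' @param cm A [count_matrix()].
#' @param doses List of >= 2 [spike_dose()] objects.
#' @return A `data.frame` per sample: per-strain estimates
#'   (`est_<strain taxon>`), `pooled` (sum-pooling estimate),
#'   `discordance` (`ln(est1/est2)`, `NA` + flag when a strain has zero
#'   reads), and `flag`.
#' @export
pooling_diagnostic <- function(cm, doses) {
  stopifnot(inherits(cm, "count_matrix"))
  if (!is.null(doses$doses)) doses <- doses$doses
  if (length(doses) < 2)
    sq_stop("pooling diagnostic requires >=2 strains")
  strain_taxa <- vapply(doses, function(d) d$strain$taxon_label, "")
  copies <- vapply(doses, function(d) d$copies_added, 0)
  spike_reads <- cm$counts[strain_taxa, , drop = FALSE]
  endo_total <- colSums(endogenous_counts(cm))
  est <- sapply(seq_along(doses), function(i) {
    r <- spike_reads[i, ]
    ifelse(r > 0, endo_total * copies[i] / r, NA_real_)
  })
  est <- matrix(est, ncol = length(doses),
                dimnames = list(colnames(cm$counts),
                                paste0("est_", strain_taxa)))
  pooled_r <- colSums(spike_reads)
  pooled <- ifelse(pooled_r > 0, endo_total * sum(copies) / pooled_r,
                   NA_real_)
  disc <- log(est[, 1] / est[, 2])
  flag <- ifelse(is.na(est[, 1]) | is.na(est[, 2]), "zero_spike_reads", "ok")
  data.frame(sample_id = colnames(cm$counts), est, pooled = pooled,
             discordance = disc, flag = flag,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Spike read count versus estimated load, per strain
#'
#' A diagnostic of the method's core mechanism: at a fixed spike dose,
#' samples with higher true microbial load leave a smaller share of reads
#' for the spike, so spike reads and estimated total load should be
#' inversely related across samples. Reports the normality-gated
#' correlation ([gated_correlation()]) per strain over QC-pass samples.
#'
#' @param cm A [count_matrix()].
#' @param aam The matching [absolute_abundance()] fit.
#' @return A `data.frame`: `strain`, `method` (pearson/spearman),
#'   `estimate`, `p_value`, `n`.
#' @export
spike_load_correlation <- function(cm, aam) {
  stopifnot(inherits(cm, "count_matrix"), inherits(aam, "abs_abund"))
  ok <- aam$qc$sample_id[aam$qc$qc_flag == "pass"]
  if (length(ok) < 3)
    sq_stop("need >=3 QC-pass samples for the spike-load correlation")
  tl <- total_load(aam)[ok]
  out <- lapply(rownames(aam$spike_reads), function(st) {
    r <- aam$spike_reads[st, ok]
    g <- gated_correlation(as.numeric(r), as.numeric(tl))
    data.frame(strain = st, method = g$method, estimate = g$estimate,
               p_value = g$p_value, n = length(ok),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
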