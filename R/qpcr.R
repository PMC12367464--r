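#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10(copies) over a dilution series.
#' Per-cycle amplification efficiency is derived from the slope as
#' `10^(-1/slope) - 1` (1.0 = perfect doubling per cycle); a warning is
#' raised when it falls outside \[0.9, 1.1\]. A non-negative slope yields
#' a curve flagged invalid (conversion refuses to use it).
#'
#' @param copies Known template copy numbers (> 0), spanning >= 2 logs.
#' @param ct Measured Ct values (same length).
#' @return An object of class `standard_curve`: `slope` (Ct per log10
#'   copies), `intercept` (Ct at 1 copy), `r_squared`, `efficiency`,
#'   `valid`, `n`.
#' @examples
#' cps <- 10^(2:7)
#' fit_standard_curve(cps, 37 - 3.3219 * log10(cps))  # efficiency ~1.00
#' @export
fit_standard_curve <- function(copies, ct) {
  if (length(copies) != length(ct)) sq_stop("copies and ct must be paired")
  if (length(copies) < 3) sq_stop("standard curve needs >= 3 points")
  if (any(!is.finite(copies) | copies <= 0))
    sq_stop("standard copies must be > 0")
  lx <- log10(copies)
  if (diff(range(lx)) < 2)
    sq_warn("standard series spans < 2 logs; curve may be unreliable")
  fit <- stats::lm(ct ~ lx)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  tss <- sum((ct - mean(ct))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  valid <- is.finite(slope) && slope < 0
  eff <- if (valid) 10^(-1 / slope) - 1 else NA_real_
  if (!valid) sq_warn("non-negative slope: invalid standard curve")
  else if (eff < 0.9 || eff > 1.1)
    sq_warn(sprintf("amplification efficiency %.3f outside [0.9, 1.1]", eff))
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 efficiency = eff, valid = valid, n = length(copies)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard_curve: Ct = %.4f %+.4f x log10(copies)  (n = %d)\n",
              x$intercept, x$slope, x$n))
  cat(sprintf("  r^2 = %.5f, efficiency = %s%s\n", x$r_squared,
              if (is.na(x$efficiency)) "NA"
              else sprintf("%.1f%%", 100 * x$efficiency),
              if (x$valid) "" else "  [INVALID: slope >= 0]"))
  invisible(x)
}

#' Predicted Ct for a given copy number
#' @param object A [fit_standard_curve()] object.
#' @param copies Copy numbers (> 0).
#' @param ... Unused.
#' @return Predicted Ct values.
#' @export
predict.standard_curve <- function(object, copies, ...) {
  object$intercept + object$slope * log10(copies)
}

#' Convert Ct values to copy numbers
#'
#' Inverts the standard curve: `copies = 10^((ct - intercept)/slope)`.
#' Ct values above the intercept imply < 1 copy; these are returned as-is
#' and flagged below quantification via the `below_loq` attribute.
#'
#' @param ct Ct values.
#' @param curve A valid [fit_standard_curve()] object (slope < 0).
#' @return Numeric copy numbers with a logical `below_loq` attribute.
#' @export
ct_to_copies <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!curve$valid) sq_stop("invalid standard curve (slope >= 0)")
  copies <- 10^((ct - curve$intercept) / curve$slope)
  structure(copies, below_loq = copies < 1)
}

#' Scale a per-reaction copy number to copies per gram
#'
#' Places a qPCR result on the same per-gram scale as spike-in
#' quantification: copies in the reaction template are scaled to the full
#' eluate (`elution_volume / template_volume`) and divided by the wet
#' feces mass extracted.
#'
#' @param copies_per_reaction Copies in the qPCR reaction template.
#' @param template_volume Template volume per reaction, uL (> 0).
#' @param elution_volume DNA elution volume, uL (> 0).
#' @param feces_mass Wet mass extracted, g (> 0).
#' @return Copies per gram of feces.
#' @examples
#' per_gram_from_reaction(1e4, 1, 200, 0.2)  # 1e7 copies/g
#' @export
per_gram_from_reaction <- function(copies_per_reaction, template_volume,
                                   elution_volume, feces_mass) {
  for (v in list(template_volume, elution_volume, feces_mass))
    if (any(!is.finite(v) | v <= 0))
      sq_stop("template_volume, elution_volume and feces_mass must be > 0")
  copies_per_reaction * (elution_volume / template_volume) / feces_mass
}

#' Read a qPCR Ct table and average replicates
#'
#' TSV with columns `sample_id`, `target`, and replicate Ct columns
#' (`ct_rep1`, `ct_rep2`, ...). Replicates (typically triplicates) are
#' averaged; the SD is reported alongside.
#'
#' @param path Path to the TSV.
#' @return `data.frame`: `sample_id`, `target`, `ct_mean`, `ct_sd`,
#'   `n_reps`.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) sq_stop("Ct table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  rep_cols <- grep("^ct_rep", names(df), value = TRUE)
  if (!length(rep_cols)) sq_stop("no ct_rep* columns found")
  reps <- as.matrix(df[rep_cols])
  data.frame(sample_id = as.character(df$sample_id),
             target = as.character(df$target),
             ct_mean = rowMeans(reps, na.rm = TRUE),
             ct_sd = apply(reps, 1, stats::sd, na.rm = TRUE),
             n_reps = rowSums(is.finite(reps)),
             stringsAsFactors = FALSE)
}

#' qPCR copies per gram for a cohort
#'
#' Joins averaged Ct values with a standard curve and per-sample physical
#' metadata to produce per-gram copy loads, returned in the long
#' measurement format used for method comparisons.
#'
#' @param ct_table Output of [read_ct_table()] (or a compatible frame
#'   with `sample_id` and `ct_mean`).
#' @param curve A valid [fit_standard_curve()] object.
#' @param meta A [sample_meta()] data frame.
#' @param template_volume Template volume per reaction, uL (default 1).
#' @return `data.frame` in [method_measurements()] layout
#'   (`method = "qpcr"`, value in copies/g).
#' @export
qpcr_per_gram <- function(ct_table, curve, meta, template_volume = 1) {
  validate_sample_meta(meta)
  idx <- match(ct_table$sample_id, meta$sample_id)
  if (anyNA(idx))
    sq_stop("metadata missing for qPCR sample(s): ",
            paste(ct_table$sample_id[is.na(idx)], collapse = ", "))
  cp <- as.numeric(ct_to_copies(ct_table$ct_mean, curve))
  val <- per_gram_from_reaction(cp, template_volume,
                                meta$elution_volume[idx],
                                meta$feces_mass[idx])
  method_measurements(ct_table$sample_id, "qpcr", val)
}
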