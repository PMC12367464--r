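#' Construct per-sample physical metadata
#'
#' Records the physical accounting needed to put read counts on a
#' per-gram scale: wet feces mass extracted, DNA elution volume, and the
#' volume of eluate actually spiked and taken into library preparation.
#'
#' @param sample_id Character sample ids (unique).
#' @param group Character group labels (e.g. `"mother"` / `"infant"`).
#' @param feces_mass Wet mass extracted, grams (> 0).
#' @param elution_volume DNA elution volume, microlitres (> 0).
#' @param spiked_aliquot_volume Volume of eluate spiked and used for the
#'   library, microlitres (> 0 and <= `elution_volume`).
#' @return A `data.frame` of class `sample_meta` with one row per sample.
#' @export
sample_meta <- function(sample_id, group, feces_mass, elution_volume,
                        spiked_aliquot_volume) {
  df <- data.frame(sample_id = as.character(sample_id),
                   group = as.character(group),
                   feces_mass = as.numeric(feces_mass),
                   elution_volume = as.numeric(elution_volume),
                   spiked_aliquot_volume = as.numeric(spiked_aliquot_volume),
                   stringsAsFactors = FALSE)
  validate_sample_meta(df)
  class(df) <- c("sample_meta", "data.frame")
  df
}

validate_sample_meta <- function(df) {
  req <- c("sample_id", "group", "feces_mass", "elution_volume",
           "spiked_aliquot_volume")
  missing <- setdiff(req, names(df))
  if (length(missing))
    sq_stop("sample metadata missing column(s): ",
            paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    sq_stop("duplicate sample id(s): ",
            paste(unique(df$sample_id[duplicated(df$sample_id)]),
                  collapse = ", "))
  for (col in c("feces_mass", "elution_volume", "spiked_aliquot_volume")) {
    v <- df[[col]]
    if (any(!is.finite(v) | v <= 0))
      sq_stop(col, " must be strictly positive for every sample")
  }
  bad <- df$spiked_aliquot_volume > df$elution_volume
  if (any(bad))
    sq_stop("spiked aliquot volume exceeds elution volume for sample(s): ",
            paste(df$sample_id[bad], collapse = ", "))
  invisible(df)
}

#' Read per-sample metadata from TSV/CSV
#'
#' Expects columns `sample_id`, `group`, `feces_mass` (g),
#' `elution_volume` (uL), `spiked_aliquot_volume` (uL). Lines starting
#' with `#` are treated as comments (unit documentation).
#'
#' @param path Path to a tab- or comma-separated file.
#' @return A validated [sample_meta()] data frame.
#' @export
read_sample_meta <- function(path) {
  if (!file.exists(path)) sq_stop("sample metadata not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = TRUE)
  sample_meta(df$sample_id, df$group, df$feces_mass, df$elution_volume,
              df$spiked_aliquot_volume)
}

#' Write per-sample metadata as TSV
#' @param meta A [sample_meta()] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_meta <- function(meta, path) {
  utils::write.table(as.data.frame(meta), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read per-sample external method measurements
#'
#' Long-format table of per-sample quantification results from external
#' methods: columns `sample_id`, `method` (one of `flow_cytometry`,
#' `plate_count`, `qpcr`, `spike_in`, `total_dna`), `value`
#' (method-specific units: cells/g, CFU/g, copies/g, or ng).
#'
#' @param path Path to a TSV/CSV file.
#' @return A `data.frame` with validated unique (sample_id, method) pairs.
#' @export
read_method_measurements <- function(path) {
  if (!file.exists(path)) sq_stop("measurements file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE)
  method_measurements(df$sample_id, df$method, df$value)
}

#' @rdname read_method_measurements
#' @param sample_id,method,value Vectors forming the long table directly.
#' @export
method_measurements <- function(sample_id, method, value) {
  known <- c("flow_cytometry", "plate_count", "qpcr", "spike_in", "total_dna")
  method <- as.character(method)
  bad <- setdiff(unique(method), known)
  if (length(bad))
    sq_stop("unknown measurement method(s): ", paste(bad, collapse = ", "),
            "; expected one of ", paste(known, collapse = ", "))
  df <- data.frame(sample_id = as.character(sample_id), method = method,
                   value = as.numeric(value), stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("sample_id", "method")]))
    sq_stop("duplicate (sample_id, method) pair in measurements")
  if (any(!is.finite(df$value) | df$value < 0))
    sq_stop("measurement values must be finite and >= 0")
  df
}
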