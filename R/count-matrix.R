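#' Construct a taxon-by-sample count matrix
#'
#' The central container for amplicon read counts: an integer matrix with
#' taxa as rows and samples as columns, plus a set of taxon labels flagged
#' as exogenous spike-in calibrants. Spike-in rows are ordinary count rows;
#' downstream quantification separates them from the endogenous community.
#'
#' @param counts Numeric matrix of non-negative whole-number read counts
#'   with unique rownames (taxa) and colnames (samples).
#' @param spike_taxa Character vector of taxon labels marking spike-in rows.
#'   Must be a subset of `rownames(counts)`.
#' @param allow_empty Logical; permit samples with zero total reads
#'   (e.g. a zero-depth simulation). Default `FALSE`.
#' @return An object of class `count_matrix`: a list with elements
#'   `counts` (integer matrix) and `spike_taxa` (character).
#' @examples
#' m <- matrix(c(10L, 5L, 2L, 20L, 1L, 4L), nrow = 3,
#'             dimnames = list(c("Blautia", "Veillonella", "Planococcus"),
#'                             c("S1", "S2")))
#' cm <- count_matrix(m, spike_taxa = "Planococcus")
#' cm
#' @export
count_matrix <- function(counts, spike_taxa = character(), allow_empty = FALSE) {
  counts <- as.matrix(counts)
  validate_counts(counts, allow_empty = allow_empty)
  spike_taxa <- as.character(spike_taxa)
  missing <- setdiff(spike_taxa, rownames(counts))
  if (length(missing))
    sq_stop("spike taxon not found in count table: ",
            paste(missing, collapse = ", "))
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, spike_taxa = spike_taxa),
            class = "count_matrix")
}

validate_counts <- function(counts, allow_empty = FALSE) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    sq_stop("count matrix must have taxon rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    sq_stop("duplicate taxon labels: ",
            paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                  collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    sq_stop("duplicate sample ids: ",
            paste(unique(colnames(counts)[duplicated(colnames(counts))]),
                  collapse = ", "))
  if (!is.numeric(counts))
    sq_stop("counts must be numeric")
  bad <- which(!is_whole(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad))
    sq_stop(sprintf(
      "non-integer or negative count at taxon '%s', sample '%s' (value %s)",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
      format(counts[bad[1, , drop = FALSE]])))
  if (!allow_empty) {
    empty <- colSums(counts) == 0
    if (any(empty))
      sq_stop("sample(s) with zero total reads: ",
              paste(colnames(counts)[empty], collapse = ", "),
              " (use allow_empty = TRUE to permit)")
  }
  invisible(counts)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d taxa x %d samples (%d spike-in)\n",
              nrow(x$counts), ncol(x$counts), length(x$spike_taxa)))
  if (length(x$spike_taxa))
    cat("  spike-in taxa:", paste(x$spike_taxa, collapse = ", "), "\n")
  cat(sprintf("  total reads: %s (median/sample %s)\n",
              format(sum(x$counts), big.mark = ","),
              format(stats::median(colSums(x$counts)), big.mark = ",")))
  invisible(x)
}

#' Taxon and sample accessors
#' @param cm A [count_matrix()].
#' @return Character vector of labels.
#' @export
taxa <- function(cm) rownames(cm$counts)

#' @rdname taxa
#' @export
sample_ids <- function(cm) colnames(cm$counts)

#' Endogenous (spike-excluded) submatrix
#'
#' @param cm A [count_matrix()].
#' @return Integer matrix of counts with spike-in rows removed.
#' @export
endogenous_counts <- function(cm) {
  cm$counts[setdiff(rownames(cm$counts), cm$spike_taxa), , drop = FALSE]
}

#' Read a taxon-by-sample count table
#'
#' Reads a dense TSV count table (taxa as rows, samples as columns) or a
#' dense BIOM-style JSON table, validates it, and flags the given spike-in
#' taxa. If the TSV header's first cell is `sample` or `#sample`, samples
#' are taken to be on rows and the table is transposed.
#'
#' @param path Path to a `.tsv`/`.txt` table or a dense `.json`/`.biom`
#'   JSON table (top-level keys `rows`, `columns`, `data`).
#' @param spike_labels Character vector of taxon labels present in the
#'   table that are spike-in calibrants. A label absent from the table is
#'   a hard error.
#' @param allow_empty Passed to [count_matrix()].
#' @return A [count_matrix()].
#' @seealso [write_count_table()]
#' @export
read_count_table <- function(path, spike_labels = character(),
                             allow_empty = FALSE) {
  if (!file.exists(path)) sq_stop("count table not found: ", path)
  if (grepl("\\.(json|biom)$", path, ignore.case = TRUE)) {
    counts <- read_biom_dense(path)
  } else {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE, comment.char = "")
    if (ncol(df) < 2) sq_stop("count table needs an id column plus >=1 sample")
    id_name <- tolower(sub("^#", "", names(df)[1]))
    counts <- as.matrix(df[, -1, drop = FALSE])
    rownames(counts) <- as.character(df[[1]])
    if (id_name %in% c("sample", "sample_id", "samples"))
      counts <- t(counts)
  }
  count_matrix(counts, spike_taxa = spike_labels, allow_empty = allow_empty)
}

# dense BIOM-ish JSON: rows/columns are lists with "id"; data is dense matrix
read_biom_dense <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(b$rows) || is.null(b$columns) || is.null(b$data))
    sq_stop("JSON count table must have 'rows', 'columns' and 'data'")
  rid <- if (is.data.frame(b$rows)) b$rows$id else vapply(b$rows, `[[`, "", "id")
  cid <- if (is.data.frame(b$columns)) b$columns$id else
    vapply(b$columns, `[[`, "", "id")
  m <- b$data
  if (is.list(m)) m <- do.call(rbind, m)
  m <- as.matrix(m)
  dimnames(m) <- list(rid, cid)
  m
}

#' Write a count table as TSV
#'
#' Inverse of [read_count_table()]: taxa as rows, samples as columns,
#' first column named `taxon`. Spike flags are not stored in the file;
#' they are supplied again at read time.
#'
#' @param cm A [count_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(cm, path) {
  df <- data.frame(taxon = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse count rows by a taxon mapping
#'
#' Sums counts of rows sharing the same mapped label (e.g. ASV to genus).
#' Spike-in flags follow the mapping. Collapsing is an explicit step: the
#' readers never collapse implicitly.
#'
#' @param cm A [count_matrix()].
#' @param mapping Named character vector: `names(mapping)` are current
#'   taxon labels, values the collapsed labels. Unmapped taxa keep their
#'   own label.
#' @return A [count_matrix()] at the collapsed level.
#' @export
collapse_taxa <- function(cm, mapping) {
  lab <- rownames(cm$counts)
  to <- ifelse(lab %in% names(mapping), mapping[lab], lab)
  agg <- rowsum(cm$counts, group = to)
  spikes <- unique(ifelse(cm$spike_taxa %in% names(mapping),
                          mapping[cm$spike_taxa], cm$spike_taxa))
  count_matrix(agg, spike_taxa = spikes, allow_empty = TRUE)
}
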