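#' Number of dsDNA molecules in a given mass
#'
#' Converts a DNA mass to molecule copies using the mean molar mass of
#' double-stranded DNA, 660 g/mol per base pair:
#' copies = mass_ng x 6.022e23 / (length_bp x 660 x 1e9).
#'
#' @param mass_ng DNA mass in nanograms (>= 0).
#' @param length_bp Length of the double-stranded molecule in base pairs
#'   (> 0). A whole genome for genomic spike-in DNA, or an amplicon
#'   length for amplicon-scale dosing.
#' @return Number of molecule copies (double).
#' @examples
#' copies_from_mass(1, 1000)        # ~9.12e8 copies
#' copies_from_mass(10.775, 4.238e6) # ~2.32e6 genome copies
#' @export
copies_from_mass <- function(mass_ng, length_bp) {
  if (any(!is.finite(length_bp) | length_bp <= 0))
    sq_stop("length_bp must be > 0")
  if (any(!is.finite(mass_ng) | mass_ng < 0))
    sq_stop("mass_ng must be >= 0")
  mass_ng * 6.022e23 / (length_bp * 660 * 1e9)
}

#' Describe one spike-in calibrant strain
#'
#' @param name Strain name (free text).
#' @param taxon_label The count-table row (typically a genus) this strain
#'   maps to; matching is by exact label.
#' @param dna_concentration DNA concentration of the spike stock, ng/uL.
#' @param volume_added Volume of stock added per sample aliquot, uL.
#' @param reference_length Length in bp used to convert mass to copies
#'   (genome size for genomic DNA dosing, amplicon length for
#'   amplicon-scale dosing).
#' @param gcn 16S rRNA gene copies per genome (>= 1), e.g. from rrnDB.
#' @return An object of class `spike_strain`.
#' @export
spike_strain <- function(name, taxon_label, dna_concentration, volume_added,
                         reference_length, gcn = 1) {
  if (!is.finite(dna_concentration) || dna_concentration < 0)
    sq_stop("dna_concentration must be >= 0")
  if (!is.finite(volume_added) || volume_added < 0)
    sq_stop("volume_added must be >= 0")
  if (!is.finite(reference_length) || reference_length <= 0)
    sq_stop("reference_length must be > 0")
  if (!is.finite(gcn) || gcn < 1)
    sq_stop("gcn must be >= 1")
  structure(list(name = as.character(name),
                 taxon_label = as.character(taxon_label),
                 dna_concentration = dna_concentration,
                 volume_added = volume_added,
                 reference_length = reference_length,
                 gcn = gcn),
            class = "spike_strain")
}

#' @export
print.spike_strain <- function(x, ...) {
  cat(sprintf("spike_strain '%s' -> taxon '%s': %.4g ng/uL x %.4g uL, %s bp, GCN %g\n",
              x$name, x$taxon_label, x$dna_concentration, x$volume_added,
              format(x$reference_length, big.mark = ","), x$gcn))
  invisible(x)
}

#' Compute the dose of a spike-in strain
#'
#' Converts the spiked DNA mass (concentration x volume) to molecule
#' copies added per sample aliquot. With `dose_in_16s_copies = TRUE` the
#' genome-copy dose is multiplied by the strain's 16S gene copy number,
#' yielding a dose in 16S gene copies.
#'
#' @param strain A [spike_strain()].
#' @param dose_in_16s_copies Logical; express the dose in 16S gene copies
#'   (genome copies x GCN) rather than genome copies. Default `FALSE`.
#' @return An object of class `spike_dose`: list with `strain`, `mass_ng`,
#'   `copies_added`, and `basis` (`"genome"` or `"16s"`).
#' @examples
#' st <- spike_strain("Pseudoalteromonas sp. APC 3896", "Pseudoalteromonas",
#'                    dna_concentration = 4.31, volume_added = 2.5,
#'                    reference_length = 4.238e6, gcn = 9)
#' spike_dose(st)  # ~2.32e6 genome copies per aliquot
#' @export
spike_dose <- function(strain, dose_in_16s_copies = FALSE) {
  stopifnot(inherits(strain, "spike_strain"))
  mass_ng <- strain$dna_concentration * strain$volume_added
  copies <- copies_from_mass(mass_ng, strain$reference_length)
  if (dose_in_16s_copies) copies <- copies * strain$gcn
  if (copies == 0)
    sq_warn("zero spike dose for strain '", strain$name,
            "' (mass or volume is zero)")
  structure(list(strain = strain, mass_ng = mass_ng, copies_added = copies,
                 basis = if (dose_in_16s_copies) "16s" else "genome"),
            class = "spike_dose")
}

#' @export
print.spike_dose <- function(x, ...) {
  cat(sprintf("spike_dose '%s': %.4g ng -> %.4g copies (%s basis)\n",
              x$strain$name, x$mass_ng, x$copies_added, x$basis))
  invisible(x)
}

#' Read a spike-in configuration file
#'
#' YAML (or JSON) file with a `spikes` list of strain entries
#' (`name`, `taxon_label`, `dna_concentration` ng/uL, `volume_added` uL,
#' `reference_length` bp, `gcn`) and optional top-level switches
#' `dose_in_16s_copies` (default false) and `gcn_default`.
#'
#' @param path Path to the config file.
#' @return A list with `strains` (list of [spike_strain()]), `doses`
#'   (list of [spike_dose()]), `dose_in_16s_copies`, and `gcn_default`.
#' @export
read_spike_config <- function(path) {
  if (!file.exists(path)) sq_stop("spike config not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  if (is.null(cfg$spikes) || !length(cfg$spikes))
    sq_stop("spike config must define at least one entry under 'spikes'")
  strains <- lapply(cfg$spikes, function(s) {
    req <- c("name", "taxon_label", "dna_concentration", "volume_added",
             "reference_length")
    miss <- setdiff(req, names(s))
    if (length(miss))
      sq_stop("spike entry missing field(s): ", paste(miss, collapse = ", "))
    spike_strain(s$name, s$taxon_label, s$dna_concentration, s$volume_added,
                 s$reference_length, gcn = if (is.null(s$gcn)) 1 else s$gcn)
  })
  in16s <- isTRUE(cfg$dose_in_16s_copies)
  list(strains = strains,
       doses = lapply(strains, spike_dose, dose_in_16s_copies = in16s),
       dose_in_16s_copies = in16s,
       gcn_default = if (is.null(cfg$gcn_default)) 1 else cfg$gcn_default)
}

#' Write a spike-in configuration file
#' @param strains List of [spike_strain()] objects.
#' @param path Output path (`.yaml`).
#' @param dose_in_16s_copies Logical switch stored in the file.
#' @return `path`, invisibly.
#' @export
write_spike_config <- function(strains, path, dose_in_16s_copies = FALSE) {
  cfg <- list(
    spikes = lapply(strains, function(s) s[c("name", "taxon_label",
                                             "dna_concentration",
                                             "volume_added",
                                             "reference_length", "gcn")]),
    dose_in_16s_copies = dose_in_16s_copies)
  yaml::write_yaml(cfg, path)
  invisible(path)
}
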