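#' Default genus pool for the synthetic mother-infant cohort
#'
#' Fifteen gut genera with group-specific Dirichlet concentration
#' vectors emulating the contrast between an adult (mother) community
#' dominated by strict-anaerobe Bacillota (Blautia, Faecalibacterium,
#' Coprococcus, Subdoligranulum, Anaerostipes, Ruminococcus) and an
#' early-life (infant) community dominated by Bifidobacterium,
#' Escherichia-Shigella, Veillonella, Streptococcus and Enterobacter.
#' Genus-level 16S gene copy numbers are typical rrnDB-style means.
#'
#' @return `data.frame`: `genus`, `alpha_mother`, `alpha_infant`, `gcn`,
#'   `bias`.
#' @export
default_genus_pool <- function() {
  data.frame(
    genus = c("Bifidobacterium", "Escherichia-Shigella", "Bacteroides",
              "Blautia", "Faecalibacterium", "Veillonella", "Streptococcus",
              "Enterobacter", "Erysipelatoclostridium", "Ruminococcus",
              "Coprococcus", "Subdoligranulum", "Anaerostipes",
              "Lactobacillus", "Akkermansia"),
    alpha_mother = c(4, 0.5, 8, 12, 10, 0.5, 1, 0.2, 0.3, 6,
                     5, 4, 3, 0.5, 1),
    alpha_infant = c(14, 8, 4, 1, 0.3, 4, 3, 2, 2, 0.3,
                     0.2, 0.2, 0.3, 1, 0.2),
    gcn = c(3, 7, 6, 4, 6, 4, 6, 7, 6, 4, 4, 5, 5, 5, 3),
    bias = 1,
    stringsAsFactors = FALSE)
}

#' Default spike-in strains
#'
#' The two marine calibrants with the doses used throughout: 2.5 uL of
#' stock at 4.31 and 9.59 ng/uL, genome-scale reference lengths chosen so
#' the genome-copy doses are 2.32e6 and 5.99e6 copies per aliquot, and
#' genus-level GCNs.
#'
#' @return List of two [spike_strain()] objects.
#' @export
default_spike_strains <- function() {
  list(
    spike_strain("Pseudoalteromonas sp. APC 3896", "Pseudoalteromonas",
                 dna_concentration = 4.31, volume_added = 2.5,
                 reference_length = 4.238e6, gcn = 9),
    spike_strain("Planococcus sp. APC 3900", "Planococcus",
                 dna_concentration = 9.59, volume_added = 2.5,
                 reference_length = 3.652e6, gcn = 7))
}

#' Parameters for a synthetic spike-in experiment
#'
#' Defaults encode the emulated study conditions: two groups of six
#' samples, total 16S loads log-normal with log10 means 11.0 (mother)
#' and 10.5 (infant) — the ~half-log gap — SD 0.3; group-specific genus
#' Dirichlet compositions; two spike strains dosed at 2.32e6 / 5.99e6
#' copies per 20 uL aliquot of a 200 uL eluate from 0.2 g feces; 5e4
#' reads per sample. Method noise: qPCR sigma 0.05 log10; flow cytometry
#' overestimates cells ~7-fold relative to plate counts.
#'
#' @param n_per_group Samples per group.
#' @param groups Two group labels.
#' @param log10_load_mean Named (by group) log10 mean total load,
#'   16S copies per gram.
#' @param log10_load_sd SD of log10 load.
#' @param genus_pool As [default_genus_pool()]; columns `genus`,
#'   `alpha_<group>` per group, `gcn`, `bias`.
#' @param depth Reads per sample.
#' @param spikes List of [spike_strain()]s.
#' @param spike_bias Amplification bias multiplier per spike strain
#'   (default 1s).
#' @param dose_in_16s_copies Dose basis switch passed to [spike_dose()].
#' @param feces_mass,elution_volume,spiked_aliquot_volume Physical
#'   defaults applied to every sample (g, uL, uL).
#' @param qpcr_sigma,flow_sigma,plate_sigma Log10 SD of method noise.
#' @param flow_factor Multiplicative overestimation of flow cytometry
#'   relative to true cell counts (default 7).
#' @param seed Integer seed.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_per_group = 6,
                       groups = c("mother", "infant"),
                       log10_load_mean = c(mother = 11.0, infant = 10.5),
                       log10_load_sd = 0.3,
                       genus_pool = default_genus_pool(),
                       depth = 50000,
                       spikes = default_spike_strains(),
                       spike_bias = NULL,
                       dose_in_16s_copies = FALSE,
                       feces_mass = 0.2,
                       elution_volume = 200,
                       spiked_aliquot_volume = 20,
                       qpcr_sigma = 0.05,
                       flow_sigma = 0.15,
                       plate_sigma = 0.20,
                       flow_factor = 7,
                       seed = 1) {
  if (is.null(spike_bias)) spike_bias <- rep(1, length(spikes))
  stopifnot(length(groups) == 2, all(groups %in% names(log10_load_mean)),
            n_per_group >= 1, depth >= 0, log10_load_sd > 0,
            length(spike_bias) == length(spikes),
            all(c("genus", "gcn", "bias") %in% names(genus_pool)),
            all(paste0("alpha_", groups) %in% names(genus_pool)),
            all(genus_pool$gcn >= 1), all(genus_pool$bias > 0),
            feces_mass > 0, elution_volume > 0,
            spiked_aliquot_volume > 0,
            spiked_aliquot_volume <= elution_volume)
  for (g in groups)
    if (any(genus_pool[[paste0("alpha_", g)]] <= 0))
      sq_stop("Dirichlet concentrations must be strictly positive")
  structure(as.list(environment()), class = "sim_params")
}

#' Named scenario presets for the simulator
#'
#' * `baseline` — defaults; expected spike fraction inside the 0.1%-10%
#'   window for nearly all samples.
#' * `low_biomass` — loads ~1.5 logs lower (log10 means 9.5 / 9.0) with
#'   spike stocks diluted 10x to keep the spike fraction in-window; rare
#'   genera fall below the ~1e5 copies/g detection threshold of amplicon
#'   sequencing and are mostly observed as zero reads.
#' * `biased_amplification` — both spike strains amplify 2x relative to
#'   the endogenous community, producing a systematic ~0.5x
#'   underestimation of loads.
#' * `out_of_window_spike` — spike stocks diluted 100x, pushing the
#'   expected spike fraction below 0.1%.
#'
#' @param name One of the scenario names above.
#' @param ... Overrides forwarded to [sim_params()].
#' @return A `sim_params` object.
#' @export
scenario_suite <- function(name, ...) {
  valid <- c("baseline", "low_biomass", "biased_amplification",
             "out_of_window_spike")
  if (!is.character(name) || length(name) != 1 || !(name %in% valid))
    sq_stop("unknown scenario '", paste(name, collapse = ","),
            "'; valid scenarios: ", paste(valid, collapse = ", "))
  switch(name,
    baseline = sim_params(...),
    low_biomass = {
      sp <- lapply(default_spike_strains(), function(s) {
        s$dna_concentration <- s$dna_concentration / 10
        s
      })
      sim_params(log10_load_mean = c(mother = 9.5, infant = 9.0),
                 spikes = sp, ...)
    },
    biased_amplification = sim_params(spike_bias = c(2, 2), ...),
    out_of_window_spike = {
      sp <- lapply(default_spike_strains(), function(s) {
        s$dna_concentration <- s$dna_concentration / 100
        s
      })
      sim_params(spikes = sp, ...)
    })
}

#' Simulate a spike-in amplicon experiment with known truth
#'
#' Per sample: draw the true total 16S load L (log-normal on log10
#' scale), draw a cell-level genus composition from the group's Dirichlet,
#' convert to gene-copy weights via per-genus GCN and amplification bias,
#' place `L x mass x aliquot/elution` endogenous gene copies in the
#' spiked aliquot alongside the fixed spike doses (times spike bias), and
#' draw reads as a multinomial of the configured depth over those copy
#' expectations. External method measurements are emitted as truth times
#' log-normal noise, with flow cytometry further multiplied by its
#' overestimation factor.
#'
#' @param params A [sim_params()] object.
#' @return List of class `spike_sim`: `cm` ([count_matrix()] including
#'   spike rows), `meta` ([sample_meta()]), `strains`, `doses`, `truth`
#'   (`data.frame` with per-sample true loads, expected spike fraction)
#'   , `composition` (true cell proportions, genus x sample),
#'   `measurements` ([method_measurements()] frame), `params`.
#' @examples
#' sim <- simulate_experiment(sim_params(n_per_group = 3, depth = 2e4,
#'                                       seed = 42))
#' sim$cm
#' @export
simulate_experiment <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  with_seed(p$seed, {
    n <- 2 * p$n_per_group
    ids <- sprintf("S%02d", seq_len(n))
    grp <- rep(p$groups, each = p$n_per_group)
    doses <- lapply(p$spikes, spike_dose,
                    dose_in_16s_copies = p$dose_in_16s_copies)
    dose_copies <- vapply(doses, function(d) d$copies_added, 0)
    spike_taxa <- vapply(p$spikes, function(s) s$taxon_label, "")
    genera <- p$genus_pool$genus
    gcn <- p$genus_pool$gcn
    bias <- p$genus_pool$bias
    aliquot_scale <- p$feces_mass * p$spiked_aliquot_volume / p$elution_volume

    counts <- matrix(0L, nrow = length(genera) + length(spike_taxa), ncol = n,
                     dimnames = list(c(genera, spike_taxa), ids))
    truth <- data.frame(sample_id = ids, group = grp,
                        true_copies_per_g = NA_real_,
                        true_cells_per_g = NA_real_,
                        expected_spike_fraction = NA_real_,
                        stringsAsFactors = FALSE)
    comp <- matrix(NA_real_, nrow = length(genera), ncol = n,
                   dimnames = list(genera, ids))
    meas <- NULL
    for (j in seq_len(n)) {
      L <- 10^stats::rnorm(1, p$log10_load_mean[[grp[j]]], p$log10_load_sd)
      pi_cells <- rdirichlet1(p$genus_pool[[paste0("alpha_", grp[j])]])
      # gene-copy composition: GCN- and bias-weighted cell proportions
      w <- pi_cells * gcn * bias
      w <- w / sum(pi_cells * gcn)  # load stays in true gene copies; bias skews
      E <- L * aliquot_scale        # endogenous gene copies in the aliquot
      expect <- c(E * w, dose_copies * p$spike_bias)
      if (p$depth > 0)
        counts[, j] <- as.integer(stats::rmultinom(1, p$depth,
                                                   expect / sum(expect)))
      comp[, j] <- pi_cells
      truth$true_copies_per_g[j] <- L
      truth$true_cells_per_g[j] <- L / sum(pi_cells * gcn)
      truth$expected_spike_fraction[j] <- sum(dose_copies * p$spike_bias) /
        sum(expect)
    }
    cells <- truth$true_cells_per_g
    meas <- rbind(
      method_measurements(ids, "qpcr",
        truth$true_copies_per_g * 10^stats::rnorm(n, 0, p$qpcr_sigma)),
      method_measurements(ids, "flow_cytometry",
        cells * p$flow_factor * 10^stats::rnorm(n, 0, p$flow_sigma)),
      method_measurements(ids, "plate_count",
        cells * 10^stats::rnorm(n, 0, p$plate_sigma)))
    meta <- sample_meta(ids, grp, p$feces_mass, p$elution_volume,
                        p$spiked_aliquot_volume)
    structure(list(cm = count_matrix(counts, spike_taxa = spike_taxa,
                                     allow_empty = p$depth == 0),
                   meta = meta, strains = p$spikes, doses = doses,
                   truth = truth, composition = comp,
                   measurements = meas, params = p),
              class = "spike_sim")
  })
}

#' @export
print.spike_sim <- function(x, ...) {
  cat(sprintf("spike_sim: %d samples (%s), depth %s, seed %s\n",
              ncol(x$cm$counts),
              paste(x$params$groups, collapse = "/"),
              format(x$params$depth, big.mark = ","),
              format(x$params$seed)))
  print(x$cm)
  invisible(x)
}

#' Write a simulated experiment as an input bundle
#'
#' Writes `counts.tsv`, `meta.tsv`, `spikes.yaml`, `truth.tsv` and
#' `measurements.tsv` to a directory, ready for the `quantify` /
#' `analyze` pipeline stages.
#'
#' @param sim A [simulate_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "spike_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(sim$cm, file.path(dir, "counts.tsv"))
  write_sample_meta(sim$meta, file.path(dir, "meta.tsv"))
  write_spike_config(sim$strains, file.path(dir, "spikes.yaml"),
                     dose_in_16s_copies = sim$params$dose_in_16s_copies)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$measurements, file.path(dir, "measurements.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
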