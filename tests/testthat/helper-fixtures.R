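# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

toy_counts <- function() {
  matrix(c(500L, 300L, 100L,
           200L, 100L, 50L),
         nrow = 3,
         dimnames = list(c("Blautia", "Bifidobacterium", "Planococcus"),
                         c("S1", "S2")))
}

toy_cm <- function() count_matrix(toy_counts(), spike_taxa = "Planococcus")

toy_meta <- function(ids = c("S1", "S2"),
                     group = c("mother", "infant")) {
  sample_meta(ids, group,
              feces_mass = 0.2, elution_volume = 200,
              spiked_aliquot_volume = 20)
}

# a single-strain dose with round numbers: copies_added == 2e6
toy_dose <- function(copies = 2e6, taxon = "Planococcus",
                     name = "Planococcus sp.") {
  # invert the mass formula so copies_added is exactly `copies` at 1000 bp
  mass <- copies * 1000 * 660 * 1e9 / 6.022e23
  spike_dose(spike_strain(name, taxon, dna_concentration = mass,
                          volume_added = 1, reference_length = 1000))
}

# cm with two spike strains and one endogenous taxon, fully specified reads
two_spike_cm <- function(taxon_reads = 500, r1 = 100, r2 = 300,
                         n_samples = 1) {
  m <- matrix(rep(c(taxon_reads, r1, r2), n_samples), nrow = 3,
              dimnames = list(c("Blautia", "SpikeA", "SpikeB"),
                              paste0("S", seq_len(n_samples))))
  storage.mode(m) <- "integer"
  count_matrix(m, spike_taxa = c("SpikeA", "SpikeB"))
}

two_spike_doses <- function(c1 = 2e6, c2 = 6e6) {
  list(toy_dose(c1, "SpikeA", "strainA"), toy_dose(c2, "SpikeB", "strainB"))
}

# identity-scaling metadata: elution == aliquot, mass 1 g
identity_meta <- function(ids) {
  sample_meta(ids, rep("g", length(ids)), feces_mass = 1,
              elution_volume = 20, spiked_aliquot_volume = 20)
}

fast_sim <- function(seed = 1, n_per_group = 3, depth = 2e4, ...) {
  simulate_experiment(sim_params(n_per_group = n_per_group, depth = depth,
                                 seed = seed, ...))
}
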