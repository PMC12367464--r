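# Mass-to-copies arithmetic: expected values computed independently as
# mass * Avogadro / (length * 660 g/mol/bp * 1e9 ng/g).

test_that("copies_from_mass reproduces hand-computed values", {
  expect_identical(copies_from_mass(0, 12345), 0)
  # 1 ng of 1000 bp dsDNA: 6.022e23 / (1000 * 660 * 1e9) = 9.1242e8
  expect_equal(copies_from_mass(1, 1000), 9.1242e8, tolerance = 1e-3)
  # the study's Pseudoalteromonas dose: 2.5 uL x 4.31 ng/uL at genome scale
  expect_equal(copies_from_mass(10.775, 4.238e6), 2.32e6, tolerance = 1e-3)
  # and the Planococcus dose: 2.5 uL x 9.59 ng/uL
  expect_equal(copies_from_mass(23.975, 3.652e6), 5.99e6, tolerance = 1e-3)
  expect_error(copies_from_mass(1, 0), "length_bp")
  expect_error(copies_from_mass(-1, 100), "mass_ng")
})

test_that("spike_dose converts stock to copies with optional 16S dosing", {
  st <- spike_strain("s", "T", dna_concentration = 1, volume_added = 1,
                     reference_length = 1000, gcn = 4)
  expect_equal(spike_dose(st)$copies_added, 9.1242e8, tolerance = 1e-3)
  expect_equal(spike_dose(st, dose_in_16s_copies = TRUE)$copies_added,
               4 * spike_dose(st)$copies_added)
  st0 <- spike_strain("s", "T", 1, 0, 1000)
  expect_warning(d0 <- spike_dose(st0), "zero spike dose")
  expect_identical(d0$copies_added, 0)
})

test_that("spike fraction QC applies the 0.1%-10% window", {
  mk <- function(spike, total) {
    m <- matrix(as.integer(c(total - spike, spike)), nrow = 2,
                dimnames = list(c("A", "Sp"), "S1"))
    count_matrix(m, spike_taxa = "Sp", allow_empty = TRUE)
  }
  expect_equal(spike_fraction_qc(mk(3000, 100000))$qc_flag, "pass")
  expect_equal(spike_fraction_qc(mk(3000, 100000))$spike_fraction, 0.03)
  expect_equal(spike_fraction_qc(mk(50, 100000))$qc_flag, "fail_low")
  expect_equal(spike_fraction_qc(mk(20000, 100000))$qc_flag, "fail_high")
  expect_equal(spike_fraction_qc(mk(0, 100000))$qc_flag, "no_spike_reads")
  empty <- count_matrix(matrix(c(0L, 0L), 2,
                               dimnames = list(c("A", "Sp"), "S1")),
                        spike_taxa = "Sp", allow_empty = TRUE)
  expect_error(spike_fraction_qc(empty), "zero total reads")
})

test_that("absolute abundance reproduces the hand-computed scale chain", {
  # reads 500, spike reads 100, 2e6 copies, elution 200, aliquot 20, 0.2 g:
  # (500/100) * 2e6 * (200/20) / 0.2 = 5e8 copies/g
  m <- matrix(c(500L, 0L, 100L), nrow = 3,
              dimnames = list(c("Blautia", "Veillonella", "Planococcus"),
                              "S1"))
  cm <- count_matrix(m, spike_taxa = "Planococcus")
  meta <- toy_meta("S1", "mother")
  fit <- absolute_abundance(cm, meta, toy_dose(2e6))
  expect_equal(fit$abundance["Blautia", "S1"], 5e8, tolerance = 1e-6)
  expect_identical(fit$abundance["Veillonella", "S1"], 0)
  expect_false("Planococcus" %in% rownames(fit$abundance))

  # identity scaling: elution == aliquot, 1 g, reads == spike reads
  m2 <- matrix(c(100L, 100L), nrow = 2,
               dimnames = list(c("Blautia", "Planococcus"), "S1"))
  cm2 <- count_matrix(m2, spike_taxa = "Planococcus")
  fit2 <- absolute_abundance(cm2, identity_meta("S1"), toy_dose(1e6))
  expect_equal(fit2$abundance["Blautia", "S1"], 1e6)
})

test_that("samples without spike reads are flagged, never imputed", {
  m <- matrix(c(500L, 100L, 300L, 0L), nrow = 2,
              dimnames = list(c("Blautia", "Planococcus"), c("S1", "S2")))
  cm <- count_matrix(m, spike_taxa = "Planococcus")
  fit <- absolute_abundance(cm, toy_meta(), toy_dose())
  expect_equal(fit$qc$qc_flag[2], "no_spike_reads")
  expect_true(is.na(fit$scale_factor["S2"]))
  expect_true(all(is.na(fit$abundance[, "S2"])))
  expect_false(anyNA(fit$abundance[, "S1"]))
})

test_that("scale factors are linear and dose-doubling invariant", {
  set.seed(71)
  for (case in 1:200) {
    n_taxa <- sample(2:6, 1)
    reads <- matrix(rpois(n_taxa, 200) + 1L, ncol = 1)
    r_s <- sample(50:500, 1)
    C_s <- runif(1, 1e5, 1e8)
    m <- rbind(reads, r_s)
    dimnames(m) <- list(c(paste0("T", seq_len(n_taxa)), "Sp"), "S1")
    storage.mode(m) <- "integer"
    cm <- count_matrix(m, spike_taxa = "Sp")
    meta <- sample_meta("S1", "g", runif(1, 0.05, 1), 200, 20)
    fit <- absolute_abundance(cm, meta, toy_dose(C_s, "Sp"))
    # linearity: value / reads constant == scale factor
    ratio <- fit$abundance[, 1] / reads[, 1]
    expect_equal(unname(ratio), rep(unname(fit$scale_factor), n_taxa),
                 tolerance = 1e-12)
    # dose invariance: double copies and observed spike reads
    m2 <- m; m2["Sp", 1] <- 2L * m["Sp", 1]
    cm2 <- count_matrix(m2, spike_taxa = "Sp")
    fit2 <- absolute_abundance(cm2, meta, toy_dose(2 * C_s, "Sp"))
    expect_equal(fit2$abundance, fit$abundance, tolerance = 1e-12)
  }
})

test_that("pooling strategies agree when per-strain dose/read ratios match", {
  set.seed(72)
  for (case in 1:50) {
    r1 <- sample(50:400, 1); r2 <- sample(50:400, 1)
    ratio <- runif(1, 1e3, 1e6)
    cm <- two_spike_cm(taxon_reads = sample(100:1000, 1), r1 = r1, r2 = r2)
    doses <- two_spike_doses(c1 = r1 * ratio, c2 = r2 * ratio)
    meta <- identity_meta("S1")
    f_sum <- absolute_abundance(cm, meta, doses, pooling = "sum")
    f_mean <- absolute_abundance(cm, meta, doses, pooling = "mean")
    f_one <- suppressWarnings(absolute_abundance(cm, meta, doses[1]))
    expect_equal(f_sum$abundance, f_mean$abundance, tolerance = 1e-9)
    expect_equal(f_sum$abundance, f_one$abundance, tolerance = 1e-9)
  }
})

test_that("pooling diagnostic reports per-strain agreement and discordance", {
  # consistent doses: both strains imply 1e7, discordance 0
  cm <- two_spike_cm(taxon_reads = 500, r1 = 100, r2 = 300)
  d <- pooling_diagnostic(cm, two_spike_doses(2e6, 6e6))
  expect_equal(d$est_SpikeA, 1e7)
  expect_equal(d$est_SpikeB, 1e7)
  expect_equal(d$pooled, 1e7)
  expect_equal(d$discordance, 0)

  # halving strain-2 reads doubles its estimate; |discordance| = ln 2
  cm2 <- two_spike_cm(taxon_reads = 500, r1 = 100, r2 = 150)
  d2 <- pooling_diagnostic(cm2, two_spike_doses(2e6, 6e6))
  expect_equal(d2$est_SpikeB, 2e7)
  expect_equal(d2$pooled, (500 / 250) * 8e6)
  expect_equal(abs(d2$discordance), log(2), tolerance = 1e-12)

  expect_error(pooling_diagnostic(cm, two_spike_doses()[1]),
               "requires >=2 strains")
  # zero reads for one strain flags the sample
  cm3 <- two_spike_cm(taxon_reads = 500, r1 = 0, r2 = 300)
  d3 <- pooling_diagnostic(cm3, two_spike_doses())
  expect_true(is.na(d3$est_SpikeA))
  expect_equal(d3$flag, "zero_spike_reads")
})

test_that("GCN correction divides copies by gene copy number", {
  m <- matrix(c(500L, 100L), nrow = 2,
              dimnames = list(c("Blautia", "Planococcus"), "S1"))
  cm <- count_matrix(m, spike_taxa = "Planococcus")
  fit <- absolute_abundance(cm, toy_meta("S1", "mother"), toy_dose(2e6))
  expect_equal(fit$abundance["Blautia", "S1"], 5e8)
  cfit <- gcn_correct(fit, c(Blautia = 4))
  expect_equal(cfit$cells["Blautia", "S1"], 1.25e8)
  expect_equal(total_load(cfit, "cells"), total_load(cfit) / 4)
  # gcn 1 is the identity
  expect_equal(gcn_correct(fit, c(Blautia = 1))$cells, fit$abundance)
  # missing taxon falls back to the default and is flagged
  miss <- gcn_correct(fit, c(Other = 4), default = 1)
  expect_equal(miss$cells["Blautia", "S1"], fit$abundance["Blautia", "S1"])
  expect_true(miss$gcn_flags[["Blautia"]])
  expect_error(gcn_correct(fit, c(Blautia = 0)), "GCN")
})

test_that("spike reads correlate inversely with estimated load in simulation", {
  for (seed in 1:3) {
    sim <- fast_sim(seed = seed, n_per_group = 6,
                    log10_load_sd = 0.5)  # loads spanning ~2 logs
    fit <- absolute_abundance(sim$cm, sim$meta, sim$doses)
    rep <- spike_load_correlation(sim$cm, fit)
    expect_equal(nrow(rep), 2)
    expect_true(all(rep$estimate < 0))
  }
  # fewer than 3 usable samples is an error
  sim <- fast_sim(seed = 1, n_per_group = 1)
  fit <- absolute_abundance(sim$cm, sim$meta, sim$doses)
  expect_error(spike_load_correlation(sim$cm, fit), ">=3")
})

test_that("a constant-load cohort yields a flagged, undefined correlation", {
  # exactly constant spike reads: no variance in x, coefficient undefined
  g <- gated_correlation(rep(100, 5), c(1, 2, 3, 4, 5))
  expect_identical(g$flag, "constant_input")
  expect_true(is.na(g$estimate))
})
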