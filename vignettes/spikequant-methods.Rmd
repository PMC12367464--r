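---
title: "Spike-in absolute quantification: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-in absolute quantification: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikequant)
```

## The quantification model

Amplicon read counts are compositional: only the within-sample
proportions are informative, and the total microbial load is lost at
library preparation. `spikequant` restores the absolute scale with an
internal calibrant — exogenous bacterial DNA of known molecule count
added to each sample's extracted DNA. Because the calibrant passes
through the same PCR and sequencing as the endogenous community, its
read count measures the (unknown) copies-per-read conversion of that
sample.

The molecule dose of a spike strain follows from its DNA mass and the
mean molar mass of double-stranded DNA (660 g/mol per base pair):

$$C = \frac{m\,[\mathrm{ng}] \times 6.022\times10^{23}}
           {L\,[\mathrm{bp}] \times 660 \times 10^{9}}.$$

For sample $s$, with pooled spike reads $r_s$ and pooled dose $C_s$,
every endogenous taxon $t$ is scaled by a per-sample
back-normalization factor:

$$\widehat{A}(t,s) = n(t,s)\,\underbrace{\frac{C_s}{r_s}}_{\text{copies/read}}
  \times \frac{V_\mathrm{elution}}{V_\mathrm{aliquot}}
  \times \frac{1}{m_\mathrm{feces}}
  \quad [\text{16S copies / g}].$$

The aliquot term rests on a conservation argument: the spiked aliquot
is a homogeneous fraction $V_\mathrm{aliquot}/V_\mathrm{elution}$ of
the whole eluate, so copies observed in the aliquot scale up linearly.
Dividing by the wet mass extracted expresses load per gram of sample.

Assumptions, in decreasing order of importance:

1. **Equal amplification efficiency** between spike and endogenous DNA.
   A uniform spike-specific bias $b$ multiplies *every* estimate by
   $1/b$ — a systematic, not random, error that cancels in cross-group
   comparisons (demonstrated by the `biased_amplification` simulation
   scenario, where a 2× spike bias produces loads uniformly
   $\approx0.5\times$ truth).
2. **The spike taxa are absent from the endogenous community**, so
   their genus-level read counts are pure calibrant signal. The package
   therefore identifies spikes by exact taxonomy label from the
   configuration, never by name heuristics.
3. **Homogeneous eluate** (the conservation argument above).
4. **Counting statistics**: reads are treated as a multinomial draw
   over copy abundances; with spike reads in the recommended window the
   relative error contributed by $r_s$ is a few percent at typical
   depths.

No pseudocounts are used anywhere in quantification: zero reads map to
zero copies, and a sample with zero spike reads has no defensible scale
factor — it is flagged `no_spike_reads` and excluded, never imputed.

### Dose basis

The mass-to-copies formula references the length of the dosed molecule.
For genomic spike DNA the genome length is the physically meaningful
choice and is the package default (`dose_basis` via
`reference_length`); an amplicon-scale length is equally supported by
supplying it as `reference_length`. Whether a dose should additionally
be expressed in 16S gene copies (genome copies × the strain's GCN)
depends on whether downstream loads are interpreted as gene copies
calibrated against genome equivalents; both conventions appear in
practice, so `spike_dose(dose_in_16s_copies =)` exposes the switch
explicitly, defaulting to genome copies. With the bundled reference
lengths (4.238 and 3.652 Mb) the two default strains dose 2.32×10⁶ and
5.99×10⁶ genome copies per aliquot.

### Multi-spike pooling

With $k$ spike strains, the default estimator pools by **summing**
reads and summing copies ($C_s = \sum_i C_i$, $r_s = \sum_i r_i$) — a
read-weighted combination that is robust to one strain dropping to low
counts. Mean pooling (average of per-strain copies-per-read ratios) is
available; when per-strain dose/read ratios agree, sum-pooling,
mean-pooling and each single strain give identical estimates (a tested
invariant). `pooling_diagnostic()` always reports the per-strain
estimates and their log-ratio discordance so strain-specific
amplification problems are visible rather than silently averaged away.

### Quality control

The spike-read fraction is checked against the recommended 0.1%–10%
window (`spike_fraction_qc()`, bounds configurable): below it the scale
factor is dominated by counting noise; above it the spike has displaced
a substantial share of endogenous reads. Flags are `pass`, `fail_low`,
`fail_high`, `no_spike_reads`; flagged samples are retained in the QC
table, and only `no_spike_reads` voids the estimate.

### GCN correction

Loads are natively in 16S gene copies per gram. `gcn_correct()` divides
each taxon by its 16S gene copy number (e.g. rrnDB genus means) to give
cells per gram; taxa without an entry use a configurable default
(1) and are flagged. GCN tables are themselves genus-level
approximations — the cells layer is an interpretation aid, not a
primary estimate.

## The gated statistical engine

Group comparisons follow a deterministic, seed-free decision tree in
which Shapiro–Wilk normality checks (and, for three or more groups,
Levene's mean-centered variance-homogeneity check) select the branch at
the conventional $P > 0.05$ gate (configurable in code, deliberately
not on the command line):

* two groups: both normal → Student's independent-samples t-test;
  otherwise the two-sided Mann–Whitney U. A constant group cannot pass
  a normality check and routes non-parametric.
* $k \ge 3$ groups: all gates pass → a parametric flavor chosen by
  `posthoc_family` — classic one-way ANOVA with Tukey HSD, or Welch's
  ANOVA with Games–Howell pairwise tests (the default for
  method-comparison analyses, whose unequal variances across
  quantification methods are the expected case); any gate fails →
  Kruskal–Wallis.
* correlation: both variables normal → Pearson; otherwise Spearman.

Shapiro–Wilk, Levene, the t/ANOVA/Kruskal machinery and correlation
tests are delegated to established routines (`stats`, `car`); the
package's contribution is the gating logic plus two pieces that are not
available as specified elsewhere: Games–Howell pairwise comparisons
(Welch-Satterthwaite degrees of freedom against the studentized range)
and a Wilcoxon rank-sum test that enumerates the exact permutation
distribution whenever the combined sample size is ≤ 10 with no ties,
falling back to the tie- and continuity-corrected normal approximation
otherwise. Exact and approximate P differ by < 0.02 at combined
$n = 10$ (tested), and the implementations are cross-checked against an
independent statistical stack on fixed vectors.

Per-genus differential-abundance scans report unadjusted Wilcoxon P
values with significance stars — the convention of the analyses this
package accompanies — with Benjamini–Hochberg adjustment available
behind a flag (`bh = TRUE`), which is the defensible default for
larger genus panels.

Method-comparison tests are run on both raw and log10 loads in the
`compare` pipeline output; microbial loads span orders of magnitude, so
the log scale is usually the interpretable one, but the choice is left
to the reader.

## Downstream relative-vs-absolute analyses

The point of absolute quantification is what it changes downstream, so
every analysis runs on both bases:

* **Top-N rankings** (`top_taxa()`) sum values over the pooled cohort
  or within one group; ties break by value then label, so rankings are
  deterministic. When per-sample scale factors are equal the relative
  and absolute rankings must agree (tested); when loads differ between
  groups, pooled absolute rankings tilt toward the high-load group —
  which is why the per-group scope exists.
* **Differential abundance** on proportions versus copies/g can
  disagree in both directions; two constructed fixtures in the test
  suite demonstrate each direction mechanically (a taxon with equal
  copies/g whose proportion is diluted by a load difference, and a
  taxon with equal proportions riding a 3× load difference).
* **Alpha diversity** (Shannon, and Chao1 on raw spike-excluded
  integer reads) is invariant to per-sample scaling, so it must be
  identical between bases — an exact, tested property. Chao1 refuses
  non-integer input: singleton/doubleton counts are meaningless after
  scaling. Spike rows are always removed before any diversity
  computation; the calibrant is not part of the community.
* **Beta diversity**: Bray–Curtis on proportions (relative basis) or
  copies/g directly (absolute basis — deliberately not re-normalized,
  so load differences contribute to dissimilarity). PCoA is classical
  scaling; negative eigenvalues are reported and excluded from the
  explained-variance denominator by default. PERMANOVA uses the
  among/within partition of squared distances with
  $P = (1 + \#\{F_\pi \ge F\})/(1 + n_\mathrm{perm})$, 999 label
  permutations by default and an explicit seed; the permutation
  distribution matches exhaustive enumeration on small designs
  (tested against an independent implementation).

## The simulator

`simulate_experiment()` generates the full input bundle with known
truth. Defaults encode the emulated study conditions: two groups
("mother"/"infant") of six samples; total 16S loads log-normal with
log10 means 11.0 and 10.5 (the ~half-log gap) and SD 0.3; 15-genus
pools with group-specific Dirichlet concentrations mirroring an adult
community (Blautia, Faecalibacterium, Coprococcus, Subdoligranulum,
Anaerostipes, Ruminococcus, Bacteroides) versus an early-life one
(Bifidobacterium, Escherichia-Shigella, Veillonella, Streptococcus,
Enterobacter, Erysipelatoclostridium); two spike strains dosed at
2.32×10⁶ / 5.99×10⁶ copies into a 20 µL aliquot of a 200 µL eluate from
0.2 g feces; 5×10⁴ reads per sample.

Loads are parameterised directly as total 16S copies/g — the quantity
the estimator recovers. Genus GCNs shape the gene-copy *composition*
(reads count gene copies, not cells) and the cells/g layer, but the
normalisation keeps the total load at its stated log-normal value, so
the load distribution does not silently depend on the GCN table. Reads
are a single multinomial draw per sample over GCN- and bias-weighted
copy expectations, so reads sum exactly to depth and, at depth
$\to\infty$, proportions converge to the weighted truth (tested at
10⁶). External measurements are truth × log-normal noise: qPCR
σ = 0.05 log10 on copies; plate counts σ = 0.2 log10 on cells; flow
cytometry σ = 0.15 log10 on cells times an overestimation factor of 7,
reproducing the reported ordering flow > plate > qPCR ≈ spike-in.

Scenario presets (`scenario_suite()`): `baseline`; `low_biomass`
(log10 means 9.5/9.0 with spike stocks diluted 10× to stay in-window —
chosen so that genera below the ~10⁵ copies/g detection threshold are
mostly observed as zeros at 5×10⁴ reads, the regime the preset
documents); `biased_amplification` (spike bias 2×); and
`out_of_window_spike` (stocks diluted 100×, expected spike fraction
below 0.1%). Bias magnitudes are illustrative presets, not estimates.

What the simulator does *not* emulate — and hence what passing tests do
not certify about real data: differential DNA extraction efficiency
between gram types (acknowledged as a wet-lab confounder; the estimator
does not correct it), chimeras and denoising artefacts, taxonomy
misassignment, overdispersion beyond multinomial (no Dirichlet
resampling at the read stage), and contamination of the spike genera in
the sample. A real cohort will therefore show weaker recovery than the
simulation's r ≳ 0.99.

All draws flow from one seeded generator confined with an
save/restore of the RNG state, so simulations are bit-reproducible and
do not disturb the caller's RNG.

## Numerical choices and degenerate inputs

* Validation is total at the readers: counts must be whole and
  non-negative (errors carry coordinates), labels unique, physical
  quantities strictly positive, aliquot ≤ eluate, spike labels must
  resolve. No invalid object can be constructed through the readers.
* Scale factors are exact ratios in double precision; report files
  round to 4 significant digits, data files keep full precision.
* Standard curves with slope ≥ 0 are flagged invalid and refuse
  conversion; efficiency outside [0.9, 1.1] warns. Triplicate Ct values
  are averaged (SD reported) before conversion — the conventional
  aggregation.
* Chao1 uses the bias-corrected form by default (defined at $F_2 = 0$);
  the classic form is available and falls back with a warning when
  undefined.
* Ranking ties break deterministically (value desc, then label);
  floating-point scaling by non-representable constants can still
  reorder *exact* ties, which is why the tested invariance uses exactly
  representable factors.
* Problem sizes in the test and acceptance runs (cohorts of 24 samples
  at 5×10⁴ reads, 20–100 replicates, 2 000 null simulations, 999
  permutations) were chosen as the smallest designs at which every
  property is comfortably resolvable; all scale linearly if larger runs
  are wanted.

## Known limitations

Beyond the simulator's idealisations above: the method cannot see taxa
below the sequencing detection threshold (≈10⁵ copies/g at typical
depths — qPCR remains more sensitive for single targets); it measures
gene copies, so between-genus cell comparisons inherit GCN
uncertainty; and marine-derived calibrants are unsuitable for habitats
where related genera occur endogenously (marine/environmental samples).
The package deliberately excludes read-level processing (denoising,
taxonomy assignment) and compositional differential-abundance models —
its inputs are the count tables such pipelines produce.
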