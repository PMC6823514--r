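---
title: "Dating sex chromosome turnovers with male mutation bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating sex chromosome turnovers with male mutation bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Spermatogenesis involves many more genome replications than oogenesis, so
most point mutations arise in males. The strength of this male mutation bias
is summarized by `alpha`, the ratio of male to female mutation rates. Because
chromosomes differ in how much evolutionary time they spend in males -- the Y
always, autosomes half, the X one third -- their neutral substitution rates
differ in a way that encodes `alpha`. Writing `X`, `Y`, `A` for the per-site
substitution rates of X-linked, Y-linked and autosomal sequences, Miyata's
classic expectations are

    X/A = 2(2 + alpha) / (3(1 + alpha))
    Y/A = 2 alpha / (1 + alpha)
    Y/X = 3 alpha / (2 + alpha)

and each ratio can be inverted for `alpha` (`alpha_yx()`, `alpha_ya()`,
`alpha_xa()`; `expected_ratio()` gives the forward direction). All three
equal 1 exactly when rates are equal: no bias.

The same physics leaves a historical footprint. A sequence that was X-linked
for `T` Myr accumulated fewer substitutions than an autosomal one -- a
deficit that persists after the chromosome reverts to autosomal inheritance
following a sex chromosome turnover. The package's second analysis exploits
this: branch lengths observed today are compared against branch lengths
simulated under scenarios in which a focal lineage retained an ancestral X
for `T = 0, 10, 20, ...` Myr, and the retention times whose simulated
interval overlaps the observed one form the inferred window. The loss date
is the system age minus that window; rejection of the `T = 0` scenario is
the evidence that the lineage carried the system at all.

## Estimating alpha from intronic rates

`estimate_alpha()` takes pairwise intronic alignments from two species,
labelled X, Y or A. Filters are applied first (`filter_introns()`), in a
fixed order: the first intron of each gene is dropped (it is enriched in
regulatory elements), 20 nt are trimmed from each intron end (splice signals
and enhancers), columns with gaps or ambiguity are masked, detectable CpG
sites are removed (hypermutable, so they cloud the X/Y/A contrast), and
genes with at most 1,000 retained columns are discarded. Each filter reports
its removals; the audit ledger conserves column counts exactly.

Two definitional choices deserve a note. "Detectable CpG" is a C followed by
a G in *either* sequence, assessed on the clean (unmasked) columns and
iterated to a fixpoint. The fixpoint matters: a single pass over `CCGG`
leaves a fresh `CG` behind, so one-pass removal is not idempotent. Assessing
adjacency on clean columns makes the CpG and ambiguity masks commute, so the
fixed filter order is not load-bearing for the surviving site set.

Rates are Tamura-Nei (TN93) distances on the per-class concatenates, with
uncertainty from a nonparametric double bootstrap (1,000 replicates by
default): introns are resampled with replacement to the original intron
count, then columns are resampled within the concatenated resample to the
original column count. Because TN93 depends on the data only through
column-category counts, both resampling stages are performed as exact
multinomial draws on counts, which is why the full double bootstrap costs
milliseconds. Saturated replicates (a correction logarithm with
non-positive argument) are excluded and counted rather than truncated, so
medians are not silently pulled toward a ceiling.

Point estimates apply the Miyata equations to the median rates; intervals
transform the bootstrap replicates pairwise (matched by replicate index) and
take 2.5/97.5 percentiles. The percentile convention, and the
introns-then-sites resampling order, are package choices where the
literature leaves the mechanism unstated. Out-of-domain replicates (pole
crossings, `alpha < 1`) are flagged, not clipped.

## Dating a turnover

`turnover_scan()` chains the full comparison:

1. **Observed side.** In-frame codon alignments of the X-linked ortholog set
   are concatenated; each codon-bootstrap replicate (100 by default)
   resamples whole codons, computes pairwise synonymous distances, fits
   branch lengths on the fixed species topology, and accumulates each
   measured species' branches from the measured clade's common ancestor so
   all species span the same amount of time. The synonymous distance is TN93
   on doubly fourfold-degenerate third codon positions -- positions whose
   codon prefix is identical in both sequences and belongs to a
   fourfold-degenerate family -- a closed-form neutral-site proxy for a
   codon-model dS. This is a deliberate simplification: no codon
   substitution model is fitted anywhere in the package. When an autosomal
   ortholog set is supplied, X-linked lengths are corrected by each species'
   deviation from the mean autosomal length (`autosomal_correction()`),
   replicate-wise; a fast lineage is shortened, a slow one stretched, and
   corrections sum to zero by construction. A ratio-form correction exists
   behind an argument but the subtractive form is the default.
2. **Simulated side.** The time-calibrated tree is converted to expected
   substitutions at `mu = 2.22e-9` per site per year. (That constant is
   quoted in the source literature as "per million years", but only the
   per-year reading reproduces its own arithmetic, e.g. 180 Myr = 0.4
   substitutions/site; the package adopts per-year.) Each scenario shortens
   the focal lineage's branches by the male-bias deficit accumulated over
   its retention window, distributed over branches in proportion to their
   overlap with the window in time; branches ancestral to several focal tips
   use the mean alpha of their focal descendants. The default `paper_linear`
   calibration anchors the deficit at 0.0227 substitutions/site per 10 Myr
   for `alpha = 6` and scales linearly in alpha, reproducing the published
   companion constants 0.0091 (`alpha = 2.4`) and 0.0151 (`alpha = 4`); a
   `miyata` mode derives the deficit from the X/A ratio instead
   (`mu * T * (alpha - 1) / (3(1 + alpha))`), which is about four times
   smaller -- the two calibrations are genuinely different claims and both
   are exposed. Branches driven below 1e-6 substitutions/site are clamped
   there and reported; with `alpha = 6` over a full 170-Myr retention the
   linear calibration over-shoots short pendant branches, so clamping is
   expected, not exceptional. Sequences (3,000 nt by default; uniform base
   composition) evolve under HKY or GTR with the transition matrix computed
   by eigendecomposition of the reversible rate matrix, scaled to one
   expected substitution per site per unit branch length.
3. **Overlap scan.** Observed intervals are bootstrap percentiles; simulated
   intervals are Welch 95% intervals over replicate means. Before
   intersection the two sides are put on a common scale using a reference
   group that no scenario touches (e.g. snakes). The default compares
   reference-normalized ratios, replicate by replicate on both sides, so
   composition differences between real and simulated sequences cancel by
   construction and the reference group's own sampling noise widens both
   intervals honestly; a simpler global median-ratio rescaling
   (`rescale_simulated()`) is available as `scale = "factor"`. The scan
   reports, per focal lineage, every scenario's intervals, the overlap set,
   its minimal covering interval `[T_min, T_max]`, the implied loss dates,
   and null-scenario compatibility. Non-contiguous overlap sets are reported
   verbatim and flagged rather than bridged.

Scenario grids put the null (`T = 0`) plus one scenario per 10 Myr up to
`t_max`. `t_max` defaults to the system age but the shipped designs cap it
at the focal lineage's own age -- a lineage cannot have retained a system
for longer than it has existed -- which is how the squamate design arrives
at 16 scenarios for a 170-Myr-old system (focal cap 150 Myr) and the mammal
design at 18 for a 180-Myr-old one (cap 170 Myr).

## Branch lengths from distances

Branch lengths on the fixed species topology are least squares on the
path-indicator design matrix, with negative estimates clamped to zero and
the remainder refit (active-set passes). Additive matrices are recovered
exactly. With a binary root the two root branches appear in paths only
together, so they are fit as one merged parameter and split in proportion to
the input tree's lengths; nothing downstream depends on that split because
cumulative lengths are measured from ancestors below the root. The pipeline
default applies Fitch-Margoliash `1/d^2` weights: distances to distant
outgroups sit near saturation, where the TN93 variance is large, and
unweighted least squares lets that noise leak into the shallow branches
being measured. Plain OLS remains the exported default for the standalone
function.

## The synthetic-data generators

Nothing in the package requires real genomes; the generators produce inputs
with the statistical structure the estimators assume, plus a machine-readable
truth record (`truth_report()`).

`gen_intron_dataset()` draws two-species intron sets. Class rates derive
from the Miyata inverses -- the generator and the estimator share only that
algebra, so recovery is a genuine round trip through sequence space.
Defaults: 77 genes per class, 4 introns of 500-1,500 nt per gene, a 15-Myr
split (class distances 0.05-0.12 substitutions/site), CpG-depleted roots
with CG decoys injected at 0.02 starts/site, first introns and 20-nt flanks
at 0.3 times the neutral rate. The split depth is a calibration choice:
the CpG mask deletes columns *conditionally on their evolved content*, so at
deep divergence it removes mismatch-enriched columns at class-dependent
rates and biases the Y-based ratios upward by several percent -- measurable
at a 110-Myr split (the depth of the real iguana comparison), negligible at
the default depth. The `divergence_myr` and `cpg_mult` arguments reach the
deep/hypermutable regimes for stress testing; the limitation is real and
applies to CpG-masked real data too.

`gen_codon_dataset()` evolves multi-taxon in-frame genes along a
scenario-transformed tree: third positions of fourfold-degenerate codons at
the full branch lengths, codon prefixes and non-degenerate codons at 0.05
times (so amino-acid structure is realistic and the fourfold extraction has
non-trivial work). Defaults: 77 genes of 333 codons, 70% fourfold families.

What the generators do *not* emulate: GC-content landscapes and
context-dependent mutation, recombination, selection on synonymous sites,
indels and alignment error, rate heterogeneity across sites or lineages, and
hidden exons. Passing recovery tests therefore demonstrates internal
consistency of the method under its own assumptions, not robustness to
those realities.

## Reproducibility and numerical choices

Every stochastic routine takes a seed; batch runs derive per-(scenario,
replicate) substreams with `derive_seed()`, a 31-bit linear-congruential
hash, so outputs are bit-identical across runs and independent of execution
order. Output tables carry the package version, a configuration hash and the
master seed. TN93 saturation is flagged (`NA`), never truncated. The
matrix exponential is exact via the symmetrized eigendecomposition (no ODE
stepping). Ties and degenerate cases: constant samples give degeneracy
flags from the Welch helpers instead of errors; width-zero bootstrap
intervals are legitimate outputs on degenerate data.

The recovery studies run at desk scale by design: the alpha coverage study
uses 200 outer runs of 25 genes per class with 300 bootstrap replicates; the
turnover study uses a 10-taxon tree, 50 genes of 333 codons, 20 simulation
replicates per scenario and 1,000-nt simulated sequences. These sizes are
stated here because they are the package's definition of its own evidence;
the full-size defaults (1,000 bootstrap replicates, 100 simulation
replicates, 3,000-nt sequences) are what `estimate_alpha()` and
`turnover_scan()` use when not told otherwise.

The package exposes its pipelines as R functions (`run_alpha_pipeline()`,
`run_turnover_pipeline()`, `run_demo()`) plus a scripted entry point under
`scripts/`; it is an analysis library, not a shell tool, so no standalone
command-line binary is shipped.

## Known limitations

- The dS proxy ignores codon-level processes (no GY94/MG94, no dN, no
  dN/dS); it is a neutral-site stand-in, adequate for relative branch
  lengths of neutral third positions, silent about selection.
- The CpG mask's conditioning bias (above) grows with divergence; alpha
  estimates from deeply diverged pairs should be read with that in mind.
- The `paper_linear` shortening constants are an external calibration taken
  as given; they are internally inconsistent with the Miyata-derived deficit
  (about 4x larger), and several published companion constants (0.00683 for
  alpha 1.8; the mammal constants 0.0113, 0.122, 0.198, 0.39) cannot be
  reproduced from any single linear anchor -- the package stores them as
  configuration (`published_shortening_constants`) without re-deriving them.
- Interval intersection is a compatibility statement, not a likelihood; the
  scan's resolution is bounded by the 10-Myr grid and by the width of both
  interval types.
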