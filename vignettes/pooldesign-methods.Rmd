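---
title: "Simulating soil sampling designs and pooling strategies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating soil sampling designs and pooling strategies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pooldesign)
```

# The question

Soil metabarcoding surveys differ enormously in how they sample: the number
of soil cores per plot, the area those cores cover, the depth they reach,
and whether cores are processed individually, composited as soil before DNA
extraction ("soil pooling"), or extracted individually and mixed as DNA
before PCR ("DNA pooling"). `pooldesign` provides a spatially explicit
virtual study system in which these choices can be compared under known
ground truth, together with the estimators and tests such comparisons need:
rarefaction and Hill numbers, the pooling-effect ratio, a rectangular
area-subsampling test, PERMANOVA and dispersion homogeneity, molecular
artefact screening, and a processing-cost calculator.

Everything below is implemented in exported functions; the `analysis/`
scripts in the source repository string the stages into one narrative run,
and `scripts/acceptance.R` recomputes the headline quantities from scratch.

# The virtual study system

## Species pools and spatial structure

Each organism group (animal-, fungus-, bacteria-like) is a pool of species
with parameters drawn from group presets (`group_presets()`,
`make_species_pool()`). Horizontal structure is a **Thomas cluster
process**: Poisson-distributed parent clusters with intensity $\kappa$
(parents m$^{-2}$), each with a Poisson($\mu$) number of propagules
displaced by an isotropic Gaussian of standard deviation $\sigma$ (m). This
is the standard minimal model of patchiness: it is stationary, tunable with
three interpretable parameters, and induces the distance decay of community
similarity that motivates multi-core sampling in the first place. Points
falling outside the plot are reflected back inside, which preserves the
uniform marginal intensity and avoids edge-depletion artefacts.

Group presets order richness bacteria > fungi > animals (150, 80, 40
species by default), patchiness animals > fungi > bacteria
($\sigma$ = 1.5, 2, 3 m), and vertical stratification animals > fungi >
bacteria (exponential depth-decay rates 0.10, 0.08, 0.06 cm$^{-1}$ on a
0–40 cm profile). A small fraction of species per group (1.5–5%) are
subsoil specialists whose density instead peaks triangularly at 30–40 cm;
this produces the observed pattern that subsoil samples are species-poor
yet contribute a small unique fraction. None of these magnitudes is an
estimate of any real site; they are chosen once so that the *qualitative*
contrasts a field survey would see (richer and more even bacterial
communities, patchy depauperate animal communities, topsoil dominance)
hold, and the test suite asserts only directions and calibrations, never
absolute richness.

The simulation is deliberately scaled down. A literal 2500 m$^2$ plot
sampled by 2.5 cm-radius cylinders has a core/plot area ratio of about
$8\times10^{-7}$; giving every core a usable propagule count would require
tens of millions of points per species pool. Instead, each simulated
propagule stands for a small colony whose DNA is recoverable in the
neighbourhood of a core, implemented as a capture-footprint multiplier on
the core radius (`capture_scale`, default 20 in the survey layer, i.e. a
0.5 m footprint for a 5 cm core). `take_core()` itself defaults to the
literal cylinder (`capture_scale = 1`), and all geometric contracts
(half-open depth intervals, area scaling with diameter squared, depth
partition additivity) are tested at that default. The footprint affects
absolute catch rates, not the contrasts between designs, which all share
it.

## Sampling designs

`builtin_designs()` encodes the twelve published design geometries (code
`N<subsamples>D<depth range>`): core counts from 5 to 75, areas from 16 to
2500 m$^2$, depths from 0–1 to 30–40 cm, core diameters 5 or 2.5 cm, and
the nested compositing trees of the pooled-only designs (5×5, 3×5×5,
10×5). Areas are modelled as concentric squares (side $\sqrt{A}$) around
the plot centre — the simplest geometry consistent with nested sampling
areas. Core positions are uniform within the design square with a minimum
spacing of twice the core diameter, enforced by rejection; positions are
reproducible from the seed. `N40D0-5A` is generated as an independent
layout by default (a flag to nest it inside `N62D0-5` is not provided
because no analysis here depends on shared physical cores).

## The laboratory model

`lab_config()` holds the wet-lab parameters. The chain is:

1. **Compositing.** Soil pooling (`pool_soil()`) takes the unweighted mean
   of core relative-abundance vectors — idealised equal 3 g aliquots, with
   an optional lognormal mass jitter (default off). DNA pooling
   (`pool_dna()`) mixes per-core extracts with equal weights — idealised
   equal concentrations from fixed 2 µL volumes, with an optional
   concentration jitter (default off).
2. **Extraction** (`extract_dna()`). A fixed-size extraction recovers
   Poisson($T p_s$) template molecules per species, $T$ = 3000 by default.
   This is the **dilution effect** in closed form: a species confined to
   one of $N$ pooled cores at within-core proportion $q$ survives a pooled
   extraction with probability $1 - e^{-Tq/N}$, monotonically decreasing
   in $N$. Unpooled and DNA-pooled samples pay $1 - e^{-Tq}$ per core
   instead, because each core got its own extraction; the mixed DNA pool
   is not re-bottlenecked (template copy numbers in a pooled extract are
   ample).
3. **PCR and sequencing** (`pcr_and_sequence()`). Biological read weights
   are templates × a species-fixed lognormal bias factor × a
   reaction-level lognormal jitter (sd 0.3). Each reaction also mints
   **artefactual OTUs** (error products and chimeras), each unique to its
   reaction: the count is Poisson with mean
   $\min(\text{depth}, D_{sat})/1000 \times (a + c \cdot {}^{1}\!D)$,
   where ${}^{1}\!D$ is the Hill-1 diversity of the template pool
   ($a$ = 0.3, $c$ = 0.15, $D_{sat}$ = 10000 by default). The chimera
   term escalates with co-amplified template diversity; the saturation
   expresses that artefact *types* arise during the reaction, so
   sequencing deeper resamples the same artefacts rather than minting new
   ones indefinitely. Each artefact OTU receives a read weight equivalent
   to about 2 expected reads. Reads are multinomial at the drawn depth.
4. **Depths.** Unpooled samples draw negative-binomial depths (mean 1200,
   size 12), giving minimum depths in the hundreds — the regime where
   near-minimum rarefaction floors matter. Pooled samples are sequenced
   deeper: mean twice the design's realised summary depth (total unpooled
   reads), so rarefying a pooled sample at 100% summary depth is always
   feasible, matching the field practice of sequencing pooled
   samples comprehensively.

Two consequences of this model are worth stating because the test suite
asserts them. For designs pooling many cores (≥ 40), the extraction
dilution dominates: pooled samples lose locally rare species and the
pooling effect on richness falls below 1. For small designs (≤ 9 cores)
dilution is mild, while the pooled reaction's higher template diversity
mints more chimera-type artefacts than the few individual reactions it
replaces, tipping the pooling effect above 1. Summed over a dense design's
many individual reactions, however, unpooled processing always accumulates
far more unique artefacts than the single pooled reaction — the two
directions coexist because one is per-OTU-table inflation at matched
depth, the other a count of distinct artefact types across reactions.

# Estimators

`divmetrics` functions operate on read-count vectors:

* Good's coverage $1 - f_1/n$; Hill diversities of order 0 (richness) and
  1 ($e^{H}$, the effective OTU number).
* Analytic rarefaction
  $E[S_d] = \sum_s \left(1 - \binom{n - n_s}{d}/\binom{n}{d}\right)$,
  evaluated via log-gamma so depths of $10^5$ reads are exact; and
  Monte-Carlo rarefaction (`rarefy_mc()`, default 1000 iterations,
  averaged), which is the estimator the analyses use because it also
  yields Shannon/Hill-1 and coverage at depth. The two agree within
  Monte-Carlo error — this oracle pair is tested on random vectors and,
  independently, against vegan.
* Bias-corrected Chao1 $S + f_1(f_1-1)/(2(f_2+1))$ (defined at
  $f_2 = 0$; the classical form is a flag), size-based richness
  extrapolation towards the Chao1 asymptote, exact sample-based
  accumulation curves, and cumulative abundance curves.
* Fractional rarefaction depths are floored to integers; compositions are
  validated to sum to 1 within $10^{-9}$.

# Design-evaluation statistics

**Summaries** (`summarise_design()`) rarefy each unpooled stratum (site ×
design) to its near-minimum read depth; samples under 100 reads are
dropped with a warning. Site-level values use the union of full-depth
samples.

**The pooling effect** (`pooling_effect()`) follows the ratio definition:
pooled value (Monte-Carlo rarefaction of the pooled sample at
`fraction` × summary depth) over the observed unpooled site-level value at
full depth. Only the pooled side is rarefied by default, because the
unpooled reference *is* the full summary depth; a both-sides-rarefied
variant sits behind `rarefy_reference = TRUE`. The default fraction grid
{0.25, 0.5, 0.75, 1} covers the sweep used for break-even analysis
(`break_even_depth()` reports the first grid fraction with PE ≥ 1 and the
linear interpolation of the crossing). Fractions whose target depth
exceeds the pooled reads are flagged infeasible, never extrapolated.

**The area test** (`area_subsampling_test()`) draws 8-sample subsets of a
design whose axis-aligned bounding rectangle is near-square
(|width − length| ≤ 5 m) with area in [327, 2000] m$^2$, stratified over
area bins so the range is covered evenly, and fits richness ~ area by
least squares (plus a site term when several sites enter). The null
distribution permutes *sample labels* — which community sits at which
coordinate, within site — and recomputes every combination, because
combinations share samples: permuting combination-level richness values
ignores that dependence and inflates the type-I error (we measured ~12%
against the nominal 5%; the label scheme restores calibration). The
bounding rectangle is anchored by the samples themselves; there is no
canonical anchoring for such rectangles, and any fixed anchor would only
shrink the feasible set.

# Composition statistics

`commstats` implements the distance-based tests from first principles, so
that each has an enumerable small-instance oracle, with vegan used purely
as an independent cross-check in the tests:

* Bray–Curtis $\sum_i |x_i - y_i| / \sum_i (x_i + y_i)$.
* PERMANOVA with Anderson's partition
  ($SS_{total} = \frac{1}{N}\sum_{i<j} d_{ij}^2$, within-group sums per
  group size), pseudo-$F$, $R^2$, and a $(b+1)/(m+1)$ permutation p-value.
  Permutations act on indices after sorting samples canonically by group,
  stratum and name, making the p-value invariant to input row order; for
  $N \le 8$ with a sufficient budget all distinct relabellings are
  enumerated and the test is exact. Strata restrict permutations within
  sites when surveys span several plots (both free and restricted
  modes exist).
* Dispersion homogeneity embeds the distance matrix by principal
  coordinates, keeps negative-eigenvalue axes on an imaginary subspace
  (squared real distance minus squared imaginary distance, floored at
  zero), measures distances to the group's spatial median (centroid
  optional) and tests the one-way ANOVA F of those distances by label
  permutation.
* The Mantel correlogram computes, per half-open geographic distance
  class, the correlation between community distance and class membership,
  sign-flipped so positive values mean short-range similarity; p-values
  permute sample identities and are Holm-corrected across classes (no
  particular correction is canonical for correlograms; Holm is
  conservative and assumption-free).

# Artefact screening

`screenfx` applies three sequence rules to a global pairwise alignment of
each OTU against its best reference (affine-gap Needleman–Wunsch via
Biostrings; gap-run extraction and p-distance are computed from the
aligned strings):

* *long indel*: any gap run strictly longer than 20 bases;
* *multi-indel window*: two or more single-base gap runs inside the
  anchored 200-base window (the 5.8S + ITS2-start stand-in; window
  coordinates travel in the reference FASTA header for synthetic data and
  are a required argument for user data);
* *excess divergence*: p-distance strictly greater than 2% over gap-free
  columns. This pairwise proxy replaces tree-based long-branch screening:
  a "relatively long branch" against the best hit corresponds to the same
  2% divergence, and a pairwise distance needs no multiple alignment or
  phylogeny.

"More than one single-nucleotide indel" is read as ≥ 2 gap *runs* of
exactly length 1 (events, not columns), and the long-indel rule as a
single run > 20 (not summed across runs); both readings are the literal
ones and are frozen in boundary tests (a 20-base run is clean, 21 flags;
exactly 2% is clean). `make_synthetic_alignment()` plants exactly one
signature per artefact OTU and mutates biological OTUs at 0.5%
substitutions (no indels), so screening recall and specificity are 100%
by construction — the tests assert precisely that, which validates the
rule implementation, not any claim about real reads.

Rare OTUs are those at ≤ 0.05% of the stratum's total reads (boundary
inclusive), with the stratum defaulting to the site — "total reads" needs a
denominator scope, and the site is the unit the uniqueness analysis
already works at. Unique OTUs are
those whose site-wide occurrences fall in a single design.

# The cost calculator

`compute_costs()` uses the stated throughputs — 10 extractions or 40 PCR
reactions per working hour — with 3 markers per sample. Unpooled
processing extracts every physical core; soil pooling extracts one sample
per top-level composite; DNA pooling still extracts every core and only
collapses PCRs and libraries. For flat designs the chemical saving is
exactly $100 (N-1)/N$%: 88.9% for N9D0-10 and 80% for N5D0-20 at any
plot count. Person-hour headlines quoted for such pooling scenarios often embed
additional fixed costs beyond the stated throughputs; this model documents
its exact formula instead of imitating any such totals.

# Problem sizes, determinism and limitations

The default experiment (3 sites, 12 designs, 3 groups, 1000 rarefaction
iterations) runs in minutes on one CPU; the test-suite and acceptance
simulations use one site and one or two designs per seeded replicate with
100-iteration rarefaction inside the pooling-effect cells, sizes chosen so
each seeded condition repeats 20–50 times while the whole suite stays
fast. Every stochastic stage derives an independent substream from the
master seed by hashing a stage key (`derive_seed()`), so results are
independent of loop order and reproducible bit-for-bit; the run manifest
records all derived seeds.

What passing tests do *not* show: the generator has no environmental
covariates, no temporal dynamics, no taxonomy or phylogeny, no per-base
error model, and its artefact and bias magnitudes are directions-only
calibrations, not estimates. Real surveys add sources of variation
(extraction efficiency differences, primer mismatch structure, index
hopping) that this model folds into a handful of lognormal jitters, and
the published person-hour totals are not reproducible from the stated
throughput constants alone. Conclusions about *which* design or strategy
is preferable on real soils should rest on the real-data study; this
package reproduces the analytical machinery and the qualitative mechanism
structure, under known truth.
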