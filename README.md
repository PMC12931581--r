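# pooldesign

Soil biodiversity surveys based on eDNA metabarcoding have to decide, before
any sequencing happens, how to sample: how many soil cores per plot, over
what area and depth, and whether to process cores individually, composite
the soil before DNA extraction (**soil pooling**), or mix the DNA extracts
before PCR (**DNA pooling**). These choices change richness estimates
several-fold and interact with sequencing depth, rare-species detection and
PCR artefact accumulation. `pooldesign` is an R package for studying those
interactions on a fully simulated, ground-truthed study system, together
with the estimators the comparisons need. It is written for ecologists and
bioinformaticians who design (or meta-analyse) soil metabarcoding campaigns.

## What is inside

* **Virtual communities** — per-group species pools (animal-, fungus-,
  bacteria-like) realised as Thomas cluster point processes in a
  50 m × 50 m × 40 cm soil volume, with patchiness, positive spatial
  autocorrelation, vertical stratification and a small subsoil-unique
  species fraction (`make_species_pool()`, `realise_site()`).
* **Twelve published sampling designs** — core counts 5–75, areas
  16–2500 m², depths 0–1 to 30–40 cm, including the nested compositing
  trees of the pooled-only designs (`builtin_designs()`, `place_cores()`,
  `take_core()`).
* **A laboratory simulator** — soil compositing, DNA-extract mixing,
  fixed-size extraction with Poisson template recovery (the dilution
  effect: a species in 1 of N pooled cores at proportion q survives with
  probability ≈ 1 − exp(−Tq/N)), PCR with species- and reaction-level
  bias and diversity-dependent chimera/artefact generation, multinomial
  sequencing (`pool_soil()`, `pool_dna()`, `extract_dna()`,
  `pcr_and_sequence()`, `run_survey()`).
* **Diversity kernels** — Good's coverage, Hill numbers (q = 0, 1),
  analytic (hypergeometric) and Monte-Carlo rarefaction, bias-corrected
  Chao1, exact accumulation curves, size-based richness extrapolation.
* **Design analytics** — depth-standardised design summaries, richness
  ratios between designs, site rankings with Kendall-tau concordance, the
  **pooling effect** PE = pooled / unpooled diversity with the pooled
  sample rarefied at a fraction of the design's summary sequencing depth,
  and a rectangular area-subsampling test of the area effect on richness.
* **Composition statistics from first principles** — Bray–Curtis,
  PERMANOVA (Anderson's partition, exact enumeration for small n),
  multivariate dispersion homogeneity with spatial medians, Mantel
  correlograms (vegan serves only as an independent oracle in the tests).
* **Artefact screening** — global pairwise alignment (Biostrings) plus the
  three screening rules: gap runs > 20 bases, more than one single-base
  indel inside a 200-base window, > 2% sequence divergence; with a
  planted-signature synthetic FASTA generator for validation.
* **A pooling cost calculator** — person-hours (10 extractions or 40 PCRs
  per hour, 3 markers per sample), chemical and library units, savings
  percentages and fold reductions; plus the break-even sequencing-depth
  fraction at which pooling starts to outperform unpooled sampling.

## A worked example

Simulate one plot, survey it with a dense and a small design under all
three strategies, and ask what pooling did to richness:

```r
library(pooldesign)

pool <- make_species_pool("fungus_like", seed = 1)
site <- realise_site(pool, extent = 50, seed = 2, site_id = "site1")
tab  <- run_survey(site, builtin_designs()[c("N62D0-5", "N9D0-10")],
                   c("unpooled", "soil_pool", "dna_pool"),
                   pool, lab_config(), seed = 3)
print(tab)
#> Read table: 75 samples x 467 OTUs (394 artefactual), 443682 reads

for (d in c("N62D0-5", "N9D0-10"))
  for (s in c("soil_pool", "dna_pool")) {
    pe <- pooling_effect(tab, "site1", d, s, q = 0, depth_fractions = 1,
                         iterations = 100, seed = 4)
    cat(sprintf("%-8s %-9s PE(100%%) = %.2f\n", d, s, pe$pe))
  }
#> N62D0-5  soil_pool PE(100%) = 0.61
#> N62D0-5  dna_pool  PE(100%) = 0.60
#> N9D0-10  soil_pool PE(100%) = 1.18
#> N9D0-10  dna_pool  PE(100%) = 1.18
```

Pooling 62 cores *loses* OTUs (PE < 1): one fixed-size extraction dilutes
locally rare templates below detection. Pooling 9 cores *gains* OTUs
(PE > 1): dilution is mild and the single diverse pooled reaction mints
more chimera-type artefacts than the few individual reactions it
replaces. The cost side of the trade-off:

```r
compute_costs(builtin_designs()[["N9D0-10"]], "soil_pool", n_plots = 100)
#> N9D0-10, soil_pool, 100 plots: 157.5 h -> 17.5 h (140.0 saved, 88.9%);
#>   chemicals 88.9% saved (9.0x); libraries 88.9% saved
```

The `analysis/` directory strings the full campaign into numbered stages
(simulate → survey → diversity → pooling effect → area/composition →
screening → costs), each a thin script over the package that prints what
it found and writes TSV tables under `results/`.

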