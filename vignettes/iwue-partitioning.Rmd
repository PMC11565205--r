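---
title: "Partitioning intrinsic water-use efficiency in genotype panels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning intrinsic water-use efficiency in genotype panels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Intrinsic water-use efficiency, iWUE = A~n~/g~s~ (µmol CO~2~ mol^-1^
H~2~O), summarizes how much carbon a leaf fixes per unit of stomatal
opening. Because A~n~ saturates with g~s~, two genotypes can reach the
same iWUE by very different routes: by closing stomata (cheap, but it
starves the leaf of CO~2~) or by keeping photosynthetic capacity high at
low intercellular CO~2~ (C~i~). Breeding for water-limited environments
wants the second kind. This package implements, as one tested pipeline,
the leaf-level analyses used to tell the two routes apart in a
multi-genotype sorghum screen under well-watered (WW) and water-stress
(WS) regimes:

1. **iWUE partitioning.** A reference iWUE–g~s~ curve is fitted across
   all retained observations of both treatments. For each genotype, the
   curve value at its g~s~ is the iWUE expected from conductance alone;
   its deviation from the treatment-mean iWUE is the *stomatal*
   component ΔiWUE~gs~, and the remainder of the genotype's deviation is
   the *photosynthetic-capacity* component ΔiWUE~pc~. The two components
   add exactly to the genotype's deviation from the treatment mean; this
   identity is asserted to 1e-9 relative error in the tests.
2. **Evaporative-flux hydraulics.** K~leaf~ = E/(Ψ~stem~ − Ψ~midday~)
   and K~plant~ = E/(Ψ~pre-dawn~ − Ψ~midday~), with resistances
   R~leaf~ = 1/K~leaf~ and R~rest~ = 1/K~plant~ − R~leaf~ so the serial
   identity 1/K~plant~ = R~leaf~ + R~rest~ holds by construction.
3. **Phenotypic-change vectors.** Per genotype, ΔA~n~ and ΔC~i~
   (WW − WS) define a vector whose angle θ = atan2(ΔA~n~, ΔC~i~), in
   degrees, separates capacity maintenance (θ small: C~i~ falls much
   more than A~n~) from joint collapse (θ large).
4. **Genetic variation.** Balanced two-way genotype × treatment ANOVA
   mean squares feed broad-sense heritability H~b~² = σ~g~²/σ~p~² and
   the genotypic/phenotypic coefficients of variation
   GCV = 100·σ~g~/|mean|, PCV = 100·σ~p~/|mean|.
5. **Haplotype contrasts.** Genotypes grouped by the inherited
   recurrent-parent (RP) versus exotic (NRP) haplotype of an aquaporin
   are compared across treatments, with Tukey HSD letter displays.

# Design decisions that were genuinely open

**Form of the reference curve.** The defensible readings are an
empirical power law iWUE = a·g~s~^b^ fitted on the log–log scale, and
the "constant A~n~" hyperbola iWUE = A~ref~/g~s~ with A~ref~ the mean
assimilation of the fitting set. Both are implemented
(`fit_reference_curve(form = "power" | "constant_A")`); the power law is
the default because it nests the hyperbola (b = −1) and adapts to the
flattening of the A~n~–g~s~ relation at high conductance. Neither is
asserted to be the historically exact choice. The partition identity
holds for any curve, so the choice moves variance between the two
components but never breaks additivity.

**Treatment mean.** The population mean iWUE for a treatment is the
unweighted mean over retained genotype × treatment means (matching
analyses performed on genotype means, n = 3 pots); replicate-level
averaging can be had by passing `treatment_means` explicitly.

**Exclusion rule.** The screen drops genotype × treatment means whose
gas exchange has collapsed, where the iWUE ratio is numerically fragile
and biologically uninformative. The rule is a joint threshold — a mean
is excluded only when *both* g~s~ < 0.02 mol m^-2^ s^-1^ and A~n~ <
2 µmol m^-2^ s^-1^ — so genuinely low-conductance but functioning
plants are retained. The filter runs before curve fitting and before
treatment means are computed, and everything downstream sees only the
retained set; both floors are parameters.

**Variance-component conventions.** Two conventions coexist.
`paper_literal` takes the ANOVA mean squares directly as σ~g~², σ~g×t~²
and σ~e~², and assembles σ~p~² = σ~g~² + σ~g×t~²/t + σ~e~²/r~std~ with
the replicate divisor standardized at r~std~ = 5 (one fewer than the six
pots a genotype present under both regimes contributes, allowing for
genotypes missing a treatment); this is the convention used for
published-style summary tables, and it guarantees H~b~² ≤ 1 and
PCV ≥ GCV. `ems` applies the standard expected-mean-squares estimators
(σ~e~² = MS~E~, σ~g×t~² = (MS~GT~ − MS~E~)/r, σ~g~² =
(MS~G~ − MS~GT~)/(rt), truncated at zero), which is what simulation
recovery tests use because it is consistent for the generating
variances. The divisor is exposed because published phenotypic variances
assembled this way are not always reproducible from their printed
components — with the A~n~ components (127.2, 61.6, 61.49) and r~std~ =
5 the formula gives 170.3, not the 160.03 that accompanies them — so
`heritability()` and `gcv_pcv()` accept the components as given rather
than recomputing σ~p~².

**Haplotype test.** The haplotype population is a genotype-level factor
while the watering treatment is applied within genotype. Pooling
replicate plants as if independent pseudoreplicates the Population test
badly: on null simulations its type-I error reaches 0.39 (and a naive
two-way ANOVA on genotype × treatment means still 0.18), because three
pots of one genotype share its genotypic effect and each genotype
appears in both treatments. `haplotype_anova()` therefore defaults to a
split-plot ANOVA on genotype × treatment means — Population tested
against genotype-within-population variation (df 1, N − 2), Treatment
and Population × Treatment against the within-genotype stratum — which
is the classical fixed-stratum analog of a mixed model with genotype as
a random effect. Its empirical type-I error is 0.055–0.065 over 200 null
seeds. The pooled-replicate analysis remains available as
`unit = "replicate"` for comparison.

**Tukey machinery.** The studentized-range CDF is computed by adaptive
quadrature of its integral definition (accuracy ~1e-6, validated against
the k = 2 closed form √2·t and against the stock `ptukey`), unequal
group sizes use the Tukey–Kramer harmonic-mean convention, and letters
come from the insert-and-absorb algorithm, so sharing a letter is
exactly equivalent to a non-significant adjusted pairwise difference.
P-values across traits and aquaporins are deliberately *not* adjusted
for multiplicity (each contrast is reported raw, as is conventional in
these screens); `p.adjust` can be applied downstream if desired.

**Change-vector scale.** θ and the magnitude are computed on raw trait
scales (mixed units: µmol m^-2^ s^-1^ against µmol mol^-1^), faithful to
the vector-analysis convention this follows; `standardize = TRUE`
z-scores the deltas first for a unit-free variant. The WW − WS sign
convention makes "stress reduces both" the positive quadrant.

# The synthetic trial generator

No accession-level dataset is distributed with the screen this package
addresses, so the generator is a first-class module: it emulates the
design (89 genotypes × 2 treatments × 3 pots, with 6 pots for a
designated recurrent parent via `replicate_overrides`) with known ground
truth, and every downstream stage is tested against that truth.

The generative model, in the order the draws are made from the single
seeded stream (genotype effects, interaction effects, capacity effects,
hydraulic effects, haplotype labels, then per-observation residuals):

* log g~s~ = log(g~s,base~) + [WS]·log(f~WS~) + G~i~ + GT~it~ + ε, with
  G ~ N(0, σ~g~²), GT ~ N(0, σ~g×t~²), ε ~ N(0, σ~e~²). Lognormal g~s~
  guarantees positivity and the right-skewed spread seen in such
  panels. Defaults: g~s,base~ = 0.20 mol m^-2^ s^-1^, f~WS~ = 0.35,
  σ~g~ = 0.20, σ~g×t~ = 0.10, σ~e~ = 0.15.
* A~n~ = c~it~·A~max~·g~s~/(g~s~ + K~half~) + η, a saturating
  A~n~–g~s~ curve (A~max~ = 45 µmol m^-2^ s^-1^, K~half~ = 0.12 mol
  m^-2^ s^-1^) scaled by a lognormal genotypic capacity multiplier
  (σ = 0.12) and, under WS, by `capacity_ws_multiplier` — the dial that
  distinguishes capacity-maintaining (1.0) from capacity-losing (< 1)
  genotypes; η is a small additive residual (σ = 0.5).
* C~i~ = C~a~ − 1.6·A~n~/g~s~ (floored at 5 µmol mol^-1^), the diffusive
  supply function with the H~2~O/CO~2~ ratio 1.6, so A~n~, g~s~ and
  C~i~ are mutually coherent and the θ analysis is internally
  consistent rather than simulated independently.
* E = 1000·g~s~·VPD/P~atm~ (mmol m^-2^ s^-1^; VPD 1.5 kPa, P 101.3
  kPa), and water potentials built to be hydraulically exact:
  Ψ~midday~ = Ψ~pre-dawn~ − E/K~plant~ and Ψ~stem~ = Ψ~midday~ +
  E/K~leaf~, with K~leaf~ = K~plant~/f~leaf~ so the leaf carries
  fraction f~leaf~ = 0.4 of total resistance. K~plant~ is lognormal
  around 3.0 mmol m^-2^ s^-1^ MPa^-1^ and halves under WS; Ψ~pre-dawn~
  is −0.1 (WW) / −0.7 (WS) MPa. These choices put simulated gas
  exchange, fold changes and midday potentials in the ballpark of the
  published screen (WW g~s~ ≈ 0.11–0.39, WW A~n~ ≈ 19–44, Ψ~midday~
  means ≈ −1.2/−1.4 MPa).
* Morphology, SPAD, ΦPSII and biomass are genotype-level normals with
  treatment shifts; leaf-disc weights are constructed from a target LMA
  and RWC so the disc formulas invert them exactly.

Because the potentials are built from the configured conductances,
applying the evaporative-flux equations to noise-free simulated plants
recovers K~leaf~ and K~plant~ to < 1e-9 relative error — that inversion
is the hydraulics oracle in the tests. `measurement_noise = TRUE` adds
instrument-level noise to Ψ and E for robustness testing; it is off by
default so algorithm verification stays separate from robustness.

What the generator does **not** emulate: SNP genotypes, recombination or
the nested-association-mapping crossing scheme (haplotype groups are
labels with an optional additive log-g~s~ shift); VPD responses and
stomatal-model dynamics; instrument drift; spatial/chamber effects; and
any correlation between capacity and hydraulic effects beyond what the
model above induces. Passing tests therefore demonstrate correctness of
the estimators under a plausible generative model, not their behaviour
on every pathology of real field data.

**Determinism.** One integer seed drives a single RNG stream with a
fixed, documented draw order; the same configuration and seed reproduce
the trial bit-identically, and the pipeline's CSV outputs
byte-identically.

# Numerical choices and degenerate inputs

* Reversed or zero water-potential gradients yield `NA` with a warning,
  never an exception, so batch runs survive messy rows; the offending
  rows are countable from the warnings.
* Negative R~rest~ (K~leaf~ < K~plant~) is returned but flagged: it is a
  measurement inconsistency the analyst must see, not silently clip.
* A zero residual mean square reports F and p as missing; zero
  phenotypic variance reports H~b~² = 0 with a warning; EMS component
  estimates are truncated at zero with a flag.
* Light-response interpolation is piecewise linear between PPFD-sorted
  points — assumption-free and bracketed by data — and refuses to
  extrapolate unless told to; no saturating curve model is imposed.
* Curve evaluation outside the fitted g~s~ domain proceeds (preserving
  the partition identity) but flags the row.
* Pearson correlations with a zero-variance argument are reported
  missing, with a warning, rather than erroring a whole correlation
  matrix.
* Unbalanced ANOVA falls back to unweighted means on cell means with
  the harmonic mean cell size, with a warning; empty cells are an
  error. No Type I/II/III machinery is attempted.

# Problem sizes used in verification

The test suite and the acceptance script size their simulations to the
design they emulate: single trials of 89 × 2 × 3 (534–540 records) for
the partition, hydraulics and pipeline checks; 100 seeds for
heritability recovery (the EMS estimate's mean tracks the realized truth
within ±0.05, in practice within ~0.01); 200 null seeds for the
Population-term type-I calibration; 20-seed panels for directional
claims (capacity-maintainers show lower θ and larger ΔiWUE~pc~ gain
under WS, tested as sign tests). Agreement between the global reference
curve and one fitted on the double-replicated recurrent parent is
asserted as a panel mean (r ≥ 0.9 per component over 20 seeds) rather
than per seed, because a single genotype contributes only ~12
observations and its fitted slope is accordingly unstable.

# Known limitations

* The ANOVA machinery targets the balanced two-factor design of this
  screen; the unweighted-means fallback is approximate for severe
  imbalance, and no REML/mixed-model variance estimation is offered.
* The `paper_literal` variance convention overstates σ~g~² relative to
  EMS estimation (mean squares contain interaction and error
  contributions); it exists to reproduce published-style tables, not
  for simulation-consistent inference.
* Published correlation strengths on the original field data (e.g.
  R² ≈ 0.91 for A~n~–g~s~) depend on that dataset and are not
  reproduction targets; the pipeline reproduces structure and
  direction, and its own printed numbers come from its own runs.
* The magnitude of the change vector mixes units; use the standardized
  variant when comparing magnitudes across traits.

# A minimal session

```{r}
library(sorghumWUE)

sim <- simulate_trial(sim_config(seed = 1))
d <- derive_physiology(sim$records)
m <- apply_exclusion_filter(aggregate_means(d))$retained

curve <- fit_reference_curve(m$g_s, m$iwue)
part <- partition_iwue(m, curve)
vecs <- change_vectors(m)
head(merge(part[part$treatment == "WS", ], vecs, by = "genotype_id"))

summ <- trait_summary_table(d, m, c("A_n", "g_s", "iwue"))
summ

at <- haplotype_anova(with(d, cbind(d, log_gs = log(g_s))), "log_gs",
                      "SbPIP1.1", sim$assignments)
at
```

The `analysis/` directory runs the same workflow as a numbered script
sequence (simulate → physiology → partition → vectors → quantgen →
haplotype) writing its tables under `results/`.
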