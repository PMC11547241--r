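---
title: "Methods: multiplex drop-off dPCR screening, quantification and calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiplex drop-off dPCR screening, quantification and calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropscreen)
```

# Scope

dropscreen analyses three-color multiplex drop-off digital PCR experiments
for rare somatic mutations in plasma cell-free DNA. The pipeline starts at
per-droplet fluorescence intensities (one row per droplet: FAM, HEX, Cy5)
and ends at per-sample mutation calls with copies/PCR, copies per mL of
plasma and mutant allele frequency (MAF), plus assay-validation and
cohort-level statistics. Everything upstream of the intensity table —
optics, image analysis, PCR kinetics — is out of scope, as is any clinical
interpretation of the calls.

# The measurement model

## Partition statistics

A reaction of volume $V$ (default 25 µL) is partitioned into $N$ droplets of
volume $v$ (default 0.68 nL; chambers hold 12,900–25,800 droplets, default
20,000 — mid-range). Only $Nv$ of the reaction is interrogated; a molecule
lands in a given droplet with per-droplet mean
$\lambda_t = c_t\,v/V$ for a template at $c_t$ copies/reaction, and
occupancies of different templates are independent Poisson. From $k$
positive droplets the standard estimator is

$$\hat\lambda = -\ln(1 - k/N), \qquad
  \widehat{\text{copies/PCR}} = \hat\lambda\,V/v ,$$

referring to the full reaction (dead volume included), because the assay's
input cap — 10,000 copies/PCR at 33 ng, i.e. 3.3 pg per haploid genome
equivalent — is a whole-reaction quantity. The analysed fraction $Nv/V$ is
reported alongside every estimate.

The 95% CI is a normal interval on $\lambda$ with
$\mathrm{var}(\hat\lambda) = k/\big(N(N-k)\big)$ (binomial variance of $k$
pushed through the log transform); an exact Clopper–Pearson interval on the
positive fraction is available as an option. Degenerate inputs error
explicitly: $k = N$ is a saturation error advising dilution, $k > N$ a data
integrity error.

## Drop-off masking and the conditional estimator

In a drop-off design the wild-type template lights the drop-off *and*
reference probes (FAM⁺Cy5⁺); a hotspot mutant lights only the reference
probe (Cy5⁺). A droplet containing both a mutant and a wild-type molecule
is therefore indistinguishable from wild-type-only: the mutant is *masked*.
At 10,000 WT copies/PCR roughly $1-e^{-\lambda_{WT}} \approx 24\%$ of
mutant molecules are masked, so the naive estimator is biased low by that
factor. The conditional estimator restricts to the wild-type-negative
subpopulation, within which mutant occupancy is unbiased because
occupancies are independent:

$$\hat\lambda_{mut} = -\ln\!\left(\frac{N - k_{WT} - k_{mut}}
                                       {N - k_{WT}}\right).$$

`quantify_chamber()` applies it to the drop-off hotspot group and the naive
estimator elsewhere. MAF is computed on the copies scale,
$100\,c_{mut}/(c_{mut}+c_{WT})$; a droplet-count-based MAF can be formed
manually from the counts table for comparison.

## Blank correction and detection limits

False-positive droplets are an intrinsic background. From $N_b$ wild-type
-only blank replicates (default 34, at 10,000 WT copies/PCR) the corrected
blank mean per detection group is

$$\mu_{corr} = \mu + 1.645\,\sigma/\sqrt{N_b},$$

with $\sigma$ the sample SD ($n-1$ normalisation — conservative for small
panels). Observed counts are LOB-corrected by subtracting $\mu_{corr}$,
floored at zero. The correction is isolated in `lob_correct_counts()` so an
alternative rule can be swapped in without touching the estimators.

LOB₉₅ is the smallest integer $L$ with $P(X > L) \le 0.05$ for a count
model with mean $\mu_{corr}$. Two bounds are computed — the normal
approximation $\lceil\mu + 1.645\sqrt{\mu}\rceil$ and the Poisson Chernoff
bound $e^{-\mu}(e\mu/k)^k \le 0.05$ — and the tighter admissible is
returned. Numerically, the returned bound tracks the exact Poisson
quantile within one droplet for $\mu_{corr}\in[0.5,5]$, while the pure
Chernoff bound is conservative and exceeds the exact quantile by up to two
droplets above $\mu_{corr}\approx 3$; the exact quantile is kept as a
verification method (`lob95(mu, method = "exact")`).

The theoretical LOD₉₅ is the smallest integer Poisson mean $d$ with
$P(X \ge \text{LOB}+1) \ge 0.95$, expressed first in droplets — the
positivity rule compares droplet counts — then converted to copies/PCR and
to the MAF equivalent against a 10,000 copies/PCR background. For samples
assayed in $r$ replicates the chambers are pooled: the blank mean scales to
$r\,\mu_{corr}$, both limits are recomputed on the pooled scale
($rN$ partitions), and because the Poisson tail tightens relative to its
mean the pooled LOD in concentration terms is strictly better than the
single-replicate LOD — the sensitivity gain that motivates replication.

## Positivity rule and the two-step strategy

A detection group is **positive** when at least two replicates reach the
LOD₉₅ in raw positive droplets; **negative** when all replicates are at or
below the LOB₉₅; **equivocal** otherwise, with a structured recommendation
(run two more replicates after a single equivocal one, one more after two).
A single replicate at or above the LOD is positive pending duplex
confirmation. Raw (not LOB-corrected) counts enter the rule; the corrected
counts feed quantification only.

The two-step caller screens first; each positive group is then identified
by the matching WT-MUT duplex assays (six are packaged: S310F, S310Y,
L755S, D769H, V777L, L869R). Final quantities are taken from the
identifying duplex. Every run requires a negative (water) and a positive
control chamber; calls from runs with failed controls are suppressed
(`invalid-controls`), a positive screen whose duplexes are all negative is
reported `unconfirmed` rather than negative, and a positive group without
duplex data is `incomplete`. Screen-detectable variants without a packaged
duplex (e.g. D769Y, V777M) deliberately end in those states — the screen
defers identity, it never invents it.

# The synthetic chamber generator

`simulate_chamber()` emulates: independent Poisson occupancy per template
(respecting the dead-volume fraction); probe logic driven entirely by the
packaged assay definition (drop-off probes bind intact-hotspot templates,
reference probes bind any template of their amplicon, mutation probes bind
their variants); cluster fluorescence as baseline + amplitude·scale +
Gaussian noise; *rain* (a configurable fraction of positive signals
attenuated by a uniform (0.2, 0.8) factor); and group-specific
false-positive droplets injected by corrupting empty droplets in place at
the group's canonical cluster position, so the partition count is
conserved. Co-occupancy masking is modeled faithfully, and templates no
probe of the running design binds are carried but invisible — a duplex
reaction sees only its own target.

Key defaults, all configurable in `chamber_config()`:

| parameter | default | rationale |
|---|---|---|
| `n_partitions` | 20,000 | mid-range of the instrument's 12,900–25,800 |
| `droplet_volume` | 0.68 nL | platform figure |
| `reaction_volume` | 25 µL | assay protocol |
| `baseline`, `amplitude` | 150, 3000 a.u. | ~30σ cluster separation at default noise, mimicking well-separated clusters with little rain |
| `noise_sd` | 100 a.u. | see above |
| `rain_fraction` | 0.01 | sparse rain, as in an optimized assay |
| `fp_rate` (per group) | 0.85 / 1.4 / 1.4 / 2.0 | calibrated so the analytic 34-replicate LOB₉₅ ladder is 3/4/4/5 droplets, the validated operating point of the screening assay |

The three duplication clusters are simulated at distinct, attenuated HEX
amplitudes (0.8, 0.65, 0.5 of full scale), reflecting the three distinct
cluster positions the assay resolves for Y772_A775dup and the two cDNA
forms of G778_P780dup. This attenuation is also what separates true
duplication droplets from droplets that co-encapsulate a wild-type and a
HEX-group mutant molecule — both are FAM⁺HEX⁺Cy5⁺, but the latter sit at
full HEX amplitude and must stay out of the duplication gate (see below).

What the generator does **not** emulate: amplification-efficiency kinetics
and partial inhibition, probe cross-hybridisation, inter-channel spectral
bleed, chip spatial artefacts, cfDNA fragment-length effects, and
droplet-volume dispersion. Passing tests therefore demonstrate that the
*analysis* is correct under the stated statistical model, not that the wet
assay achieves any particular performance on real plasma.

Reproducibility: every chamber is seeded from `(seed, chamber_id)`, so an
element of a series is reproducible in isolation; the global RNG state is
restored after each call.

# Gating: numerical choices

Gates are rectangles (general simple polygons are accepted from gate
files) on 2D channel planes. `derive_gates()` automates what an operator
does on the instrument: estimate per-channel negative and positive levels
from a positive-control chamber (medians of the two sides of the midpoint;
a positive cluster must clear six MADs of the negative spread) and place
per-class boxes with bounds at fixed fractions of the negative-to-positive
gap:

* "negative" axis: up to 15% of the gap — below the 20% floor of the rain
  attenuation, so rained droplets cannot re-enter a negative region;
* "positive" axis: from 45% of the gap — permissive enough to keep the
  attenuated duplication clusters;
* "mid" axis (duplication gate HEX): 30–90% of the gap — the upper bound
  excludes the full-amplitude co-occupancy cluster;
* droplets in no gate are *empty* below 15% of the gap in every channel
  and *rain* (unclassified) otherwise.

Point-in-polygon membership uses the even-odd rule with an explicit
boundary test (boundary counts as inside), matching manual-gating
convention; it is cross-checked against an independent implementation in
the tests. Gate counts are tallied independently per plane, as the
instrument software does — a duplication droplet is counted in both the WT
gate (FAM×Cy5) and the duplication gate (FAM×HEX), and
`correct_dup_overlap()` subtracts the duplication count from the WT tally,
flooring at zero with a warning. For droplet-conservation accounting each
droplet is also resolved to a single class by the design's precedence
order, so classified + rain + empty always equals the partition count.
Gate placement is affine-equivariant: rescaling all intensities and
re-deriving from the rescaled control reproduces the classification.

A control must exhibit every expected cluster: a gate capturing fewer than
max(10, 0.05% of partitions) control droplets aborts derivation, naming
the missing class — a handful of stray co-occupancy droplets does not
constitute a cluster.

# Validation statistics: conventions

* **CV%** is $100\,\sigma/\mu$ with the sample SD; the accepted ceiling in
  dPCR validation is 20%.
* **Linearity** is the OLS $R^2$ of measured vs expected copies/PCR over a
  5–1000 copies/PCR series in triplicate, fitted on the per-dilution
  replicate means (six points) — the standard calibration-curve
  convention. Under the generator's conditions the binomial counting noise
  of the high end alone places per-replicate fits below 0.9948 in roughly
  one seed in eight, while means-of-triplicates fits exceed it across the
  entire partition range; the reported statistic uses means.
* **Dilution sensitivity** walks the MAF ladder (5% down to 0.05%, mutant
  copies = MAF × 10,000 WT copies/PCR, triplicate, quadruplicate at
  0.05%) and reports, per group, the mean measured MAF at the lowest
  dilution where at least two replicates reach the LOD₉₅. Under the
  calibrated defaults the theoretical LOD for the hotspot group is ~0.2%
  MAF; at the 0.25% rung the expected unmasked count (≈10.3 droplets) sits
  just below the LOD of 11, so the floor lands on the 0.25% or 0.5% rung
  depending on sampling — the package's tests assert the floor at ≤0.5%
  and the empirically reported sub-0.3% sensitivities of optimized wet
  assays should be read as the favorable end of that distribution.
* **Cohort summaries** count prevalence over patients and frequencies over
  mutation events (a two-mutation patient counts once in prevalence,
  twice in the spectrum); histology strata are IBC-NST, pure ILC, and
  pure+mixed ILC combined; a matched tissue pair is concordant when every
  plasma mutation of the patient is found in tissue. Printed percentages
  use round-half-away-from-zero at one decimal (prevalence), two decimals
  (spectrum) and whole percent (concordance) — the conventions that make
  9/272 → 3.3, 2/12 → 16.67 and 5/6 → 83.

# Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic data:
linearity uses 20 seed sets × 6 levels × 3 replicates of full 20,000-
droplet chambers; reproducibility uses 8 chambers at 500 copies/PCR; LOB
coverage and LOD detection use 10,000 reduced chambers (2,000 partitions)
each, which leaves the count distributions unchanged; estimator-bias
checks use 1,000 count-level draws per occupancy level. These sizes were
chosen to keep Monte-Carlo margins a small fraction of each tolerance.

# Known limitations

* Assay definitions are data, but the decode truth table is boolean:
  intensity-level phenomena beyond amplitude scaling (bleed-through,
  competition) have no representation.
* The variant list packaged for the screening assay is a reconstruction
  from the published description of the design; cDNA annotations for the
  rarer hotspot substitutions are placeholders.
* The duplication gate relies on the amplitude attenuation of the
  duplication clusters; an assay whose duplication and co-occupancy
  clusters genuinely coincide would need manual gate files.
* The LOB correction is a mean subtraction with flooring; it slightly
  over-corrects near zero (the floor induces a small positive bias on
  blank-level samples and a small negative bias just above it).
* Identification granularity is bounded by the duplex panel: six duplexes
  cover the mutations the screen most often finds; other screen-positive
  variants end `unconfirmed`/`incomplete` by design.
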