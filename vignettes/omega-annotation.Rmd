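---
title: "Locating fatty-acyl double-bond positions from retention time"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating fatty-acyl double-bond positions from retention time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omegaRT)
```

## The problem

Routine reverse-phase LC-MS/MS resolves complex lipids to the *molecular
species* level — the class and the individual fatty-acyl chains, e.g.
PC 16:0_20:4 — but not the position of the carbon–carbon double bonds
within each chain. The terminal (ω, or n−x) double-bond position
distinguishes, say, an omega-3 from an omega-6 acyl and has direct
physiological meaning, yet the gas-phase methods that localize C=C bonds
(EAD, OzID, Paternò–Büchi derivatization, …) need special instrumentation
or chemistry and lose sensitivity.

The position is, however, encoded in chromatography: ω-positional isomers
of the same molecular species separate reproducibly on reverse-phase
columns, typically by ten seconds or more, while modern retention times
are stable to a few seconds. Given a reference database of ω-resolved
retention times (an RT-DB) and a way to transfer it to the chromatography
at hand, the ω position can be read off the retention time of each
identified peak. omegaRT implements that pipeline: RT-DB construction
from stable-isotope-labeling experiments, RT-DB calibration via anchor
species, and per-peak ω annotation.

## Building the RT database from labeling experiments

Authentic standards for ω-resolved complex lipids barely exist, so the
reference data come from cells fed stable-isotope-labeled fatty acids
whose label sits at the methyl (ω) terminus. Elongation, desaturation and
β-oxidation act on the carboxyl end only, so the label — and with it the
known ω position — survives metabolic incorporation into complex lipids.
Five one-letter prefixes encode the built-in labels in shorthand names
(`A18:1` is the D17-labeled n−9 oleate, `18:1(n−9)` its native
counterpart):

| code | isotope | atoms | implied ω | nominal shift |
|------|---------|-------|-----------|---------------|
| A    | ²H      | 17    | n−9       | 17 Da         |
| B    | ²H      | 11    | n−6       | 11 Da         |
| C    | ²H      | 5     | n−3       | 5 Da          |
| D    | ¹³C     | 16    | n−7       | 16 Da         |
| E    | ²H      | 19    | n−10      | 19 Da         |

`parseChain()` / `formatChain()` handle these tokens (accepting both the
Unicode minus and the ASCII hyphen, emitting the former), and
`enumerateMolecularSpecies()` + `applySilLabels()` + `buildMassList()`
generate the combinatorial mass lists — native, singly, doubly and
mixed-labeled — that the upstream identification software screens for.

### The deuterium isotope effect on retention

Deuterated lipids elute slightly earlier than their protiated
counterparts. On retention factors $k = (t_R - t_0)/t_0$ (with $t_0$ the
column dead time) the adjusted total isotope effect is

$$\mathrm{aTIE} = \frac{k_H/k_D - 1}{f_a} + 1,$$

where $f_a$ is a gradient-adjustment factor (default 1, adjustable per
gradient program). `estimateIsotopeEffect()` obtains $k_H/k_D$ from pairs
of unlabeled authentic standards and their deuterated counterparts.
Because compounds carry different deuterium counts, the package models
the effect *per deuterium atom* as a geometric factor $r$ on the
retention factor, $k_H/k_D = r^{n_D}$, pooling pairs by the geometric
mean of their $n_D$-th roots. This functional form is a design choice:
it is multiplicative in $k$, reduces to a per-compound correction
proportional to the deuterium count for small effects, and makes the
multi-chain correction additive — each labeled chain contributes
$\Delta t = (t_R - t_0)(r^{n} - 1)$ and `correctLabeledRT()` simply sums
the per-chain shifts, which matches the observed additivity of two
labels in one lipid. ¹³C labels have no measurable retention effect and
contribute nothing. The simulator inverts this correction exactly, so the
noiseless label→correct round trip reproduces native RTs to numerical
precision.

$t_0$ is never published with a gradient program, so it is a required
per-method configuration value; the fixtures use 0.5 min for the
30-min-like method. The sensitivity is mild: the correction scales with
$(t_R - t_0)$, so a ±0.2 min error in $t_0$ perturbs a corrected RT by
well under a second at typical effect sizes.

### Aggregating ω combinations

Feeding one label at a time maximizes coverage but never observes mixed
combinations like PI 18:1(n−9)/20:4(n−6) directly.
`groupOmegaCombinations()` recovers them computationally: identifications
that share a molecular species and fall within a grouping tolerance
(default 5 s) after isotope-effect correction are merged by
single-linkage clustering on RT; the merged entry takes the median member
RT (robust to a straggler replicate; the mean is available behind a
switch), pools the source batches, and unions the per-chain ω
assignments. Members that disagree on the ω of the same chain produce an
entry flagged `"conflict"`, which is excluded from anchor selection and
annotation rather than silently averaged. Grouping is idempotent and
order-invariant. `mergeRTDBs()` applies the same machinery across
measurement batches after mapping each batch onto a reference gradient,
and takes an explicit list of curated outlier keys to exclude, since no
objective outlier criterion is defined for the reference data.

## Calibrating an RT-DB to a new chromatography

RTs transfer between columns, mobile-phase batches and gradient programs
through a monotone warp that is estimated from *anchor species* — species
observed both in the RT-DB's source conditions and in the current
experiment. `selectAnchors()` implements three strategies: (1) maximize
the anchor count, admitting biological species and using standards, when
present, to screen outliers against a preliminary standards-only fit;
(2) maximize reliability, keeping standards plus biological anchors whose
replicate RT spread stays below 0.05 min and which give a single
chromatographic peak; (3) take every match, the right choice for runs of
standards. Biological anchors are matched at molecular level and
therefore require a unique ω entry for that molecular species in the
database — ω-ambiguous species never calibrate. A species producing
several target peaks is dropped under strategies 1–2 and kept as multiple
candidates under strategy 3 only for standards.

Anchors are binned on source RT (default bin width 0.5 min — coarser than
replicate jitter, finer than gradient curvature) and each bin contributes
one knot at the median source/target RT; adjacent non-increasing knots
are re-merged until the knot sequence is strictly increasing. Through the
knots of each group (lipid class, user-defined group, or all data
combined) `fitRTMapping()` fits a **natural interpolating cubic spline**.
Interpolation rather than penalized smoothing is deliberate: spline
interpolation outperforms heavier regressors (deep networks, MARS) when
noise is low and data sparse, and the noise robustness here comes from
binning, not from a smoothing penalty. Groups need at least four knots
for a cubic; sparser groups fall back along class → user group → global,
and a global pool of two or three knots degrades to a linear
interpolant.

Two mapping policies are explicit rather than silent. First, each RT is
served by the most specific model *whose knot range covers it*; a class
model is not extrapolated when a wider model covers the RT, because the
boundary slope of a cubic fitted to noisy knots is the least reliable
part of the fit. Second, an RT outside every range is continued linearly
with the boundary slope and flagged `"extrapolated"`; fallback mappings
are flagged `"fallback"`. Non-monotone mapped segments are reported, not
repaired: the spline is not constrained monotone, and on knots sampled
from a monotone warp with spacing at least the bin width it stays
monotone in practice.

`evaluateMapping()` reports the median and mean absolute deviation of
held-out anchors in seconds. At the package's benchmark scale (below),
mapping a 30-min-like database onto a doubled, nonuniformly stretched
gradient from 40 anchors with 2-s RT noise leaves a held-out median
deviation of about 1–2 s and a mean of about 2 s.

## Annotating runs

`annotateRun()` matches each identified peak against the mapped database
**within its molecular-species key only** — knowledge of the sum
composition (PC 40:5) never suffices, and a PC 18:0_22:5 peak can never
receive a PC 16:0_24:5 entry, so coeluting isomers of the same sum
composition are resolved per species. Candidates inside a wide window
(default 15 s) are ranked by |ΔRT|; the assignment is

* **automated** — exactly one candidate within the match window (default
  5 s, mirroring the grouping tolerance, against isomer separations of
  typically ≥ 10 s) *and* the nearest competitor at least
  `marginFactor` (default 2) times farther than the chosen candidate;
* **ambiguous** — two or more candidates inside the match window;
* **suggested** — candidates exist in the wide window but the automated
  conditions fail; flagged for manual review;
* **none** — otherwise.

The competitor margin is *relative* to the chosen candidate's |ΔRT|. An
absolute margin of `marginFactor × matchS` (10 s at the defaults) would
disqualify exactly the 10-s-separated isomer pairs the method is built
for whenever noise nudges the competitor below the threshold; the
relative rule keeps a near-perfect match automated while still demoting
genuinely borderline cases, and two true coeluters always fall into
`ambiguous` via the match-window rule first. The reported confidence,
$\max(0, 1 - |\Delta t|/\mathrm{matchS})$, is a package-defined score
that decreases monotonically in |ΔRT|; shrinking the match window can
only demote assignments, never promote them. Peaks identified at sum
composition only are never ω-annotated.

## The simulator and what the benchmarks mean

`synthRTDB()`, `makeWarp()`, `simulateRun()` and `benchmarkPipeline()`
generate fully controlled end-to-end experiments. The generator's
defaults encode the reference study design: a 30-min-like gradient
(span 0.5–32 min, $t_0 = 0.5$ min), eight phospholipid classes with 18
species per class, ω-isomer families (pair probability 0.5) placed with
pairwise separations of at least 10 s (drawn uniformly up to 3× that
minimum, lower ω eluting earlier), Gaussian RT noise of 2 s truncated to
the gradient span, technical triplicates, six authentic standards spread
over the gradient (marked with a synthetic 15:0 chain so they never
collide with generated biological species), a per-deuterium retention
factor ratio of 1.0015 (a D17 label then shifts a 20-min species by
roughly half a minute), and a continuous piecewise-linear
`gradient_stretch` warp emulating a 30→60-min gradient change. Elution
order follows the qualitative reverse-phase rule — RT rising with chain
carbons, falling with double bonds — as a fixture convention, not a
chromatographic claim.

The benchmark pipeline runs, per seed: database generation → simulated
target run → anchor selection → spline fit on 40 anchors → evaluation on
up to 30 disjoint held-out anchors → database mapping → annotation →
scoring against ground truth. Twenty seeds take on the order of a minute;
these problem sizes are the package's chosen desk scale and are stated
here so results are reproducible.

What passing benchmarks do **not** show: real chromatography has
peak-shape distortions, co-elution-dependent RT shifts, missing
identifications and class-dependent warp deviations that the generator
does not model; the synthetic warp's sharp segment boundary is harsher
than a real gradient change in one respect (curvature concentrates at a
point) and milder in others. Accordingly the simulated calibration
accuracy (≈1–2 s median) should be read as the method's noise floor
under its own assumptions, consistent with — not a reproduction of — the
few-second deviations reported on real cross-gradient data. The rare
automated misassignments in the benchmark cluster exactly where the
mapping is weakest, at the warp's kink and gradient edges, and carry
`"fallback"`/`"extrapolated"` flags — in practice those flags are the cue
for manual review.

## Known limitations

* Chain counts are restricted to one (lyso) or two in the built-in class
  registry; classes with three acyls would need combinatorial and
  chromatographic extensions.
* sn positions are taken as given in input tables; the package never
  infers them.
* Double-bond geometry (cis/trans) is not modeled; the scope is the ω
  position.
* The precursor-matching tolerance (10 ppm) and the automated/suggested
  policy thresholds are package defaults, configurable because no
  authoritative values exist for them.
* Only ²H and ¹³C labels are supported; the label registry is an
  editable file, but the isotope-effect model assumes deuterium drives
  the RT shift.

## A worked miniature

```{r example}
## estimate the isotope effect from one standard pair
std <- data.frame(native_rt = 20.4, labeled_rt = 19.9, n_d = 17)
model <- estimateIsotopeEffect(std, t0 = 0.5)
aTIE(model)

## build a two-entry database from labeled identifications
ids <- data.frame(batch = c("runB", "runC"), class = "PC",
                  chains = c("B20:4_22:5", "20:4_C22:5"),
                  rt_min = c(19.62, 19.87))
db <- buildRTDB(ids, model, gradientSpan = c(0.5, 32))
rtdbEntries(db)[, c("species_key_omega", "reference_rt_min", "batches")]
```
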