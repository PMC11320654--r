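---
title: "Shift-based conformational analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shift-based conformational analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confshift)
```

## The model

`confshift` treats conformational assignment as Bayesian model selection
among candidate shift sets. A candidate is either a single DFT-optimised
conformer or a molar-fraction mixture of cluster representatives; in both
cases it predicts one calculated shift per assigned site, obtained from
GIAO isotropic shieldings as $\delta^{calc}_i = \sigma_{ref} - \sigma_i$,
with experimentally isochronous atoms (methyl rotors, equivalent
methylenes) averaged arithmetically before referencing.

Two error channels are scored per nucleus. The *unscaled* channel uses
$e_i = \delta^{calc}_i - \delta^{exp}_i$ directly, so it is sensitive to
the systematic bias of the level of theory and, through $\sigma_{ref}$, to
the referencing. The *scaled* channel first regresses
$\delta^{calc} = m\,\delta^{exp} + b$ per candidate and nucleus (ordinary
least squares) and scores
$e_i = (\delta^{calc}_i - b)/m - \delta^{exp}_i$, which removes
slope/offset error and makes the channel exactly invariant under any
affine distortion applied to all candidates — a property the test suite
asserts. Each error contributes a Student-t log density with per-channel
location $\mu$, scale $\sigma$ and degrees of freedom $\nu$; a
candidate's log likelihood is the sum over selected channels and sites,
and posterior probabilities are the normalised likelihoods under a
uniform prior:

$$P(i) = \frac{\exp \ell_i}{\sum_j \exp \ell_j}.$$

The prior is deliberately uniform over candidates: the point of the
method is to rank conformers by shift agreement alone, independent of the
force-field or DFT energy ordering, which is often unreliable for
flexible, hydrogen-bond-networked molecules. Boltzmann populations
$w_k \propto \exp(-\Delta E_k / RT)$ are computed separately so the two
rankings can be confronted.

Alongside the probability, the corrected error statistics
$\mathrm{CMAE} = \sum_i |\delta^{scaled}_i - \delta^{exp}_i| / n$ and
$\mathrm{CMaxErr} = \max_i |\delta^{scaled}_i - \delta^{exp}_i|$ are
reported per candidate and nucleus; they are the interpretable "how many
ppm off" companions to the sharper but opaque probabilities.

### Mixtures

For molecules in fast exchange, no single conformer reproduces the
population-averaged spectrum. The mixture scan enumerates every
molar-fraction vector on a simplex grid (all $k$-tuples of non-negative
multiples of the step summing to 1; $\binom{1/s + k - 1}{k - 1}$
compositions, e.g. 286 for $k = 4$ at step 0.1), averages the
representatives' *shieldings* at each composition, and scores each
composition as one DP4+ candidate with its own scaling fit. Averaging in
shielding space rather than shift space is a single-code-path
convenience: every downstream map (referencing, scaling) is affine, so
the two orders are mathematically identical. Probabilities are
normalised over the whole grid (uniform prior over compositions), so the
reported numbers are relative plausibilities within the scanned space,
and sum to 1 by construction. `band_probability()` integrates them over
any user-defined region; `aggregate_ternary()` collapses a
four-component grid onto three axes (minor components summed) for
ternary-diagram display, conserving total probability.

The mixture can never fit worse than the best pure conformer (vertices
are grid points), so a sharp interior maximum is evidence *for*
conformational averaging, not an artefact of extra flexibility — the
grid has no fitted parameters, only enumerated compositions.

Ensemble-averaged couplings provide an independent check on the same
compositions: $J^{mix} = \sum_k x_k J_k$ per pair and
$\mathrm{RMSD} = \sqrt{\tfrac1n \sum (J^{mix} - J^{exp})^2}$, scanned
over the same grid. Calculated $J$ values are consumed as input; no
Karplus-equation fallback is provided, because an empirical Karplus
parameterisation would introduce a second, unanchored model into a
package whose point is the quantum-chemical one.

## Parameters that matter

- **t-distribution parameters** ($\mu$, $\sigma$ in ppm, $\nu$), per
  nucleus and channel, and **reference shieldings** $\sigma_{ref}$ (ppm).
  These depend on the functional/basis combination and on whether the
  GIAO job used a continuum solvent model; they are shipped as an
  editable YAML (`inst/extdata/dp4_params.yaml`) with named `pcm` and
  `gas` sets, never hard-coded. The shipped defaults carry the classic
  DP4-lineage statistics ($\sigma_C = 2.306$ ppm, $\nu_C = 11.38$;
  $\sigma_H = 0.185$ ppm, $\nu_H = 14.18$; zero locations) in both
  channels; users working at a specific level of theory should replace
  them — in particular the unscaled-channel locations, which are
  genuinely non-zero at most levels — with the published values for that
  level. The log-file parser is deliberately agnostic about the solvent
  model, so choosing the matching parameter set is the user's
  responsibility.
- **Energy window** (default 12 kJ/mol) and **RMSD redundancy cutoff**
  (default 1 Å) for pre-filtering: wide enough to keep every conformer
  that could plausibly contribute population at room temperature, tight
  enough that near-duplicate geometries — which would only replicate
  each other's shifts — are removed. Filtering drops the energy window
  first, then scans in ascending energy so the result is independent of
  input order.
- **Merge distance** (default 0.25 Å) for clustering, with complete
  linkage by default: under complete linkage a cut at $h$ guarantees
  every within-cluster pair sits within $h$, which is what
  "geometrically homogeneous cluster" should mean. Single and average
  linkage remain selectable. RMSD uses heavy atoms by default (hydrogen
  positions are soft and inflate differences); any atom subset can be
  selected instead.
- **Grid step** (default 0.1): the resolution of the composition
  estimate. Finer steps grow the grid combinatorially and suggest a
  precision the data rarely support.
- **Temperature** (default 298.15 K) for Boltzmann weights, matching
  room-temperature acquisition. Energies are accepted in Hartree at the
  I/O boundary and converted once to kJ/mol (× 2625.4996); any
  well-defined conformer energy (electronic SCF or Gibbs) can be
  supplied, with the caveat that the two give different populations.

## Numerical choices

- Likelihoods are accumulated in log space and normalised by subtracting
  the per-set maximum before exponentiation: a 50-site product of
  densities underflows double precision otherwise. A test verifies that
  the log-space route reproduces direct products on small inputs.
- The scaling fit refuses fewer than two sites or zero variance in the
  experimental shifts, with an error instructing the user to fall back
  to the unscaled channel, rather than silently producing a degenerate
  slope.
- Grid fractions are rounded at the twelfth decimal after construction
  so compositions sum to exactly 1 at double precision and vertex rows
  compare exactly against `diag(k)`.
- Kabsch superposition enforces a proper rotation (determinant
  correction on the SVD), so mirror images are *not* superposable to
  zero; ties in any argmax (probability or error) are reported as a set
  rather than broken silently.
- A single candidate yields probability 1 with an explicit notice, and
  sites lacking an experimental shift are dropped from all candidates
  symmetrically, keeping comparisons paired.
- Scaled-channel CMAE/CMaxErr are computed from plain scaled errors; no
  outlier down-weighting of large ¹³C deviations is applied, so the
  statistics remain the literal mean/max of what the regression leaves
  behind.

## The synthetic generator: what it does and does not show

`generate_study()` emulates the *statistical* shape of a real
multi-conformer data set: ¹H sites in the 0.5–8.5 ppm shift range and
¹³C sites in 10–160 ppm; per-conformer shieldings spread around the site
centres with sd 0.3 ppm (¹H) and 3 ppm (¹³C), typical magnitudes of
conformational shift differences; pseudo-experimental shifts equal to
the ground-truth mixture average, optionally distorted by an affine
slope/offset (mimicking level-of-theory bias), plus t-distributed noise
(defaults σ = 0.10 ppm, ν = 10 for ¹H; σ = 1.5 ppm, ν = 10 for ¹³C);
energies arranged so Boltzmann weights track the generating fractions;
and per-conformer couplings mixed with the same fractions. Noise is
drawn from the same t family the scoring model assumes, which makes
mixture recovery a well-posed self-consistency check; a Gaussian option
(`gaussian_noise = TRUE`) probes mild model misspecification.

What it does **not** emulate: real correlations between neighbouring
sites, assignment errors, overlapping or missing peaks, solvent and
concentration effects, or meaningful geometries — coordinates are random
point clouds, sufficient to exercise the RMSD/clustering machinery but
chemically meaningless. Passing the recovery tests therefore
demonstrates that the *inference* is correct when the error model holds,
not that any particular real molecule will be solved; on real data the
binding constraint is the quality of the conformational search and the
QM shifts, which the package consumes but cannot repair.

Determinism: the generator seeds R's RNG on entry with the supplied seed
and restores the caller's RNG state on exit, so studies regenerate
bit-identically and surrounding code is unaffected.

## Validation problem sizes

The recovery experiments used in the tests and in
`scripts/acceptance.R` run 100 replicate studies with 4 conformers and
20 + 20 sites at the default noise (the regime where recovery within one
grid step is expected but not trivial — observed rates sit a little
above 90%), 10 zero-noise replicates (recovery must be exact), and
smaller 3-component studies for the brute-force cross-checks; a full
acceptance run takes well under a minute on one core. These sizes were
chosen as the smallest that make the stochastic rates stable to a few
percent.

## Known limitations

- Atom order must be consistent across conformers; there is no
  graph-matching or symmetry-equivalent renumbering before RMSD, and no
  automatic assignment of experimental peaks to atoms.
- The composition estimate is grid-restricted by design; there is no
  continuous optimisation over the simplex, and no kinetic or
  chemical-exchange modelling behind the mixture picture.
- The shipped t-parameters are placeholders of the correct form, not a
  calibration: quantitative probabilities on real data require the
  parameter set matching the actual level of theory and solvent model.
- Conformers differing mainly in hydroxyl/hydroperoxide rotamer
  orientation can be nearly isochronous at every carbon; the method can
  only distinguish what the shifts distinguish.
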