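---
title: "Linear-response redox free energies from vertical energy gaps"
author: "redoxlra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear-response redox free energies from vertical energy gaps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxlra)
```

## The model

For the one-electron oxidation Reduced → Oxidized + e⁻ in solution, the
reaction coordinate is the vertical energy gap ΔE = E_ox − E_red
evaluated at fixed nuclei. Free-energy perturbation gives the exact
one-sided identities

$$\Delta G^\circ_{ox} = -k_BT\,\ln\langle e^{-\Delta E/k_BT}\rangle_{red}
  = +k_BT\,\ln\langle e^{+\Delta E/k_BT}\rangle_{ox},$$

implemented in `zwanzig_free_energy()` by log-sum-exp so that
exponents up to |ΔE|/k_BT ≈ 400 cannot overflow. If the gap is Gaussian
on each surface — the linear-response regime — the cumulant expansion
truncates exactly after second order, and combining the two first-order
(mean-gap) truncations gives the estimator this package is built
around, `lra_free_energy()`:

$$\Delta G^\circ_{ox} = \tfrac12\left(\langle\Delta E\rangle_{red} +
\langle\Delta E\rangle_{ox}\right),\qquad
\lambda = \tfrac12\left(\langle\Delta E\rangle_{red} -
\langle\Delta E\rangle_{ox}\right).$$

Linear response additionally fixes the gap variance on both surfaces to
σ² = 2k_BTλ and places two common-curvature parabolas on the gap
coordinate (`marcus_parabolas()`, `predict()`):
G_red(x) = (x − ⟨ΔE⟩_red)²/4λ and G_ox(x) = (x − ⟨ΔE⟩_ox)²/4λ + ΔG°_ox,
which satisfy the identity G_ox(x) − G_red(x) = x for every x — the
algebraic signature of the construction, tested to 10⁻¹⁰ eV. The
electrode potential is E° = (ΔG°_ox − ΔG°_SHE)/n
(`oxidation_potential()`), with ΔG°_SHE = 4.44 eV per electron; because
energies are carried in eV per transferred electron, the Faraday
constant cancels numerically and never appears as a factor.

### Why the exponential estimator is reported but not trusted

Both directional exponential averages are exact in principle, and the
package evaluates them. They are dominated, however, by configurations
at |ΔE − m| of order σ²/k_BT below (above) the mean; for aqueous redox
couples σ/k_BT is of order ten, and the empirical average then behaves
like a lognormal sample mean with log-sd σ/k_BT. Its finite-sample
estimate is systematically biased by several tenths of an eV at any
sample size a simulation campaign can reach (the bias decays only like
σ√(2 ln n) against a σ²/2 target in log units). We verified this
directly: at λ = 1 eV, T = 310 K and n = 500 per state, the forward
estimator is biased by ≈ +0.45 eV while the LRA estimate is unbiased to
< 0.01 eV. For this reason the LRA value is the headline output; the
exponential values are printed alongside as a diagnostic, and they
agree with LRA only in the narrow-fluctuation regime (σ ≲ a few k_BT),
which the test suite exercises at σ = 0.05 eV.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| temperature | 310 | K | simulation temperature of the sampled ensembles; a field of every ensemble, not a constant |
| ΔG°_SHE | 4.44 | eV | absolute SHE oxidation free energy per electron |
| n_boot | 1000 | — | within-state paired bootstrap resamples; percentile 2.5/97.5 interval |
| gap histogram bin | 0.05 | eV | resolves structure in a ~1 eV-wide gap distribution |
| smoothing window | 3 | bins | moving average before mode/extremum counting |
| RDF bin width | 0.05 | Å | fine enough to localize a first peak to ~±0.03 Å |
| RDF r_cut | 10 | Å | covers two solvation shells; must stay ≤ box/2 for minimum image |
| QM cutoff radii | 0, 4.0–7.5 by 0.5 | Å | 0 is the solute-only sentinel; the sweep range over which gap convergence is probed |
| ion bin edges | 10, 20 | Å | near / intermediate / far counterion placements (r<10, 10≤r≤20, r>20) |
| k_B | 8.617333262e-5 | eV/K | CODATA |
| k_e | 14.399645 | eV·Å/e² | Coulomb constant in the package's unit system |

Units are fixed package-wide (Å, eV, e, K) with no autodetection.
Uncertainties are additive: the sampled literature workflow this
package systematizes reports none, so the bootstrap interval is the
package's own choice (percentile intervals on the half-sum of two
state means are well calibrated; measured coverage 0.96 over 200
replicates at the default conditions).

## Diagnostics

`running_average()` exposes the cumulative mean used to judge whether
500 frames suffice; its last element equals the ensemble mean to
1e-12 relative, by construction. `gap_histogram_modes()` counts strict
local maxima after smoothing — a converged single-basin ensemble shows
one mode. Note a caveat we quantified: at the linear-response σ ≈ 0.23
eV and n = 500, the default 0.05 eV bin holds only ~20 counts, and
Poisson noise fakes a second mode in roughly half of random ensembles;
for mode *counting* (rather than display) a 0.1 eV bin is reliable
(0/200 false multimodality in our checks). Both the bin width and
window are arguments.

`decorrelation_check()` guards against gaps that track slow
conformational drift: solute coordinates are rigid-body aligned to the
first frame by the orthogonal-Procrustes (Kabsch) SVD solution with
centroids removed, the aligned coordinates are decomposed by PCA
(plain covariance eigendecomposition, no mass weighting, hydrogens
included as read — the workflow it mirrors does not specify either),
and Pearson |ρ| of the PC1/PC2 projections against the gaps is
reported. Frames differing only by rigid motion have zero
conformational variance; correlations are then reported as 0 by
convention rather than NaN.

## Solvation structure and the counterion

`radial_distribution()` computes g(r) between pooled reference atoms
(default: all solute heavy atoms — every atom heavier than hydrogen)
and water oxygens, normalized by the ideal-gas shell expectation
N_ref·frames·ρ·(4π/3)[(r+dr)³−r³]; uniform random targets give g ≡ 1
within sampling error, which the tests use as an oracle. All distances
are minimum-image in a cubic box (components wrapped into (−L/2, L/2]),
cross-checked against a 27-image brute-force search; non-cubic boxes
are rejected rather than silently wrapped. Pooling all heavy atoms as
references (rather than averaging per-atom RDFs) is the reading we
adopt of the source workflow; for the first-peak position the two
differ negligibly.

`first_shell()` smooths g with a 3-bin moving average, takes r_max as
the first strict local maximum with g > 1 and r_min1 as the first
strict local minimum after it, and integrates n_wat = 4πρ Σ g r² dr up
to r_min1. Because first-shell estimation is genuinely ambiguous for
structureless or monotone profiles, a profile with no qualifying peak
returns NA fields behind an `undefined` flag instead of fabricated
values; if a peak exists but no strict minimum follows within r_cut,
the integral runs to r_cut (the shell is reported unterminated rather
than guessed).

`ion_distance_bins()` partitions frames by the minimum-image distance
from the solute center of mass (standard atomic masses) to the single
counterion, default bins r < 10, 10 ≤ r ≤ 20, r > 20 Å, and averages
the gaps per bin. For gaps generated independently of ion placement the
bin means agree within pooled standard errors — the negative control
mirroring the empirical finding that a randomly placed neutralizing ion
does not bias the sampled gaps.

## QM-region construction

`select_qm_region()` implements both water-selection criteria used for
electrostatic-embedding single points: **com** (water oxygen within r
of the solute center of mass) and **atom** (water oxygen within r of
the nearest solute atom). Membership is decided solely by the oxygen;
hydrogens follow their oxygen, so only whole waters are selected; ties
at exactly r are included; radius 0.0 is the solute-only sentinel; the
counterion is never quantum. Every atom lands in exactly one of the QM
set or the MM point-charge list (charges taken from the reduced or
oxidized set as requested) — an exact partition the tests verify
per frame. Selections are nested under increasing radius.

One property we deliberately do **not** assert universally: that the
atom criterion always selects a superset of the com criterion at equal
radius. It is true for the overwhelming majority of waters (the nearest
atom is almost always closer than the center of mass), and mean
selected counts are ordered accordingly, but it fails for the rare
water near the ring axis: above a planar ring of circumradius
r_ring, an on-axis oxygen at COM distance d has nearest-atom distance
√(d² + r_ring²) > d, so for d slightly below the cutoff the com
criterion selects it and the atom criterion does not. We measured about
one such water per ~35,000 selection decisions in dense synthetic
boxes.

`surrogate_gap()` provides a fixed-charge Coulomb stand-in for the
quantum single points: ΔE = ΔE_gas + k_e Σ (q_i^ox − q_i^red) q_j /
r_ij over solute atoms i and MM charges j, with QM waters contributing
no point-charge term. It has no polarization and is documented as
pipeline plumbing for trends (e.g. gap convergence as the QM region
grows), never as a substitute for electronic-structure gaps. Contacts
below 0.5 Å raise a clash error naming both atoms.

## The synthetic generator

`generate_gap_ensembles()` draws reduced gaps from
Normal(ΔG + λ, σ) and oxidized gaps from Normal(ΔG − λ, σ) with
σ = √(2k_BTλ) — exactly the statistics under which the LRA estimator is
unbiased — with an optional mean/variance-matched skew-normal shape for
robustness checks. Defaults (T = 310 K, 500 samples per state) match
the sampled production protocol the package emulates: 500 frames per
oxidation state. `generate_solvated_box()` builds cubic boxes (50 Å
default) with a rigid idealized solute template centered (regular
polygon rings, 1.4 Å bonds, hand-assigned bookkeeping charges whose
sums give the correct formal charges with ox − red = +1), rigid 3-site
waters (O–H 0.9572 Å, 104.52°, TIP3P-like charges) placed by seeded
rejection sampling with a 2.4 Å intermolecular heavy-atom separation,
and one neutralizing counterion placed uniformly at least 3 Å from the
solute.

What the generator does *not* emulate, and hence what passing tests do
not show about real data: frames are independent draws with no time
correlation (the workflow's own decorrelation check treats frames as
independent, but real MD frames are correlated and effective sample
sizes smaller); water density is configurable rather than ambient by
construction; the template charges and geometries are stand-ins, so
surrogate gap magnitudes are not physical; and real gap distributions
can deviate from Gaussianity in ways the skew option only caricatures.

## Numerical choices and degenerate inputs

- Log-sum-exp with max subtraction for all exponential averages.
- Exact identities (ΔG = half-sum, λ = half-difference) are computed in
  that literal form, so the invariants hold to machine precision.
- Percentile bootstrap interval clamped to bracket the point estimate
  (a percentile interval excludes it only through resampling accident
  at tiny n).
- λ ≤ 0 (mean_red < mean_ox) flags the fit as anomalous rather than
  erroring — the estimator is still defined; Marcus parabolas, which
  need λ > 0 for finite curvature, refuse it.
- Constant ensembles: histograms degenerate to one bin with one mode;
  Zwanzig of a constant is that constant.
- Rounding to printed precision uses half-away-from-zero with a 1e-9
  guard (`round_half_up()`), since binary floating point would
  otherwise round a printed 7.135 down.
- Problem sizes in the test suite are chosen for seconds-scale runs:
  synthetic boxes of 100–150 waters at 20–24 Å (the full-scale 50 Å /
  500-water boxes are exercised once in the generator tests), 50-frame
  pipeline smoke runs, 200-replicate coverage checks.

## Known limitations

Higher-order cumulant corrections and overlap-based estimators
(BAR/MBAR) are out of scope, as are binary trajectory formats, non-cubic
boxes, link-atom QM/MM boundaries, polarizable embedding, and any
actual execution of MD or quantum-chemistry engines. Two cells of the
published comparison table this package's worked examples mirror are
internally inconsistent with their stated inputs at rounding precision
(the phenol QM/MM and phenolate MM free energies, presumably computed
from unrounded averages); the bundled worked examples therefore cover
the ten arithmetic-consistent cells plus derived potentials.
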