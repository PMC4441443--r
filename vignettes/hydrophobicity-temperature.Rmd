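---
title: "Extracting the temperature dependence of amino-acid hydrophobicity from structure sets"
author: "hydrotemp developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting the temperature dependence of amino-acid hydrophobicity from structure sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

The burial of hydrophobic side chains is the dominant driving force of
protein folding, and it is strongly temperature dependent: the effective
cost of exposing a nonpolar group to water peaks somewhere above room
temperature and weakens on cooling, which is the accepted explanation of
cold denaturation. Direct calorimetric access to this dependence per amino
acid type is hard. An alternative is statistical: solution-NMR structures
are deposited together with their acquisition temperature, so a large,
redundancy-filtered set of chains solved at different temperatures carries
an imprint of how burial preferences shift with temperature. `hydrotemp`
implements that mining pipeline end to end, together with a synthetic
generator that makes every stage testable without any external data.

## Estimators

All estimators reduce a temperature bin of chains to per-residue-type
sufficient statistics and return a core-to-surface transfer free energy in
kT units, oriented so that positive = burial-favouring (hydrophobic). The
raw material is the relative exposure of residue $r$,
$\alpha_r = S_r / \max S_{a(r)}$, where $S_r$ is the accessible surface
area (DSSP's ACC column, averaged over the NMR models of the deposition)
and $\max S_a$ the maximum accessible area of the type in an unfolded
chain. $\alpha_r$ is clamped to $[0,1]$: extended conformations can exceed
the tabulated maximum.

* **contact**: a knowledge-based pair potential restricted to the
  residue–solvent column. Each residue offers $q = 4$ contact slots, of
  which $q\alpha_r$ touch water, so a type's observed solvent contacts are
  $c_{a,w} = \sum_{r \in a} q\alpha_r$ and the total pool of water contact
  points is $W = \sum_r q\alpha_r$. Under random mixing the expected count
  is $\omega_{a,w} = n_a q \cdot W / (qN + W)$, and
  $\Delta G = -\ln(c_{a,w}/\omega_{a,w})$.
* **surface**: a burial propensity with a hard cutoff — a residue is
  *buried* when $\alpha_r < 7\%$ (strict). To make the buried and
  non-buried viewpoints exactly antisymmetric the propensity is defined
  like a partition coefficient,
  $\Delta G = \ln\!\big[(N_{a,b}/N_{a,nb}) \,/\, (N_b/N_{nb})\big]$.
* **area** and **scaled area**: the cutoff-free limit, comparing a type's
  summed exposure to the average residue:
  $C_a = -\ln\!\big[(N/n_a)\sum_{r\in a}\alpha_r / \sum_r \alpha_r\big]$,
  optionally multiplied by $\max S_a$ (for pools, the count-weighted mean
  of member maxima) so that large residues score proportionally larger.

Cells with a zero count are reported as missing (`NA`), never $\pm\infty$;
they simply drop out of downstream fits. The natural logarithm is used
throughout, including in the area estimator, for consistency.

## Binning, reference, and inference

Chains are assigned to five inclusive integer-kelvin bins — 265–290,
291–296, 297–299, 300–305, 306–340 — after rounding the reported
temperature to the nearest kelvin (bounds are integers, reported
temperatures may be fractional). Acquisition temperatures at or below
150 K are rejected as a data-entry artefact (values entered in celsius
cluster just above absolute zero, well separated from genuine NMR
temperatures); entries with several disagreeing temperatures are rejected
too.

Raw statistical potentials are only relative within a bin, so to compare
across temperatures every bin/method is optionally shifted by a
*reference*: the energy of the pooled charged + polar residues (ARG, ASP,
GLU, LYS, ASN, GLN, SER, THR) of the same bin. Pooling always sums counts
before evaluating the energy — never averages per-type energies.

Three inferential tools sit on top:

* **Split-sample errors.** Each bin is split at random into $k = 5$
  equal parts (remainders round-robin), the estimator recomputed per part,
  and $SE = sd(\text{parts})/\sqrt{5}$; $\pm 2\,SE$ is the quoted 95%
  interval. With only 5 parts this is a $t$-like quantity with 4 degrees
  of freedom, so the realised coverage of $\pm 2\,SE$ is ~88%, not 95% —
  the coverage test in the suite asserts exactly that behaviour. The
  partition is random (the deposition order of chains is not exchangeable)
  and seeded.
* **Permutation significance.** The quantity of interest is
  $\Delta\Delta G = \Delta G(297\!-\!299) - \Delta G(265\!-\!290)$,
  positive when hydrophobicity is weaker in the cold. Chains (the sampling
  unit) of the two bins are pooled, temperature labels reshuffled
  preserving bin sizes, and the statistic recomputed 1000 times; the
  p-value is the fraction of resamples at least as large in absolute value
  as the observation. Ties and non-finite resamples count as exceedances
  (conservative). When the corrected statistic is tested, the reference
  correction is recomputed inside every resample.
* **Parabola fits.** Within each bin the mean chain temperature is the
  abscissa; $\Delta G(T)$ is fitted with a weighted least-squares parabola
  (weights = the entity's residue count per bin, solved by QR on the
  weighted design). The vertex $-a_1/(2a_2)$ is only interpreted as the
  temperature of strongest hydrophobicity when $a_2 < 0$ (`is_max`).

## The synthetic generator and what a green test establishes

`generator_config()` states a world in which the analysis assumptions hold
exactly: residue types i.i.d. from an average globular-protein
composition; chain lengths normal (100 ± 30, floor 20), typical of NMR
targets; chains spread over the five bins in the proportions of the
filtered structure counts of the source study (207/344/1033/560/412),
uniform within a bin. Each class carries an injected transfer-energy
parabola $g_c(T) = g_{\max} - \kappa (T - T_{peak})^2$ in kT, mapped to a
mean exposure through the logistic link $\mu = 1/(1+e^{g})$ — the simplest
monotone map onto $(0,1)$ consistent with a two-state buried/exposed
picture — and exposures are Beta-distributed around $\mu$ with
concentration 2.5.

Default curve parameters were fixed once, for realism and identifiability,
before any test was written: the hydrophobic class peaks at
$T_{peak} = 310$ K — the low end of the 310–350 K window reported for
such fits, and the end that temperature coverage of the NMR record (very
few depositions above 320 K) can actually constrain — with
$\kappa = 9\times10^{-4}$ kT/K², which makes the injected low-vs-room
surface $\Delta\Delta G \approx 0.36$ kT, the magnitude scale reported by
this kind of analysis. Charged ($g = -1.2$) and polar ($g = -0.8$)
residues are surface-seeking and temperature-flat, which is what makes
them usable as a reference. At the 7% cutoff this yields roughly 35%
buried hydrophobic residues and well under 1% buried charged residues,
with the right-skewed, zero-spiked exposure distributions seen in real
relative-accessibility data.

`truth_report()` returns the closed-form expectation of the
surface-method quantities under a configuration (burial probability by
quadrature over the within-bin temperature law), so recovery tests compare
an estimate against an analytic truth rather than against another
simulation.

The generator deliberately omits what real data have and the model does
not: within-chain correlation of exposure (cores are spatial, not i.i.d.),
composition drift with temperature of deposition, per-structure
differences in model count and quality, and any pairwise residue–residue
energetics. A green recovery test therefore establishes that the
*pipeline* is a consistent estimator of the world it assumes — not that
the biological claim is true; the latter would need the real structure
record.

## Numerical and design choices

* Exposure is computed by averaging areas over models first, then dividing
  by $\max S_a$ (the averaging sentence of the source protocol), not by
  averaging per-model fractions.
* The max-ASA scale is configurable and defaults to the theoretical
  Gly-X-Gly values of Tien et al. (2013); results depend only weakly on
  the scale.
* Buried means strictly $\alpha_r < 0.07$.
* The 5-way split is random and seeded, not deposition-ordered.
* p-values are stored as plain fractions; the print method displays
  `< 1/n` when no resample reached the observation.
* Nonstandard residues are dropped (with a warning), not remapped.
* Counts tables are written with 17 significant digits so that a
  write/read round trip is bit-exact.
* The type-I-error acceptance test runs the null generator at 400 chains
  per repetition rather than the 1500-chain default, purely for runtime:
  the size of a permutation test does not depend on sample size.

## Known limitations

* The published tables of the source analysis can only be reproduced from
  its supplementary per-structure counts file; without it the
  corresponding acceptance test reports exactly that, and the synthetic
  criteria are the effective acceptance surface.
* Pairwise residue–residue contact energies from 3D geometry are out of
  scope; only the residue–solvent column is implemented.
* With only five bins, the parabola vertex is an extrapolation whenever
  the true peak lies above ~320 K; its uncertainty grows quickly with
  $T_{peak}$, which is why the generator's default peak sits at the edge
  of the constrained region.
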