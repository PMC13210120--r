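---
title: "Distance-based NMR crystallography validation: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-based NMR crystallography validation: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dqcryst)
```

## The model

A 2Q–1Q ¹H correlation spectrum acquired with a short double-quantum
excitation period operates in a linear regime: the integrated 2D volume of
the peak(s) belonging to a proton site-pair family j–k is proportional to
the squared effective dipolar coupling of that family,

$$ b_\mathrm{eff}^2(\mathrm{H}^j\text{–}\mathrm{H}^k) \;=\;
   \sum_{m,n} b^2(r_{mn}), \qquad b(r) = K_{HH}\, r^{-3}, $$

with the sum running over all crystallographic and periodic copies of the
pair (for j = k each unordered pair once), and
$K_{HH} = -\mu_0\hbar\gamma_H^2/8\pi^2$. Because only *ratios* of these
quantities are compared, the recoupling scale factor $\kappa$ of the pulse
sequence cancels; this is verified as a property test rather than assumed.

Three derived quantities carry the validation:

* **fractions** $f_\alpha = b_\mathrm{eff}^2 / b_\mathrm{eff}^2(\mathrm{tot})$
  for a model $\alpha$, against $f_\mathrm{NMR} = I / I_\mathrm{tot}$;
* the **R² statistic**
  $1 - \sum(f_\alpha - f_\mathrm{NMR})^2 / \sum(f_\mathrm{NMR}-\bar f)^2$,
  where the denominator is the population total sum of squares;
* **effective distances**
  $r_\mathrm{eff} = (M_{jk} K_{HH}^2 / b_\mathrm{eff}^2)^{1/6}$, an r⁻⁶
  aggregate close to the shortest contact, with $M_{jk}$ the count of
  near-degenerate shortest couplings. Experimental fractions convert to
  distances only *relative to a reference structure* (its
  $b_\mathrm{eff}^2(\mathrm{tot})$ and $M_{jk}$), so NMR-referenced
  distances are reported as deviations, not absolutes.

The chemical-shift arm is independent: computed shieldings are converted
by $\delta = \sigma_\mathrm{ref} - \sigma_\mathrm{iso}$ with
$\sigma_\mathrm{ref}$ fitted (slope fixed at −1, so the intercept is the
mean of $\delta_\mathrm{exp} + \sigma_\mathrm{iso}$) on a calibration
structure, then per-site deviations and their population rmsd are
tabulated.

## Parameters that matter

| parameter | default | why |
|---|---|---|
| distance cutoff | 1000 pm | r⁻⁶ sums converge well below this; `cutoff_convergence()` reports the 800 pm tail change per pair |
| multiplicity tolerance | 10 % relative to the shortest distance | the only delimitation of "the set of largest couplings" that makes three near-equal methyl distances count as M = 3; configurable |
| merge tolerance in `expand_to_p1()` | 10 pm | typical special-position noise in deposited CIFs |
| motion model | `static` or `fast_3site` | the two limits that admit closed-form scaling; fast three-site jumps multiply each intra-methyl coupling by −1/2 (×1/4 on b²) and leave methyl–external couplings untouched. Intermediate (hindered) rotation is deliberately treated as static |
| κ, τ_exc | 0.5, 16.67 µs | recorded in the config echo; κ cancels, and the simulator is linear so τ_exc never enters a propagation |
| linewidths | 0.15 / 0.25 ppm (1Q / 2Q Gaussian σ) | typical fast-MAS ¹H widths; volume ratios are lineshape-independent for separated peaks |

## Counting convention

Pair sums are normalized "per central cell": the first proton of every
counted pair lies in the home unit cell; distinct central atoms of an
equivalent pair obey m < n (each unordered pair once), and a proton paired
with its own lattice image counts every translation T ≠ 0. This
reproduces, e.g., the six nearest neighbours of one proton in a primitive
cubic cell and the three intra-methyl pairs of a CH₃ triangle, and it is
frozen by a brute-force supercell oracle
(`brute_force_pair_distances()`) that shares no distance code with the
production enumerator. The image search range is derived from the
inter-planar spacings of the cell metric, so sub-cutoff cells (a 400 pm
toy lattice) are handled without a fixed 3×3×3 shell.

## What the synthetic generators emulate — and what they do not

`make_methyl_structure()` and `make_toy_crystal()` produce isolated
motifs (methyl triangles, H-bond contacts, a periodic chain, random
cells) with *exact* target geometry and an independently computed
ground-truth coupling table. `perturb_fractions()` injects noise at the
point the real analysis acquires it: the integration of replicate
rectangles. A 5 % multiplicative perturbation on fractions mirrors the
dispersion of "several independent integrations" of one peak.
`synth_shieldings()` generates $\sigma = \sigma_\mathrm{ref} - \delta +
\mathcal{N}(0, sd)$, the statistical structure the reference fit assumes.

What a green test therefore establishes: the algebra from geometry to
statistics is exact, the counting convention matches an independent
oracle, and the statistics degrade gracefully under integration-like
noise. What it does not establish: agreement with spin dynamics (no
recoupling propagation, no relaxation, no buildup curves), behaviour
under peak overlap worse than the grouping mechanism models, disorder or
partial occupancy (warned, ignored), or intermediate methyl dynamics.

## Numerical choices

* `b_eff²` is accumulated directly in Hz² double precision; magnitudes
  (~10⁸ Hz²) are far from overflow, and κ-invariance is guaranteed by
  construction of the ratios, not by symbolic cancellation.
* Cross-peak volumes split exactly in half between the two peaks of a
  j ≠ k coherence, so integrating both rectangles recovers the full pair
  volume; any other split would be unobservable after summation anyway.
* Replicate integration rectangles jitter their bounds by ±10 % under a
  caller-supplied seed; RNG state is saved and restored so library calls
  never disturb a user's random stream.
* Pairs with `f_NMR = 0` get an infinite-distance sentinel and are
  excluded from the rmsd (the distance formula diverges at zero
  coupling), with a warning.
* Assignment blocks are solved by exhaustive permutation up to size 8;
  ties (degenerate calculated shifts) keep input order and are flagged
  ambiguous rather than resolved arbitrarily.
* Merged (overlapping-peak) groups sum their `b_eff²`/intensities before
  normalization; a merged group's effective distance uses the dominant
  member's multiplicity. Exclusion removes a group from the normalizing
  denominator while still reporting its fraction on the retained scale,
  preventing one unexplained intensity from corrupting every other
  distance.

## Open design points, decided

* The cutoff is applied to raw distances (with a convergence diagnostic)
  rather than as a per-pair convergence criterion; the reference tables'
  exact convergence protocol is not recoverable, and the 1000 pm raw
  cutoff reproduces the worked methyl aggregate.
* R² recomputed from *printed, rounded* fraction columns reproduces the
  published Para/DFT value within 0.01 but not every published R² (the
  unrounded inputs and exact grouping of the originals are not
  recoverable). Tests and acceptance therefore assert only the
  reproducible case, at ±0.01.
* The rmsd over pairs weights each site-group pair equally (one row, one
  weight), matching how the published per-pair tables summarize; it is
  not weighted by the number of underlying proton pairs.
* Occupancy is never used as a weight; partially occupied sites warn.

## Known limitations

No spin-dynamics simulation (the ≲1/3-of-maximum short-τ_exc criterion is
a documented validity condition the user must check experimentally); no
automatic assignment-block inference; no structure refinement driven by
the NMR constraints; the CIF subset covers cell/symmetry/atom-site records
but not disorder groups or multi-block files.
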