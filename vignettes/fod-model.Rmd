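---
title: "The fuzzy-oil-drop model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The fuzzy-oil-drop model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fodm)
```

## The model

Water drives a folding polypeptide toward a micelle-like arrangement:
hydrophobic side chains buried centrally, polar ones exposed. `fodm`
quantifies how far a given structure realizes that arrangement, and how
strongly a non-aqueous environment would have to modify the target field to
explain what is observed.

Each residue is reduced to an **effective atom**, the unweighted mean of
its heavy-atom coordinates. Over a *structural unit* — a single chain, a
proto-fibril (one stack of chains in a fibril), or a super-fibril (the
whole assembly) — four per-residue distributions are compared, each
normalized to unit sum:

* **T (theoretical)** — a 3D Gaussian spanned over the unit's body,
  evaluated at every effective atom in the principal-axis frame:
  \(T_i \propto \exp(-x_i'^2/2\sigma_x^2)\exp(-y_i'^2/2\sigma_y^2)
  \exp(-z_i'^2/2\sigma_z^2)\). This is the idealized micelle: maximal
  hydrophobicity at the center, vanishing at the surface.
* **O (observed)** — pairwise hydrophobic interactions collected with
  Levitt's polynomial attenuation. For residues \(i, j\) at distance
  \(r_{ij}\le c\):
  \(O_i \propto \sum_j (H_i^r + H_j^r)\,
  [1 - \tfrac12(7(r_{ij}/c)^2 - 9(r_{ij}/c)^4 + 5(r_{ij}/c)^6 -
  (r_{ij}/c)^8)]\),
  where \(H^r\) is the residue's intrinsic hydrophobicity. The bracket is
  1 at contact and 0 at the cutoff; pairs beyond \(c\) contribute nothing.
* **R (reference)** — uniform, \(R_i = 1/N\): hydrophobicity dispersed
  with no core at all.
* **M (modified)** — the micelle field blended with its complement:
  \(M_i \propto T_i + K\,[(T_{max}-T_i)]_n\), the complement normalized to
  unit sum before blending. The complement is the membrane-like inverse of
  the drop: maximal where the Gaussian is smallest.

Distances between distributions are Kullback–Leibler divergences (base 2,
reported in bits). Two summary parameters follow:

\[ RD = \frac{D_{KL}(O|T)}{D_{KL}(O|T) + D_{KL}(O|R)} \]

\(RD < 0.5\) means the observed distribution is divergence-closer to the
micelle target than to structureless dispersion — a centric hydrophobic
core is present. The environment parameter \(K\) is the value minimizing
\(D_{KL}(O\,|\,M(K))\): \(K = 0\) is a purely aqueous ordering; large
\(K\) means the structure records a strongly non-aqueous (e.g. membrane)
field.

## Tunable parameters

| knob | default | meaning |
|---|---|---|
| scale | `black_mould` | intrinsic hydrophobicity per residue, normalized 0–1 |
| `cutoff_c` | 9.0 Å | Levitt-function interaction cutoff |
| `sigma_rule` | `extent_over_3` | Gaussian width: half-extent along each principal axis / 3 |
| `include_self` | `TRUE` | whether the \(j=i\) term (distance 0) enters \(O_i\) |
| K grid | 0–10 by 0.1 | scan range and resolution of the K fit |

Every result carries a snapshot of these five knobs, because any numeric
comparison depends on them.

**Scale.** Divergence arithmetic needs nonnegative hydrophobicities, so
all registered scales live on \([0,1]\). The default is the Black & Mould
(1991) relative-hydrophobicity scale, which is published directly on that
range (Phe = 1, Arg = 0); Kyte–Doolittle (min–max rescaled) is built in as
an alternative, and two-column text files supply anything else. The
package does not claim either scale is the uniquely correct one — scale
choice is logged in every output for exactly that reason.

**Cutoff.** 9 Å is the conventional reach of the Levitt pairwise function
in hydrophobic-core analysis; it is a config knob, not a constant.

**Sigma rule.** "Spanned over the body" is made concrete as: center at the
mean effective-atom position, axes from the positional covariance
(descending eigenvalue, right-handed — fixed deterministically so frames
are reproducible even though the even, separable Gaussian is indifferent
to axis sign), and \(\sigma\) = half-extent/3 along each axis, so the unit
sits within \(\pm 3\sigma\). A sample-standard-deviation rule is provided
as an alternative. Both are floored at 1 Å: flat amyloid ribbons otherwise
produce singular Gaussians.

**Self term.** The pairwise sum's bound is read literally (\(j\) runs over
all residues, \(r_{ii}=0\le c\)), so the self term is included by default;
excluding it is a pure normalization-level change exposed as a flag.

**K grid.** K is conventionally reported to one decimal; a 0.1-step grid
up to 10 matches that precision with headroom. Ties break toward the
smaller (least-modified) K. Whether a continuous optimizer would be more
faithful is undecidable from one-decimal reported values; the grid also
makes the fit exactly reproducible.

## Structural units

Units are assembled from author residue numbering (deposited fragment
annotations use author numbers), chains concatenated in the caller's
order. Insertion-coded residues are distinct and ordered after their base
number. Multi-model depositions default to the first model, overridable —
which model underlies any published per-structure number is generally
unstated, and the choice is recorded in provenance. Alternate locations
keep the highest-occupancy label (tie: first alphabetically). Which chains
constitute a proto-fibril is deposition-specific knowledge and is always
user-declared; no automatic partitioning is attempted.

## Stepwise elimination

For units with \(RD \ge 0.5\) the residues carrying the discordance are
identified greedily: remove the residue with the largest \(|O_i - T_i|\)
on the *current* profiles, recompute everything on the kept set
(distributions renormalized; envelope refit by default, since removal
changes the body — a flag freezes the original envelope, and both
behaviors are logged), and stop when RD drops below the target, when a
quarter of the unit has been removed (`max_fraction` guards against
degenerate "remove half the protein" runs), or when no residues remain to
remove. Absolute difference is the simplest reading of "high differences"
and reproduces the expected culprits (polar deficits at buried positions,
hydrophobic excesses at exposed ones) on the synthetic fixtures. A
caller-named segment can instead be removed in one step, reporting RD and
K before and after.

The greedy local step is a heuristic, not a theorem: on well-fitted units
(RD well below 0.5) the largest-|O−T| residue can sit at the envelope
center, and deleting it *raises* \(D_{KL}(O|T)\) after renormalization. In
the regime where elimination actually operates — no centric core — the
property tests confirm the step is non-increasing across all seeded cases.

## The synthetic generator

`synthetic_spec()` / `generate_unit()` produce seeded chain-like point
sets: a self-avoiding walk with 3.8 Å steps inside a protein-density
sphere (`globule`), or planar zig-zag strands stacked 4.8 Å apart — the
cross-β repeat — for fibril-like fixtures (`ribbon_stack`). The planted
hydrophobicity pattern is the model's own target: an isotropic Gaussian of
the distance from the center whose width follows the same ±3σ convention
as the fitted envelope (`micelle`), its complement (`inverted`), a single
residue type (`uniform`), or a micelle with one maximally hydrophobic
residue forced onto the surface (`planted_outlier`). Continuous targets
are mapped to the nearest real amino acid by scale value, so fixtures stay
valid inputs for the scale-dependent observed profile.

The generator's defaults — 80 residues, noise-free assignment, 20 seeds in
the property suite — are the study conditions under which classification
is asserted (micelle fixtures below RD 0.5, inverted fixtures above with
\(K > 0\), in at least 18 of 20 seeds each). What these fixtures do *not*
emulate: real backbone geometry, sterics, hydrogen-bond networks, sequence
correlation, or the partial, noisy core organization of real deposited
fibrils. Passing them shows the pipeline detects planted organization of
the exact kind the model formalizes; it does not show that any particular
real structure will land on a particular side of 0.5.

## Numerical choices

* The Gaussian is evaluated in log space and floored at the smallest
  positive double, so far-flung residues cannot underflow \(T_i\) to an
  exact zero (T must stay strictly positive for \(D_{KL}(O|T)\)).
* \(0\log 0 = 0\) in every divergence; a zero in the reference
  distribution facing positive mass is an error, never epsilon-patched —
  it can only arise from a pathological scale the user should see.
* \(O = T = R\) (all divergences zero) reports \(RD = 0.5\) with a
  warning rather than NaN.
* A uniform T makes the complement \(T_{max}-T_i\) vanish; its
  normalization is then taken uniform, making M well-defined (and K
  irrelevant, resolved to 0 by the tie rule).
* Degenerate geometry (collinear/coplanar units) triggers the σ floor
  with a warning rather than an error.

## Problem sizes

The property suite runs entirely on synthetic units: oracle equivalence
on 100 seeded instances (N = 20–30), classification on 20 seeds per kind
at N = 80, elimination and reporting tests at N = 30–60. These sizes were
chosen to exercise every code path at desk scale; the statistics are not
sensitive to them (N = 80 globules already show the full RD separation
between planted kinds). The acceptance script reruns the same conditions
from a caller-supplied master seed.

## Known limitations

* RD and K are point values; no uncertainty is attached.
* No solvent-accessible-surface or per-atom hydrophobicity refinement;
  the effective-atom reduction is the model's resolution.
* Numeric agreement with any published per-structure table depends on the
  scale / cutoff / σ-rule convention used there; when that convention is
  not printed alongside the numbers, only classification-level agreement
  (which side of 0.5) is a robust expectation.
* Biological-assembly expansion, structure repair and secondary-structure
  assignment are out of scope; inputs are analyzed as deposited.
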