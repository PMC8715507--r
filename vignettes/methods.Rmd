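---
title: "Methods: chi1 rotamer determination from vicinal couplings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chi1 rotamer determination from vicinal couplings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotamerfit)
```

## The model

A vicinal three-bond coupling constant across the C&alpha;&ndash;C&beta;
bond depends on the dihedral angle &theta; of its coupling path through an
extended Karplus equation, here the six-term truncated Fourier series

$$ J(\theta) = C_0 + C_1\cos\theta + C_2\cos 2\theta + C_3\cos 3\theta
   + S_1\sin\theta + S_2\sin 2\theta \quad \mathrm{(Hz)} . $$

The printed sources this package regresses against name the coefficients in
exactly this order but do not reproduce the equation body in the text we
had access to; we adopt the standard form above (cosine harmonics up to
3&theta;, sine harmonics up to 2&theta;), which matches the named
coefficient set and the empirical Karplus literature. All angle arithmetic
is in degrees wrapped to $(-180, 180]$.

Each coupling path is offset from &chi;&#8321; by a phase shift,
$\theta = \chi_1 + \Delta\theta$. The tetrahedral defaults
($\Delta\theta \in \{0, \pm 120^\circ\}$) are tabulated per residue type in
`residue_topology()`; the backbone-side assignments are N&prime; = 0,
C&prime; = +120, H&alpha; = &minus;120, and the &beta;-side reference
branch (C&gamma;1 for Val/Ile, C&gamma; for Leu) carries 0. Optimized
geometries deviate from ideal tetrahedra by up to ~15&deg;, so every
function accepts per-coupling `delta_theta_override` values; refined phases
are not shipped because they are not printed in our sources.

### Fitting coefficients

`fit_coefficients()` is ordinary least squares on the design
$\{1, \cos\theta, \cos 2\theta, \cos 3\theta, \sin\theta, \sin 2\theta\}$,
restricted to any requested subset of terms. On the canonical six-angle
grid (0, &plusmn;60, &plusmn;120, 180&deg;) with all six terms the design
is square and orthogonal up to column scaling, so the fit interpolates
exactly; with fewer terms the discarded harmonics alias into the retained
ones, which the tests exercise explicitly. Rank deficiency (e.g. requesting
$C_3$ on a grid where $\cos 3\theta$ is constant) is an error naming the
aliased columns, not a silent pseudo-inverse. An optional sign constraint
reproduces the empirical convention of forcing $C_1 \le 0$ (&ge; 0 for
&sup1;&#8309;N partners, whose magnetogyric ratio is negative) by clamping
$C_1$ and refitting.

### Comparing parameterizations

Two rmsd statistics are kept mutually consistent by construction:
`rmsd_couplings()` is the root-mean-square difference of two coupling sets,
and `rmsd_coefficients()` is *defined* as `rmsd_couplings` of the two
curves sampled on the canonical six angles. Discrete orthogonality on that
grid gives the closed form
$\sqrt{\Delta C_0^2 + \tfrac12(\Delta C_1^2 + \Delta C_2^2 + \Delta S_1^2
+ \Delta S_2^2) + \Delta C_3^2}$ &mdash; note the full weight on
$\Delta C_3$, because on six points $\cos 3\theta$ aliases to the
alternating vector of unit norm. A `mode = "continuous"` flag gives the
full-circle Parseval alternative (weight &frac12; on every harmonic),
for users comparing against continuous-integral conventions.

The cross-type summary `awrmsd()` is, in percent,
$100\sum_i w_i\,(\mathrm{rmsd}_i/|C_{0,i}|)\,/\sum_i w_i$ with weights
$w_i = |C_{0,i}|$ by default, collapsing to
$100\sum_i \mathrm{rmsd}_i / \sum_i |C_{0,i}|$. The defining text was not
printed in our sources; this is the unique reading in which $|C_0|$ acts
simultaneously as the "average coupling" normalizer and as the relative
weight, and it keeps the statistic invariant under a common rescaling of
the weights. Branch couplings that share a type can be pooled or kept
separate by the caller; the package does not force either choice.

## The three conformer models

For a residue with $n$ measured couplings $J_i^{\exp}$:

* **UMS** minimizes
  $\mathrm{rmsd}_J(\chi_1) = \sqrt{\tfrac1n \sum_i (J_i^{\exp} -
  J_i(\chi_1))^2}$ over a 0.1&deg; grid (the reference results quote
  &chi;&#8321; to 0.1&deg;; no sub-grid refinement is attempted). The
  Karplus degeneracy generically yields a second minimum roughly opposite
  the first, so `ums_minima()` returns *all* local minima (plateau-aware,
  on the periodic grid) ranked by residual.
* **TMSS** models the couplings as a population mixture of the three
  staggered conformers (60, 180, &minus;60&deg;) and minimizes the same
  residual over the probability simplex. The 3-variable constrained
  least-squares problem is solved exactly by enumerating its seven support
  sets (vertices, edges, interior KKT solve). A generic
  quadratic-programming solver is the usual tool for such problems; at this
  size exhaustive active-set enumeration is provably optimal and removes a
  solver dependency. The tests verify it against a 0.001-resolution simplex
  grid.
* **TMST** frees the angle: conformers at &chi;&#8321;,
  &chi;&#8321;&nbsp;&plusmn;&nbsp;120&deg; with two free populations. The
  joint optimum is an outer 0.1&deg; grid over a 120&deg; fundamental
  domain (the conformer triple is invariant under 120&deg; rotation with
  permuted labels) with the exact simplex solve inside. The report is
  canonicalized so `chi1` belongs to the most populated conformer and each
  population is tagged with its nearest staggered bin via the
  total-distance-minimizing cyclic assignment (deterministic at ties).

Since UMS and TMSS are restrictions of TMST (unit population; pinned
angle), rmsd(TMST) &le; min(rmsd(TMSS), rmsd(UMS)) up to grid resolution;
this nesting is asserted in the test suite.

### Minimum selection and uncertainty

Among UMS local minima the package prefers, by default, the lowest-residual
minimum lying within &plusmn;30&deg; (inclusive) of a staggered angle, and
falls back to the global minimum when none qualifies
(`force_global = TRUE` disables the preference). This single rule
reproduces the documented second-minimum choices in the reference tables
(three Leu residues select their second minimum) without per-residue
overrides. Ties in residual are broken by smaller deviation from the
nearest staggered angle.

The &chi;&#8321; uncertainty is the distance from the selected minimum to
either edge of the contiguous region where the residual stays below the
minimum plus a 0.2 Hz window (configurable). The two extents are reported
in below-/above-minimum order; the printed sources do not state their
ordering convention, and our fixtures are symmetric enough that it never
matters for the regression.

### Classification

A residue is **unimodal** iff (a) the selected UMS &chi;&#8321; is within
&plusmn;30&deg; (inclusive) of 60, 180 or &minus;60&deg;, and (b) the
largest conformer population *strictly* exceeds 0.60. Published usage
varies between basing (b) on the TMSS and on the TMST populations; both
agree on every reference residue, and the package defaults to TMST
(`population_from = "tmss"` switches). Both thresholds are configurable.

## Circular statistics

Angles are compared on the unit circle: `circ_distance()` is the minor arc
(&le; 180&deg;), `circ_mean()` is atan2 of the summed unit vectors (a
vanishing resultant is an error, never a silent 0). `rmsd_chi1()` is the
root-mean-square circular distance over shared residues, excluding pairs
deviating *strictly more* than 40&deg; (a 40.0&deg; deviation is kept);
the analogous conventions — &plusmn;30&deg; staggered inclusive, &gt;30&deg;
X-ray outlier exclusive — are fixed here once. `robust_xray_average()`
iterates exclude-then-average to a fixed point with a monotone-shrinking
retained set (one-pass mode by flag); the sources do not say whether their
removal was iterated, and on clustered crystallographic angles one pass
almost always already is the fixed point. The reported spread is the rms
circular deviation from the final mean; it matches the magnitude of the
&plusmn; values in the reference tables but is not separately validated,
because the individual X-ray angles behind them are in unavailable
supporting material.

## Reference fixtures and what the regression establishes

`load_flavodoxin_tables()` ships the published per-residue results for
*D. vulgaris* flavodoxin: 25 unimodal residues (UMS angle, residual and
uncertainty; TMSS and TMST populations; coupling count; two empirical NMR
determinations; robust X-ray average) and 4 trimodal residues with both
UMS minima and dual X-ray averages. File integrity is md5-checked at load.
`reference_stats()` recomputes the cross-method circular rmsd matrix, the
pooled coupling count (181) and the 25/4 classification from those columns.

These fixtures regress the *analysis* stages (circular statistics,
classification, bookkeeping). The per-residue residuals, populations and
angles themselves are **not** desk-reproducible here: they require the
quantum-chemically derived Fourier coefficients and the original
experimental couplings, both of which live in supporting material that is
not printed in our sources. The inference stages are therefore validated
generatively instead (below).

## Synthetic data: the stated world

`generate_residue()` draws couplings from a known Karplus set as a pure
conformer or a staggered/trigonal population mixture, adds independent
Gaussian noise with a common &sigma; (the sources give no error model;
heteroscedastic per-type &sigma; can be emulated by masking and merging),
and optionally masks couplings to mimic incomplete data (e.g. the
five-proton-coupling pattern of one reference residue). Seeded generation
uses Mersenne-Twister with inversion sampling, so output is byte-identical
across platforms. The acceptance battery uses &sigma; = 0.2 Hz on nine
couplings for the stochastic recovery property — a noise level matching
the package's default uncertainty window — and noise-free generation for
the exactness properties.

A green synthetic test establishes that each fitting stage inverts its own
generative model (and that the exact solver beats a dense oracle); it does
not establish that any particular Karplus parameterization describes real
molecules — that is what the fixture regression of the published
cross-method statistics speaks to, and only at the aggregate level.
`demo_karplus_set()` is labelled synthetic for the same reason: its
coefficients have realistic magnitudes and signs but are invented, because
the published coefficient tables are not available to ship.

## Numerical choices and degenerate inputs

* Grids: 0.1&deg; default for UMS and TMST (configurable); minima analysis
  refuses profiles coarser than 0.5&deg;.
* Flat residual profiles (all values equal) are a degeneracy error.
* Fewer than three couplings triggers an under-determination warning but
  still fits (populations are then a continuum; the solver returns one
  optimum of the enumeration deterministically).
* The simplex enumeration accepts an interior KKT solution only when the
  normal system is nonsingular; a singular system means the optimum is
  flat toward the boundary and a smaller support captures it.
* PDB reading: first model only, altloc by highest occupancy with label
  order as tie-break, fixed-column parsing (no general PDB reader exists
  in the dependency set); the &gamma;-atom registry is configurable
  because swapping the &beta; branch shifts &chi;&#8321; by
  &plusmn;120&deg;.

## Known limitations

* No dynamic (time-dependent) rotamer models, no backbone &phi;/&psi;
  inference, and &chi;&#8322; enters only as coefficient metadata.
* Coefficient provenance (method/basis/backbone labels) is carried but
  never interpreted; backbone-conformer mixing is the caller's problem.
* The two-minima treatment assumes the grid resolves both minima; a
  sub-0.2 Hz saddle between near-degenerate minima merges them into one
  plateau minimum at coarse resolution.
* The robust X-ray average never resurrects an excluded angle; in
  principle an excluded value could fall back within the threshold of the
  final mean, which we accept in exchange for guaranteed termination.
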