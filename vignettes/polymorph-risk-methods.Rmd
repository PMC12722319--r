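---
title: "Methods: crystal-energy landscapes, pattern matching and polymorph risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crystal-energy landscapes, pattern matching and polymorph risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyrisk)
```

# The problem

Crystal structure prediction (CSP) ranks hypothetical packings of a drug
molecule by free energy. The risk question it answers is blunt: *is there a
plausible crystal form more stable than the one being developed, and would
its appearance break the product?* `polyrisk` turns a predicted landscape —
structures plus (possibly incomplete) energy tables — into that answer: a
ranked free-energy-vs-density landscape, identification of which predicted
structure matches an experimental powder pattern, disorder corrections, and
quantitative risk statistics.

This vignette documents the models, their assumptions, the tunable
parameters, and the numerical choices. It states no empirical result beyond
what the package's tests and acceptance script themselves compute.

# Crystal structures and density

Structures are fractional-coordinate site lists with a unit cell and
symmetry operators. The CIF reader covers the core 1.1 subset produced by
common deposition pipelines: cell tags, either operator-loop dialect
(`_symmetry_equiv_pos_as_xyz` or `_space_group_symop_operation_xyz`, quoted
or not, with standard uncertainties stripped), and the atom-site loop with
optional occupancy (default 1) and disorder-group tags. When only a
space-group symbol is present, operators are resolved from a built-in table
covering the chiral groups this pipeline generates in: P1, P2~1~, C2,
P2~1~2~1~2~1~. Anything else must supply its operator loop.

Symmetry expansion wraps coordinates into [0, 1) and merges orbit duplicates
within 0.01 fractional units (minimum-image metric). The tolerance absorbs
rounding in published coordinates; sites on special positions collapse to
their true orbit size.

Density is ρ = Z·M/(N~A~·V), with V from the triclinic volume formula and
N~A~ = 6.02214076×10²³ mol⁻¹. The molar mass comes preferentially from a
declared molecular formula (IUPAC 2021 standard weights) rather than the
site list, because deposited models can omit hydrogens; the site-list sum is
the fallback. Density is computed from whatever cell the input carries — the
package does not distinguish 0 K optimized from thermally expanded cells.

# Powder pattern simulation

Kinematic simulation: all hkl inside the observable d-spacing sphere
(the per-axis bound |h~i~| ≤ |a~i~|/d~min~ is exact), d-spacings via the
reciprocal metric tensor, 2θ = 2·arcsin(λ/2d), and

$$|F(hkl)|^2 = \Big|\sum_j o_j f_j(s)\, e^{-B s^2} e^{2\pi i\, hkl\cdot x_j}\Big|^2,
\qquad s = 1/(2d),$$

with 4-term Cromer–Mann form factors for H, C, N, O, S and a constant-Z
fallback for other elements. Reflections coincident in 2θ within 10⁻⁴° are
merged, accumulating multiplicity — a 2θ-coincidence merge rather than a
group-theoretic orbit construction, which is correct for intensity synthesis
and much simpler; accidental overlaps merely sum, as they do physically in
the 1-D pattern. Peak intensity is multiplicity × LP × |F|² with
LP = (1 + cos²2θ)/(sin²θ·cosθ), convolved with a unit-area pseudo-Voigt and
normalized to a maximum of 100.

Defaults emulate a laboratory pharmaceutical measurement: Cu Kα₁
λ = 1.5406 Å, 3–40° 2θ, 0.02° step, 0.1° fwhm, η = 0.5. There is no
preferred orientation, no Kα₂ doublet and no Debye–Waller damping by default
(optional global B): the matching stage correlates many peak positions, so
positional information dominates and these intensity refinements would not
change rankings. Profile tails are truncated at ±4°; the truncation is far
below the similarity scores' sensitivity. Screw-axis systematic absences
(0k0 with k odd for P2~1~; all odd axials for P2~1~2~1~2~1~) emerge from the
structure-factor sum itself and are verified to < 10⁻⁹ of the maximum
intensity in the tests.

# Pattern similarity and candidate ranking

Two patterns are compared with the weighted cross-correlation score

$$S(p,q) = \frac{\sum_m w_m\, c_{pq}(m)}{\sqrt{\sum_m w_m\, c_{pp}(m)\; \sum_m w_m\, c_{qq}(m)}},
\qquad w_m = \max(0,\, 1 - m\,\Delta/l),$$

implemented as shifted dot products on the common uniform grid with the
triangular weight sampled at integer-step offsets — O(n·l/Δ) and exactly
reproducible. S is symmetric, scale-invariant, 1 for identical shapes, and
in [0, 1] for non-negative inputs. The half-width defaults to l = 1.5° 2θ,
the conventional choice, which tolerates the small peak displacements caused
by cell-parameter error between predicted and measured structures; for the
same reason the zero-point shift is *not* refined during scoring — the
weight absorbs it and the score stays a pure function of the two curves.
With l at the grid step the score reduces to the cosine similarity of the
intensity vectors (a tested property). For two isolated narrow peaks offset
by Δ the score tends to 1 − Δ/l; at finite peak width the autocorrelation
denominator is reduced by smearing over the weight's kink at r = 0, so e.g.
fwhm 0.1° peaks at 0.5° offset score 0.689 rather than 2/3 — the tests pin
both regimes, the delta limit with 0.02° peaks and the finite-width value
against direct numeric integration.

Preprocessing resamples linearly onto the common grid, removes a polynomial
baseline, clips negatives and normalizes to unit area. The baseline is an
*iterative clipped* least-squares polynomial (refit after clipping the
signal to the previous fit, to convergence): a plain least-squares fit of
degree 0 would subtract the pattern mean and distort a background-free
pattern, whereas the clipped iteration converges to the low envelope.
Because each iteration commutes with the addition of any polynomial of the
fitted degree, a pattern contaminated by such a background preprocesses
*identically* to the clean one — the property the matching stage needs.
Background degree defaults to 2 (amorphous hump); the exact preprocessing an
external digitized pattern received is unknowable, so all of it is exposed
as parameters.

Ranking simulates every candidate, scores it against the experimental
pattern preprocessed identically, and sorts descending with lexicographic id
tie-breaks; a candidate whose simulation fails is kept with score `NA` at
the bottom rather than aborting the ranking.

# The energy landscape

Inputs are per-structure lattice energies E~latt~ (kJ/mol per molecule) and,
for a subset, an explicit vibrational free-energy term F~vib~ at the
reporting temperature (default 300 K). Computing F~vib~ is the expensive
step upstream, so the assembly supports the standard approximation: entries
without it receive a *uniform shift* equal to the unweighted mean F~vib~ of
the explicit subset (at least 2 required). The cost of the approximation is
made visible in the error bars: explicit entries carry σ = σ~base~, shifted
entries carry σ = √(σ~base~² + sd(F~vib~)²) with the sample (n−1) standard
deviation of the explicit terms — shifted entries are never *more* certain.

Relative free energies are referenced to the global minimum; ranks ascend in
free energy with ties broken toward higher density (denser packings are the
more dangerous hypothesis) and then id, for deterministic output. Everything
is translation-invariant in E~latt~. Structures the generation stage cannot
reach (e.g. high-Z′ forms) enter as externally supplied entries.

σ~base~ defaults to 1.9 kJ/mol. The error model's published description
gives the tail probabilities it implies rather than the σ itself; 1.9 is the
value consistent with a 2.0% inversion tail at a 3.89 kJ/mol gap
(σ = 3.89/Φ⁻¹(0.98) = 1.894), and `calibrate_sigma_pair()` performs exactly
that calibration so users can derive σ from any stated tail.

# Disorder

Occupational disorder stabilizes a polymorph configurationally. The
isolated-site model treats each disordered fragment as an independent site
with configurations i of free energy g~i~ and degeneracy d~i~:

$$p_i = \frac{d_i e^{-g_i/RT}}{\sum_j d_j e^{-g_j/RT}}, \qquad
\Delta F_\mathrm{stab} = \min_i g_i - \Big(-RT \ln \sum_i d_i e^{-g_i/RT}\Big) \ge 0,$$

computed with a max-shift for stability and reported as a positive
magnitude (the API's sign convention: corrections *lower* entry free
energies). Independence makes the joint partition function factorize, so
per-site stabilizations add — verified against brute-force enumeration of
all joint configurations in the tests. Two useful closed forms anchor the
scale: two degenerate configurations give RT·ln 2 = 1.729 kJ/mol at 300 K,
and a two-state site's occupancies invert to its gap via
Δg = −RT·ln(p₂/p₁), e.g. a 58/42 split at 298 K ⇔ 0.80 kJ/mol.

Configuration energies are *inputs* (upstream they come from electronic
structure theory); the synthetic module supplies them for testing. Closely
interacting disordered groups violate the independence assumption and are
deliberately unsupported — no additive answer would be honest there.

# Risk statistics

With Gaussian errors on relative free energies, the probability that a
challenger lies below a reference form is the one-sided tail
P = Φ(−ΔF/σ~pair~). σ~pair~ is applied directly to the pairwise difference
with no √2 inflation, taking the larger of the two entries' σ: the model
error is dominated by systematic method error common to the comparison, not
by independent per-structure noise, and this is the only reading under which
a single σ reproduces both of the calibrated tails above (2.0% at 3.89 and
~0.2% at 5.51 kJ/mol).

Solubility: S~ref~/S~new~ = e^(ΔF/RT) (ideal-solution thermodynamics; the
same Δμ drives both solubilities regardless of solvent). A 1.62 kJ/mol gap
at 300 K is a 1.91-fold — "about two-fold" — loss. The inverse RT·ln(ratio)
converts measured solubility ratios to free-energy gaps.

Severity: *severe* if the inversion probability reaches `p_threshold`
**and** the implied solubility loss exceeds `tolerance_fold`; *moderate* if
exactly one holds; *low* otherwise. Defaults p_threshold = 0.05 and
tolerance_fold = 1.05 encode a solution formulation holding the drug near
saturation, where even a minor solubility decrease precipitates the dose;
both are exposed because tolerance is a property of the formulation, not of
the landscape. Probabilities print to 2 significant figures in the text
report; JSON keeps full precision.

# Synthetic data: what it emulates, and what it does not

All fixtures are pure functions of (seed, parameters); one root seed fans
out to per-fixture substreams through a counter so adding a fixture never
perturbs existing ones.

- `make_toy_structure`: 1–20 random atoms (C/N/O/S) on general positions in
  a random cell (edges 4–30 Å, angles 80–120°, constrained to the space
  group's crystal system: P1, P2~1~ or P2~1~2~1~2~1~).
- `make_candidate_landscape`: true relative free energies with
  exponential-spacing gaps (scale default 2 kJ/mol — qualitatively the
  dense-above-minimum shape of CSP landscapes without claiming any exact
  distribution; explicit `gaps` can pin a known configuration). Each
  candidate's true F~vib~ ~ N(−2, sd 0.5) kJ/mol; the observed lattice
  energy is F − F~vib~ + N(0, noise_sigma), so each observed total free
  energy carries exactly `noise_sigma` of error — which makes the
  rank-inversion frequency of a pinned gap analytically checkable against
  Φ(−gap/(σ√2)) — and with both spreads at zero the true ranking is
  recovered exactly.
- `make_noisy_pattern`: simulation ∘ zero-point shift (default 0.02°) ∘
  polynomial background (default quadratic, positive over 3–40°) ∘
  multiplicative Gaussian noise (default 5%), clipped at zero — a stand-in
  for a digitized experimental pattern.
- `make_disorder_ensemble`: 2–3 configurations per site, gaps uniform in
  [0, gap_scale].

What passing tests on these fixtures show: the pipeline's mathematics —
geometry, structure factors, scoring, Boltzmann statistics, error
propagation — and its end-to-end identification power under stated noise.
What they do not show: behavior on real pharmaceutical crystals. Toy
structures are sparse (unphysically low densities), have no molecular
connectivity, hydrogens, preferred orientation or realistic thermal motion,
and their patterns are far more distinctive than those of 50-atom
conformational polymorphs whose cells nearly coincide. The 100-trial
self-identification rate is a property of these conditions, not a clinical
sensitivity claim.

# Numerical choices and degenerate inputs

- R = 8.31446×10⁻³ kJ/(mol·K); energies per molecule in kJ/mol throughout.
- Reflections with λ/2d > 1 are dropped (unobservable), not an error; a
  structure with no reflection in range yields a flat zero pattern with a
  warning, and an all-zero pattern makes similarity *undefined* (error)
  rather than 0.
- Occupancies must lie in (0, 1]; sites sharing a disorder group must have
  occupancies summing to 1 ± 0.01.
- The baseline iteration stops at 50 iterations or a 10⁻¹⁰ relative change;
  polynomial bases are centered and scaled before solving.
- Two-configuration occupancy inversion rejects probabilities of exactly
  0 or 1 (infinite gap).
- Landscape assembly requires ≥ 1 entry, finite lattice energies,
  σ~base~ ≥ 0, and ≥ 2 explicit F~vib~ values whenever any entry needs the
  shift.

# Problem sizes used in the shipped analyses

The analysis scripts and acceptance checks use 15–20 candidate landscapes,
toy asymmetric units of 4–8 atoms, 100 matching trials of 20 candidates
each, 2000-seed rank-inversion ensembles and 10⁵-draw Monte-Carlo
probability checks — sizes at which every stochastic assertion has
comfortable binomial margins while the full suite stays fast on one CPU.

# Known limitations

- No Rietveld/Pawley refinement, no indexing, no instrument geometry beyond
  the LP factor; matching is pattern-shape identification only.
- The built-in space-group table covers only the four groups the synthetic
  generators use; other groups need explicit operator loops.
- No Z′ > 1 structure generation; such forms must be supplied externally.
- The disorder model excludes interacting disordered groups by design.
- No kinetics: a thermodynamic threat says nothing about when (or whether)
  nucleation of the more stable form will occur. The risk statistics bound
  the hazard, not its timing.
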