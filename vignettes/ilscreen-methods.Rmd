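---
title: "Screening ionic liquids by sigma-profile thermodynamics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening ionic liquids by sigma-profile thermodynamics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ilscreen)
```

## The model

`ilscreen` implements the conductor-like screening model (COSMO-RS) chain
from screening-charge surfaces to a capacity-ranked ionic-liquid screen.
Three assumptions underlie the statistical thermodynamics: the liquid is
incompressible, all parts of the molecular surfaces may contact each other,
and only pairwise contacts of surface patches contribute. Under these, a
compound is fully described by its sigma profile `p(σ)` — surface area per
screening-charge-density bin — and a solvent mixture by the mole-fraction
sum of its components' profiles. An ionic liquid is treated as the
two-component ensemble of its bare ions; no ion pairing, viscosity, or
mass-transfer physics is modeled.

Contacting patches pay a quadratic electrostatic misfit
`(α'/2)(σ+σ')²` and may gain a hydrogen-bond energy
`c_hb · max(0, σ_acc − σ_hb) · min(0, σ_don + σ_hb)` once one patch
exceeds the acceptor threshold `+σ_hb` while the other lies below
`−σ_hb`. Both energies are per unit contact area; the effective contact
area `a_eff` multiplies them exactly once, inside the exponent of the
self-consistent sigma-potential equation (the alternative reading, with
`a_eff` inside the quadratic, is dimensionally inconsistent with the
`RT/a_eff` prefactor and is not used). The sigma potential `μ_S(σ)` is
solved on the grid; the solute's pseudo-chemical potential is the
profile-weighted sum `Σ_σ p_X(σ) μ_S(σ)`, and

$$\ln\gamma^\infty = \frac{\mu_X^{\mathrm{solvent}} - \mu_X^{\mathrm{pure}\,X}}{RT},
\qquad C^\infty = 1/\gamma^\infty .$$

Infinite dilution is realized structurally: the solvent ensemble contains
no solute, so no small-mole-fraction limit needs numerical care. Two exact
identities follow and are enforced by tests: any compound in itself has
`γ∞ = 1`, and `C∞ · γ∞ = 1` on every emitted row.

## Parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| `alpha_prime` | 8419 | kcal Å⁴ mol⁻¹ e⁻² | misfit prefactor |
| `a_eff` | 7.5 | Å² | effective contact area |
| `c_hb` | 85580 | kcal Å⁴ mol⁻¹ e⁻² | hydrogen-bond strength |
| `sigma_hb` | 0.0084 | e/Å² | hydrogen-bond threshold |
| `T` | 298.15 | K | screening temperature |
| `R` | 1.987e-3 | kcal mol⁻¹ K⁻¹ | gas constant |

These are open-literature constants of the COSMO-RS/COSMO-SAC lineage, not
a fitted parameterization; absolute γ∞ values therefore carry no
quantitative meaning and the package's purpose is the *ordering* of
solvents. The functional form of the hydrogen-bond term is the standard
threshold form; commercial implementations differ in both form and
constants. A Staverman–Guggenheim combinatorial contribution (coordination
number 10, conventional volume/area normalizations 66.69 Å³ and 79.53 Å²)
is available but off by default: the reciprocal capacity identity used in
published screening tables is purely residual arithmetic, and the
combinatorial term requires cavity volumes that COSMO files do not always
carry.

The sigma grid defaults to 51 bins on [−0.025, +0.025] e/Å² (width 0.001),
the conventional discretization. The polarity cutoff separating
hydrogen-bond donor (σ < −0.01), non-polar (|σ| ≤ 0.01) and acceptor
(σ > +0.01) surface is 0.01 e/Å²; the package works throughout in e/Å²
(a published variant of this boundary printed in e/nm² is treated as a
unit typo, the ±0.01 e/Å² value being the standard one).

## Numerical choices

**Solver.** The discretized sigma-potential equation is solved from
`μ ≡ 0` by damped successive substitution (damping 0.4) for a 20-iteration
burn-in, then Newton steps on `G(μ) = μ − F(μ)`. The Jacobian `I + W`
(with `W` the softmax weight matrix of the map, available for free) is
nearly singular along one direction — the misfit kernel admits an
approximate gauge `μ(σ) → μ(σ) + cσ` — so the Newton system is solved by
truncated SVD (singular values below 1e-8 of the largest are dropped); a
backtracking line search (step fractions 1, 0.5, 0.25, 0.1) falls back to
a damped substitution step whenever the Newton candidate does not reduce
the max-norm residual. Convergence is declared when the undamped residual
`max|μ − F(μ)|` falls below 1e-8 (default), typically after 30–160
iterations; plain damped substitution alone converges to the same fixed
point but needs thousands of iterations for profiles with strong
hydrogen-bond structure. Because the solute's profile has zero net
screening charge in the neutral-solute screening use case, its γ∞ is
invariant under the gauge direction. Map evaluations use log-sum-exp, so
the large exponents produced by ionic hydrogen-bond contacts cannot
overflow. The solution is deterministic for fixed inputs; solver failure
raises an error carrying the iteration count and last residual, and the
screen records such combinations as failed rows rather than aborting.

**Binning.** A segment's area is split linearly between the two bin
centers bracketing its charge density, which conserves both total area and
the first moment (net screening charge) exactly; densities outside the
grid are clipped with a counted warning. Region decomposition treats each
bin's mass as uniform over its support and splits boundary bins
fractionally at the cutoff, making region areas stable under grid
refinement (tested: doubling resolution moves each region by < 1 Å² per
100 Å² for smooth profiles).

**Charge averaging.** When segment positions are available, raw densities
are smoothed with the standard radial kernel
`w_j ∝ (r_j² r_av²/(r_j²+r_av²)) · exp(−d²/(r_j²+r_av²))` (`r_av` = 0.5 Å).
The kernel does not conserve the area-weighted net charge exactly, so a
uniform density shift restores it afterwards; without positions the
averaging step is skipped with a notice.

**Ion pairing.** `build_il_solvent` offers two conventions: `"equimolar"`
(1:1, the default; a monocation with a divalent sulfate-like anion then
carries net charge −1 e, which is recorded, not forced away) and
`"electroneutral"` (smallest integer stoichiometry with zero net charge,
2:1 for divalent anions). Both are exposed because the literature is not
explicit about how net-charged 1:1 ensembles are handled internally by
commercial screens.

## The synthetic-data generator

`generate_profile` realizes a Gaussian-mixture profile on the grid,
applies a small (2%) seeded log-normal shape jitter, and projects the
result to satisfy exactly `Σp = total area` and `Σσp = −formal charge`
(screening charge mirrors the molecular charge). The projection is least
squares *weighted by the unprojected profile* with an active-set
non-negativity loop: the correction is then proportional to local mass, so
near-empty tail bins stay near-empty. This matters because the
hydrogen-bond term amplifies spurious tail mass exponentially — an
unweighted projection adds a linear-in-σ ramp across all bins whose
presence or absence below the donor threshold changes capacities by tens
of log units. An infeasible charge constraint (required mean σ outside the
grid's reachable support) raises an error rather than silently distorting
the shape.

`generate_surface` draws equal-area segments by low-variance systematic
inverse-CDF sampling of the realized profile (so the re-binned surface
converges to the profile as segments grow; tested at 2% L1 with 10⁵
segments), places them on a sphere of matching area, and shifts densities
uniformly to hit the exact net charge.

The fixture catalogue emulates the screening cast of an EPA/ionic-liquid
study. Choices, made once on physical grounds:

* **EPA-like solute**: 457 Å², neutral; 91% of area in a non-polar peak at
  σ = 0 (sd 0.0033), a 4% hydrogen-bond-donor shoulder at −0.015 (the
  carboxylic OH; hydroxyl donors in real sigma profiles sit near −0.015 to
  −0.02 e/Å²) and a 5% acceptor shoulder at +0.014 (the carbonyl/ether
  oxygens). This reproduces the strongly non-polar profile with minor
  donor/acceptor shoulders expected for a long-chain fatty acid.
* **Anions**: single peaks centered at `+|q|/area` (the exact first-moment
  requirement), with compact high-charge-density profiles for halide- and
  sulfate-like ions (79–122 Å², widths 0.0016–0.002) and broad low-density
  profiles for large fluorinated anions (Tf2N-like: 228 Å², width 0.003).
  Sulfate carries formal charge −2.
* **Cations**: realistic cavity areas (imidazolium-like 236–362 Å²,
  growing ~42 Å² per two methylenes; tetramethylammonium smallest at
  165 Å²) with a narrow polar "ring" peak near −0.007 — deliberately
  *inside* the hydrogen-bond threshold, so cations do not act as spurious
  donors — and a non-polar alkyl peak near −0.001. The first-moment
  constraint then makes the ring area shrink and the non-polar area grow
  with chain length, which is what drives the chain-length capacity trend.

What the generator does *not* emulate: multi-modal fine structure of real
sigma profiles, conformational averaging, dispersion differences between
isomers, and any quantitative match to published profiles. Passing trend
tests on these fixtures therefore shows that the *model* orders solvents
by charge-density complementarity as expected, not that specific real ILs
would rank identically.

## Design decisions on open points

* **Chain-length trend and pairing mode.** With the equimolar convention,
  the monocation/sulfate ensemble carries an unpaired −1 e of acceptor
  surface that saturates the solute-donor channel; the capacity of the
  imidazolium series is then nearly flat in chain length. Under the
  electroneutral 2:1 convention the ensemble is charge-balanced and
  capacity falls strictly and strongly with chain length, as expected from
  charge-density dilution. The chain-trend checks therefore use
  electroneutral pairing; the anion-compactness ordering (sulfate >
  chloride > bromide ≫ Tf2N-like) holds under both conventions and is
  tested under the default equimolar one.
* **Problem sizes.** Tests and the acceptance script use the 51-bin grid,
  toy 5–8-bin grids for oracle equivalence against an independent
  root-finder, ≤ 10⁵-segment synthetic surfaces, and the full 352-IL
  synthetic screen (a few seconds end to end). Milder interaction
  constants (`α' = 1000`, `c_hb = 5000`) are used in the root-finder
  oracle tests because generic solvers without log-sum-exp safeguards
  overflow at the default constants.
* **File formats.** The COSMO reader targets the TURBOMOLE-style
  `$segment_information` layout with configurable column positions and
  ignores unknown trailing columns; only area and charge density are
  required, positions are optional. Gaussian/ORCA dialects are out of
  scope (the column mapping is the extension point). Densities declared in
  e/nm² are converted on read.

## Known limitations

Absolute γ∞ and C∞ values are not comparable to commercial COSMO-RS
outputs (different parameterization, no dispersion term, bare-ion
ensembles); only orderings are. Temperature enters only through `RT` — the
interaction constants are temperature-independent. Selectivity and
performance-index metrics, finite-concentration activity coefficients and
phase-equilibrium calculations are out of scope. The hydrogen-bond form is
a stated stand-in for unpublished functional choices, and screens with
net-charged equimolar ensembles should be interpreted with the caveat
discussed above.
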