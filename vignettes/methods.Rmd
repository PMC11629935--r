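---
title: "Modelling diffusion-mediated beam damage in STEM scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling diffusion-mediated beam damage in STEM scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemdiff)
```

## The physical picture and its assumptions

Radiolysis-type beam damage in scanning transmission electron microscopy
(STEM) is delocalised: secondary electrons, radicals, ions or heat released
under the probe spread through the specimen and can damage regions that the
scan has not yet reached, or has long left. `stemdiff` abstracts all of these
mechanisms into a single *diffusion distribution* $\phi$ — the density, in
arbitrary species units u per nm², of a damage-mediating species that obeys
Fick's second law. The model deliberately makes no claim about what the
species is; it provides a common currency in which scans can be compared.

The assumptions, and what they buy:

* **Infinite, homogeneous, thin 2-D medium.** The specimen is much larger
  than the probe and effectively two-dimensional, so no boundary conditions
  are needed and the per-axis diffusion coefficients $D_l$ (nm²/s) are
  constants. Concentration-dependent or spatially varying diffusion is out
  of scope.
* **Gaussian probe.** An aberration-free focused probe (an Airy disc) is
  approximated by an isotropic Gaussian of variance $D_s$ (nm²); a probe of
  0.1 nm radius corresponds to $D_s = 0.01$ nm². Circular-disc and
  square-disc sources are provided for wide-beam geometries.
* **Unit-mass source profiles.** Every spatial profile integrates to one,
  so changing the probe size never changes the number of species deposited:
  the total after a dwell $\tau$ is always $Q_0\,\min(t - t_0, \tau)$. This
  mirrors the optics of real instruments, where defocusing does not change
  the beam current, and it pins down the normalisation of every closed form
  (the conservation tests enforce it numerically for all four source
  shapes).
* **Instantaneous, error-free probe motion.** Scan-coil dynamics, flyback
  and hysteresis are ignored; position jitter is out of scope.

For a single Gaussian probe the distribution has a closed
exponential-integral form (log-branches at the activation point), and its
maximum — the *maximum beam diffusion distribution* (M-BDD),
$Q_0/(4\pi D)\,\log(1 + 2\tau D/D_s)$ — is attained at the activation point
at the end of the dwell. Summing shifted copies over the scan gives the
cumulative diffusion distribution (CDD); its running point-wise maximum
(PM-CDD) and the spatial maximum of that (GM-CDD) are the damage-relevant
statistics: a scan produces zero diffusion-induced damage (DID) for a
threshold $\lambda$ precisely when GM-CDD $\le \lambda$.

## Parameters that matter

| Parameter | Units | Default | Meaning |
|---|---|---|---|
| `D` | nm²/s | 10 | medium diffusion coefficient (sample-dependent) |
| `Ds` | nm² | 0.01 | Gaussian probe variance (0.1 nm probe radius) |
| `Q0` | u/s | 63.45×10⁶ | species release rate (proportional to beam current) |
| `dwell` (τ) | s | 10×10⁻⁶ | probe residence time per position |
| `settle` (τ̄) | s | 0 | blanked dead time between positions |
| `step` (Δp) | nm | 0.05 | scan step |
| `nx`, `ny` | — | 20 | probe grid |
| `subpixels` | — | 10 | field-map pixels per scan step |
| `NT` | — | 1 | temporal samples per probe slot |
| `margin` | steps | 5 | field padding around the probe array |

The defaults are the baseline acquisition studied throughout the package: a
4 ms, 400-probe raster whose M-BDD is ≈10⁴ u/nm² while its GM-CDD reaches
≈2.5×10⁵ u/nm² — a 25-fold accumulation penalty that single-probe reasoning
misses entirely. The PM-CDD grows when diffusion slows (smaller `D`), the
probe widens (larger `Ds`), probes crowd together (smaller `step`), or
dwells lengthen; blanking (`settle > 0`) lets the field relax between
probes at constant deposited dose.

## Numerical design

**Exact lattice factorisation.** Probe positions and field-map pixels share
one integer sub-pixel lattice, and all activations start on a regular slot
grid of width τ + τ̄. At the dwell-end instants the contribution of a probe
lagging the evaluation slot by $\ell$ depends only on the integer squared
pixel offset $s = dx^2 + dy^2$:
$E_1(s c / d_1(\ell)) - E_1(s c / d_0(\ell))$ with
$d_0(\ell) = 2D_s + 4D\ell(\tau+\bar\tau)$, $d_1(\ell) = d_0(\ell) + 4D\tau$
and $c$ the squared pixel size. One 1-D table per lag therefore reproduces
the accumulation *exactly* — no kernel truncation — and reduces the full
baseline PM-CDD (400 probes × 291² pixels × 400 time points) to table
lookups, about a minute and a half on one CPU. A per-lag cutoff radius, below
which tabulated increments fall under `epsRel` (default 10⁻⁹) of the
single-probe peak, skips negligible stamps; a test verifies cutoff and
no-cutoff passes agree on a 10×10 sub-problem. The same engine drives the
damage integral and the greedy mask designer. Arbitrary (off-lattice,
`NT > 1`) configurations use a direct per-time evaluation path, and a test
pins the two paths against each other to 10⁻¹².

**E1 evaluation.** The exponential integral is computed in compiled code by
the standard power series for arguments ≤ 1 and a modified-Lentz continued
fraction above, to near machine precision (cross-checked against an
independent implementation in the tests).

**Quadrature.** Disc and square sources use adaptive quadrature with a
relative target of 10⁻⁸; the circular-disc inner integral evaluates the
Bessel kernel $I_0$ in exponentially scaled form to avoid overflow, and
both sources use envelope-scaled absolute floors so the far field (where
the integrals underflow) cannot stall the adaptive subdivision. The square
source's per-axis error-function differences are written as upper-tail
normal probabilities to avoid catastrophic cancellation far from the
source. The verification oracle — direct quadrature of the space–time
superposition integral — uses nested 1-D adaptive rules throughout because
2-D cubature error estimates proved unreliable at the 10⁻⁶ level the
equivalence tests demand; for the Gaussian source the spatial integral is
taken in kernel-scaled coordinates so that it stays smooth as the kernel
degenerates to a delta near the upper time limit.

**Singular branches.** $E_1(0) = \infty$, so the value *at* a probe node
uses the logarithmic branch. Dispatch is by exact coordinate equality —
probe positions are grid nodes generated by the same expression as pixel
coordinates — never by epsilon comparison.

**Time discretisation.** With `NT = 1` the CDD is examined at dwell-end
instants only, where each probe's own contribution peaks; the reported
PM-CDD is thus a tight lower bound on the continuous-time maximum, and
`NT > 1` refines it (a test checks refinement never lowers it). The DID
integral uses the rectangle rule over probe slots with the CDD at each
slot's dwell end and slot width τ + τ̄ (final slot τ); a 2×2 toy scan
against a 50-fold finer time grid agrees to 2%.

## Scan plans, masks and hardware timing

Trajectories (raster, snake, seeded random, alternating of order κ, custom
orders) are permutations of the grid nodes; the alternating scan visits the
κ×κ interleaved sublattices in row-major offset order, reducing to raster
at κ = 1. Subsampling masks select M of the N probes: uniform density
sampling (UDS) draws them uniformly without replacement; linehop builds L
lanes that each take one pixel per column and move by at most one row
between columns (collisions are resampled, then shifted deterministically —
the collision rule is this package's own dialect, as the original scheme
leaves it open).

Two hardware models realise a mask. A *beam blanker* keeps the full raster
clock: every slot elapses, unselected slots deposit nothing, acquisition
takes Nτ. A *scan generator* visits only selected positions back-to-back in
Mτ. Blanker timing therefore interleaves relaxation time between selected
probes and yields lower accumulated fields at equal dose. Linehop is the
exception: its lanes form a connected, physically scannable path with
nothing to blank, so both hardware models are scheduled identically
(column-major lane order, packed slots) and produce identical CDD fields —
by construction here, matching the behaviour expected of the pattern.

The greedy diffusion-controlled sampling (DCS) designer walks the base
trajectory and accepts a candidate only if the would-be CDD at its dwell
end stays strictly below λ everywhere on the full simulation grid (not just
at probe nodes — the guarantee quantifies over all positions). Accepted
probes update the running point-wise maximum; rejected slots still elapse
under blanker timing and vanish under generator timing. The result is
damage-free by the GM-CDD criterion for *any* non-negative activation, at
the NT = 1 time discretisation. The greedy rule is order-dependent and not
unique; a minimum-distance side constraint is available as an optional
post-filter (the greedy safety check is re-run on the filtered candidate
set). Thresholds at or below the M-BDD provably admit no probes at all.

## What the synthetic campaigns do and do not show

The package's campaigns (`runBaseline`, `runSweep`, `runCompressive`,
`dcsEfficiencyCurve`) are simulations of the model itself — there is no
external data. Agreement of the test suite therefore demonstrates internal
correctness (closed forms vs brute-force superposition quadrature,
conservation, engine-vs-engine equality, the threshold theorems) and
reproduction of the model's published behaviour (the 25× accumulation
ratio, the ~5× GM-CDD reduction at 10% UDS sampling, monotonicities in D,
τ, τ̄, trajectory ordering), not the fidelity of the diffusion abstraction
to any particular specimen. Real samples add everything the assumptions
exclude: finite thickness and boundaries, concentration- and
state-dependent transport, healing and secondary damage mechanisms, scan
coil dynamics, and a physical calibration of u and of the threshold λ —
all of which remain outside the model.

Problem sizes were chosen so each piece of evidence is computed at the
scale where it is meaningful: printed reference values at the full 20×20
baseline with 10 sub-pixels per step, structural and theorem properties on
2×2–10×10 scans at 4 sub-pixels per step, where they are scale-invariant.
The field margin of 5 scan steps keeps boundary maxima unclipped; maxima of
the baseline live well inside the probe array, so results are insensitive
to it.

## Known limitations

* The PM-CDD/GM-CDD are maxima over a discrete time set; pathological
  configurations with `NT = 1` could peak between dwell ends (refine with
  `NT`).
* The online pupil can be zero for all time at pixels never approached by a
  later probe; there the zero-damage ⇔ threshold equivalence is only
  sufficient, and `isDidFree()` warns.
* DID units differ by activation: seconds for `sign` (exceedance duration),
  u·s/nm² for `relu` (integrated exceedance); they are reported in the map
  metadata, not normalised away.
* Greedy DCS answers "max probes under a threshold", not "min damage at
  fixed M"; globally optimal mask design is out of scope.
* 3-D diffusion, pulsed/TEM geometries and image reconstruction from
  subsampled scans are out of scope.
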