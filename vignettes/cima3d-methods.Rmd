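---
title: "Models and methods behind cima3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cima3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cima3d)
```

`cima3d` analyses impedance-based 3D cell invasion/migration assays: cells
seeded on interdigitated electrodes (IDEs) under a collagen matrix migrate
upward along a serum gradient, and the chamber's complex impedance spectrum,
swept over 10–100 kHz, reports their departure label-free. This vignette
documents the models, the estimation machinery, the identifiability
properties of the circuit, the synthetic-data generators, and the design
decisions taken where more than one defensible choice existed.

## The equivalent circuit

The chamber impedance is modelled as four series blocks:

$$Z(\omega, \mathbf p) = \frac{R_{ct} Z_{CPA}}{R_{ct} + Z_{CPA}} + R_{ccm}
+ \frac{R_{ECM}}{j\omega C_{ECM} R_{ECM} + 1}
+ \frac{R_{seal} R_{cell}}{j\omega C_{cell} R_{seal} R_{cell} + R_{seal} + R_{cell}}$$

with the constant-phase element $Z_{CPA} = 1/(Q (j\omega)^n)$, $0 \le n \le 1$,
capturing the distributed electrode–electrolyte interface ($n = 1$ is an ideal
capacitor, $n = 0$ a resistor; the phase is frequency-independent at
$-n \cdot 90^\circ$). The parameter vector is
$\mathbf p = [R_{ccm}, R_{ECM}, C_{ECM}, R_{seal}, R_{cell}, C_{cell}, R_{ct}, Q, n]$.
Frequencies enter the public interface in Hz (the instrument's convention);
$\omega = 2\pi f$ is used internally.

Estimation minimises the least-squares cost
$e(\mathbf p) = \sum_i |Z_i - Z(\omega_i, \mathbf p)|^2$, implemented as
stacked real/imaginary residuals (identical by Pythagoras) under
Levenberg–Marquardt with box constraints. The eight positive parameters are
searched in $\log_{10}$ space — they span decades and must never go negative —
while $n$ stays linear in $[0,1]$. Residuals are unweighted by default, since
the instrument noise model is not known; `weighting = "inv-magnitude"` scales
residuals by $1/|Z_i|$, which is the efficient choice when noise is
proportional to $|Z|$ (as in the package's own simulations). The reported
`cost` is always the unweighted value, and never exceeds the cost at the
supplied start. Convergence uses relative tolerances of $10^{-15}$ (cost) and
$10^{-13}$ (step) with up to 1000 iterations, one restart from the incumbent
(resetting the trust region, which reliably walks out of the shallow valleys
this very anisotropic surface produces), and an optional 8-point multistart
over $(n, Q)$ when no initial guess is supplied. Non-convergence is flagged,
never silently accepted.

### Identifiability: what a spectrum can and cannot determine

The cell block algebraically equals
$1/(j\omega C_{cell} + 1/R_{seal} + 1/R_{cell})$: a spectrum determines only
the **parallel conductance** $G = 1/R_{seal} + 1/R_{cell}$, never the split
between seal and cell resistance, at any frequency. This is a structural
degeneracy of the model, not a numerical artefact — the fitter reaches
numerically zero cost anywhere on the one-dimensional manifold of splits.
`fit_circuit()` therefore:

* computes per-parameter uncertainty proxies through an SVD pseudo-inverse of
  the normal matrix, marking parameters that carry a null direction as
  infinitely uncertain and warning when both seal and cell resistances exceed
  100% relative uncertainty;
* offers `fix_seal_cell_ratio` (and a general `fix =` pin) to resolve the
  split by convention when absolute values are required.

`track_parameters()` resolves the split across a time series by freezing
`R_seal` at its first-fit value (`hold = "R_seal"`, the default), attributing
all conductance drift to `R_cell`; `hold = "ratio"` pins the ratio instead.
The trajectory object also reports the linear trend of $G(t)$ itself, which
is identifiable under any convention. A consequence worth stating plainly:
when both resistances drift simultaneously, their individual slopes are not
recoverable from spectra alone — only the conductance trend is.

Two further facts shape what recovery tests can demand. First, the matrix
block and the cell block are both single-pole $R \| C$ forms, so their labels
can swap at identical cost; fits started near the truth stay in the correct
basin, which is why the recovery tests perturb a known start rather than
using the blind heuristic. Second, the circuit is *sloppy* in the usual
sense: at the simulation defaults (50 points, 10–100 kHz) the Cramér–Rao
bound at 1% relative noise is 40–170% per parameter even with efficient
weighting and the ratio pinned. Noiseless spectra are recovered to machine
precision; at 0.1% noise the median estimates are within a few percent; at 1%
noise only well-conditioned quantities (the parallel conductance, $R_{ccm}$,
$n$) remain reliable. The tests assert exactly these three regimes.

## The cell invasion/migration index

$$\Psi = \max_\omega \frac{|Z_t(\omega) - Z_0(\omega)|}{|Z_0(\omega)|}$$

is the maximal relative change of the spectrum between time $t$ and baseline.
Two decisions are folded in. The index is the *maximum* of the relative
change, not the maximising frequency: every downstream use treats $\Psi$ as a
dimensionless fraction (steady-state values of 0.1–0.64), which only the
maximum provides. And the numerator is the modulus of the complex difference;
`cimi_mode = "magnitude-diff"` exposes the alternative $||Z_t| - |Z_0||/|Z_0|$
for sensitivity analyses. $\Psi \ge 0$ always, $\Psi = 0$ at baseline by
construction, and $\Psi$ is invariant to any common complex scale factor on
both spectra — the property that makes it comparable across chambers with
different cell densities and adhesion.

## Saturating-exponential kinetics and dose–response

All kinetic relationships in the assay share one two-parameter form,
$y = A(1 - e^{-x/s})$: invasion distance vs time ($H_0$, $\tau$), CIMI vs
time, CIMI vs distance, and — reparameterised with rate $k = 1/s$ — CIMI vs
drug concentration. `fit_saturating_exp()` exploits the conditional linearity
of $A$: the scale is found by profiling $A(s) = \sum y g / \sum g^2$
($g = 1 - e^{-x/s}$) over a 60-point log-spaced grid spanning
$[\mathrm{span}/10^3, \mathrm{span}\cdot 10^3]$, refining with 1-D
minimisation, then polishing $(A, s)$ jointly by Levenberg–Marquardt. The fit
is deterministic for identical input. A scale escaping to the top of its
search range flags non-saturating (concave-up) data via `converged = FALSE`;
a negative profiled amplitude is clamped to zero and flagged. $R^2$ is the
standard $1 - SS_{res}/SS_{tot}$ about the response mean. `fix_scale` fits
the amplitude alone when a common time constant (e.g. 100 min) is imposed
across treatment groups — the assay's kinetics literature is ambiguous about
whether the time constant was fitted per group or shared, so both paths are
first-class.

The plateau $A$ and initial rate $A/s$ (the analytic derivative at 0)
summarise each group. The dose–response model $\Psi(c) = A(1 - e^{-kc})$
yields the half-maximal effective concentration in closed form,
$EC_{50} = \ln 2 / k$; the tests cross-check this against root-finding on the
fitted curve at $A/2$ to $10^{-10}$. Responses are expected normalised to the
zero-dose control, and the design must include the control. No Hill or
four-parameter logistic alternative is offered: the assay's reported
pharmacology is the single-exponential saturation, and a richer model could
not be validated against it.

## Pore-size quantification by morphological opening

Fluorescence images of labelled collagen networks are segmented by a global
between-class-variance (Otsu) threshold, optionally after subtracting a wide
Gaussian background estimate (off by default — a perfectly flat image should
segment exactly, and the background option exists for uneven illumination).
Polarity is explicit via `invert`.

"Filling the pores with disks of diameter $d$" is morphological opening of
the pore phase: the opened set is exactly the union of all disk placements
that fit. The implementation uses exact Euclidean distance transforms — a
disk centred at $p$ fits iff no fibril pixel lies within $d/2$ of $p$
(erosion as $dt > d/2$), and the opening is every pixel within $d/2$ of a
fitting centre. Opening is anti-extensive by construction. One lattice
subtlety matters: with disk centres restricted to integer pixels, a *larger*
disk can occasionally cover boundary pixels a smaller one cannot reach
(the intermediate continuous centres do not exist on the grid), so raw
coverable fractions are not guaranteed monotone. Since every lattice opening
at diameter $d' \ge d$ lower-bounds the continuous coverable area at $d$, the
ladder reports the running maximum from the right — the tightest lattice
estimate, non-increasing by construction. The fraction at $d = 1$ is exactly
1 (a single-pixel disk fits everywhere in the pore phase).

The mean pore diameter is the 50% point of the ladder, by piecewise-linear
interpolation; an unbracketed ladder is an error advising a wider one. The
default ladder is all odd diameters 1–31 px for interpolation accuracy; the
coarse instrument ladder $\{1, 5, 10, 15\}$ px remains available for
fidelity runs. On phantoms with disjoint circular pores of known diameter
$D \in \{9, 15, 21\}$ px the estimate lands at $D + 1$ — the pixel-centre
convention widens effective diameters by about one pixel — comfortably within
the $\pm 2$ px acceptance band. Fibril content is the fibril-pixel fraction,
averaged over slices; 3D stacks are analysed slice-wise, matching the 2D
character of the underlying imaging.

## Confocal z-profiling

Stacks are indexed $(z, y, x)$ with $z = 0$ at the electrode plane and plane
heights at voxel centres. The per-plane intensity sums, normalised to unit
mass, form the invasion profile; the collective cell position is its
intensity-weighted centroid, and the invasion distance
$H(t)$ is the centroid rise over the $t = 0$ baseline (negative values, which
noise can produce at early times, clip to zero with a warning). A
single-Gaussian fit of the profile supplies plume centre and width. The
centroid was chosen over per-cell detection deliberately: at collective
migration densities it is robust, parameter-free, and the CIMI–distance
calibration is agnostic to the convention. Per-plane median background
subtraction is available but off by default — it would annihilate spatially
uniform stacks, and the generators produce background-free stacks; enable it
for real data with haze. Profiles are invariant to intensity scaling and
equivariant to z-translation; both are asserted as properties in the tests.

## Synthetic-data generators

The generators emulate the statistical structure the analyses assume — no
cell–matrix mechanics, no MMP kinetics, no chemoattractant diffusion:

* **Spectra** come from the forward circuit with `R_cell` and `R_seal`
  drifting linearly (the observed signature of cell departure), plus complex
  Gaussian noise scaled by $|Z|$. Defaults: 50 log-spaced frequencies over
  10–100 kHz, times 0–180 min every 30 min, baseline parameters of realistic
  magnitude ($R_{ccm} = 500\,\Omega$, $R_{ECM} = 2\,k\Omega$,
  $C_{ECM} = 3\,nF$, $R_{seal} = 3\,k\Omega$, $R_{cell} = 5\,k\Omega$,
  $C_{cell} = 1\,nF$, $R_{ct} = 50\,k\Omega$, $Q = 10^{-8}$, $n = 0.8$); no
  measured parameter table exists to copy, so these are stated as plausible
  placeholders whose block corner frequencies all fall inside the sweep band,
  and no claim is made of matching a physical chip.
* **Networks** are random full-width chords of calibrated thickness drawn
  until the fibril area density target (default 12%) is met; a small closed
  loop adjusts thickness until the package's own 50%-rule pore diameter of
  the noiseless mask hits the target (default 15 px) within 10%, erroring if
  the density/pore combination proves infeasible. The noisy image adds
  Poisson shot noise and Gaussian read noise (fibril level 200, background
  10, read SD 5 — SNR ≈ 10). Real collagen networks have curved, branching,
  finite-length fibrils and depth-dependent blur; passing tests on these
  phantoms validates the morphology pipeline's geometry, not its behaviour
  on every real-world illumination artefact.
* **Invasion stacks** place `n_cells` (default 200) point sources with
  heights from a truncated Gaussian centred at $base + H(t)$,
  $H(t) = H_0(1 - e^{-t/\tau})$ (defaults $H_0 = 100$ µm, $\tau = 100$ min,
  SD 10 µm, base 20 µm), rendered with 2 µm axial blur into a
  $31 \times 32 \times 32$ stack at 5 µm z-pitch. The default 31 planes
  mirror the acquisition geometry; the lateral extent is kept small because
  the z-profile marginalises it out.
* **CIMI tables** add i.i.d. Gaussian noise to the saturating-exponential
  mean; the response at covariate 0 is pinned to exactly 0, as the measured
  index is at baseline by construction (elsewhere noise may take simulated
  values slightly negative, which the fitters accept).

Every generator takes an explicit seed, is bit-reproducible, and restores the
caller's RNG state. Default noise magnitudes (CIMI SD 0.02, distance SD 3 µm)
are chosen so fitted $R^2$ on simulated traces lands in the high-0.9s, the
regime the assay reports.

## Problem sizes and numerical conventions

The test suite and the acceptance script use 100 Monte-Carlo replicates for
kinetic/dose recovery (medians reported), 20–50 replicates for image and
stack round trips, 40 replicates for noisy circuit recovery, and 10-minute
CIMI sampling over 0–180 min (the impedance sampling cadence) versus 30-min
sampling for confocal-derived distances — each chosen as a realistic assay
size that keeps the full suite under ten seconds. CSV dialects are fixed
(comma, `.` decimal, UTF-8, mandatory header); JSON outputs carry a schema
version; run configuration is YAML with unknown keys rejected by name; TIFF
I/O is 16-bit grayscale, exact for integer intensities up to 65535.

## Known limitations

* The seal/cell split (and hence separate seal/cell drift slopes) is not
  identifiable from spectra; all reported splits are conventions, clearly
  labelled as such.
* Circuit parameter estimates at realistic (≥1%) noise are reliable only for
  well-conditioned combinations; uncertainty proxies quantify this per fit.
* The pore ladder assumes roughly isotropic pores; strongly anisotropic
  channels are summarised by their width.
* The centroid-based invasion distance underestimates leading-front advances
  of strongly skewed plumes.
* Generators emulate observable statistics, not biophysics; agreement on
  synthetic data bounds, but does not prove, performance on real chips.
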