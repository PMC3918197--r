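---
title: "TG-43U1 dose calculation for Cs-137 pellet trains"
author: "pelletdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TG-43U1 dose calculation for Cs-137 pellet trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelletdose)
```

## The dose model

Low-dose-rate Selectron afterloaders treat gynaecological cancers with
trains of 2.5 mm spherical Cs-137 pellets pushed into a cylindrical
applicator; each slot of the train holds either an active source or an
inactive steel spacer. `pelletdose` computes the dose-rate distribution
around an arbitrary active/inactive configuration by superposing
single-pellet dose rates evaluated with the AAPM TG-43U1 formalism in its
point-source form:

$$\dot D(r,\theta) \;=\; S_K \,\Lambda\,
  \frac{G_P(r)}{G_P(r_0)}\, g(r)\, F(r,\theta),
  \qquad G_P(r) = \frac{1}{r^2},$$

with the conventional reference geometry $r_0 = 1$ cm, $\theta_0 =
90^\circ$. Here $S_K$ is the air-kerma strength (U), $\Lambda$ the
dose-rate constant (cGy h^-1^ U^-1^), $g(r)$ the radial dose function and
$F(r,\theta)$ the 2D anisotropy function. The train dose at a point $Q$ is

$$\dot D(Q) = \sum_{i \,\in\, \text{active}} \dot D_i(r_i, \theta_i),$$

where $r_i$ is the distance from pellet $i$ to $Q$ and $\theta_i$ the
angle between the applicator axis and the line from pellet $i$ to $Q$.

The key physical point is *where the applicator physics lives*. A bare
pellet is nearly isotropic; inside the applicator, the steel wall, the
polyethylene carrier and the neighbouring pellets attenuate and scatter
photons differently in different directions. Those effects are folded
into position-dependent $g$ and $F$ tables derived with the full geometry
present (one single active pellet, everything else in place). The
superposition then inherits the shielding without any explicit transport
at dose-calculation time, which is why inactive spacers contribute no
term of their own.

The packaged parameter set (`cs137_pellet_model()`) covers a pellet in
the first (tip-most) slot: $g(r)$ at 1--10 cm and $F(r,\theta)$ at
$r \in \{3,5,7\}$ cm, $\theta \in \{15^\circ,\dots,165^\circ\}$. The
anisotropy is a 5--10 % suppression toward both poles and is *not*
symmetric about $90^\circ$ — the train extends to one side of the first
pellet only. $\Lambda$ and $S_K$ ship as placeholder values of 1 because
absolute calibration is site-specific; every comparison the package makes
is a ratio, and users doing absolute work edit the two header fields of
the parameter file.

## Conventions and tunable parameters

* **Lengths** in cm, **angles** in degrees, **dose rate** in cGy/h,
  $S_K$ in U (1 U = 1 µGy m² h⁻¹).
* **Pellet geometry**: 0.75 mm active core plus 0.5 mm shell gives a
  1.25 mm outer radius; touching pellets give the default pitch of
  0.25 cm (`pellet_pitch_cm`, configurable).
* **Slot order and angle origin**: slot 1 is nearest the applicator tip;
  slot index grows toward the base along `axis`. $\theta = 0$ points from
  a pellet *toward the tip* by default (`theta_zero = "tip"`). Published
  pellet tables rarely state this convention; since the sub-unity
  small-angle anisotropy values represent attenuation along the train,
  the tip-ward choice is the physically natural reading, and the option
  exists to flip it.
* **Applicator tip**: profiles "beyond the tip" start at the distal
  surface of the tip-most pellet, i.e. the first slot center minus one
  pellet radius (0.125 cm). A real applicator adds a wall and a small
  air gap distally; anyone comparing against measured data at millimetre
  accuracy should shift the origin accordingly.
* **Grid spacing** defaults to 0.125 cm, the resolution at which fine
  scoring lattices for pellet dosimetry are commonly run; comparisons
  (`percent_difference()`) require congruent grids and never interpolate.

## Interpolation and extrapolation policy

Tables are coarse, so the interpolators are deliberately simple and
reproducible: linear in $r$ for $g$, bilinear in $(r,\theta)$ for $F$.
Both reproduce every tabulated node exactly and are continuous across
nodes. Outside the tabulated range values are clamped to the nearest
edge and a warning is emitted — polynomial extrapolation beyond a table
that stops at $r = 7$ cm or $\theta = 15^\circ$ can go badly wrong near
the axis, and clamping errs on the side of smoothness. Points closer to
the poles than the first tabulated angle therefore take the
$15^\circ$/$165^\circ$ values; on-axis profiles through a long train are
dominated by exactly these clamped values, which callers see flagged via
the warning.

File validation uses a looser tolerance (1e-6 relative) for the
normalization checks $g(r_0)=1$ and $F(r,90^\circ)=1$ than the in-memory
table invariants (1e-9), because printed tables carry 3--4 digits; on
load, residual rounding is rescaled away so the strict invariants hold
exactly afterwards.

## Parameter extraction from sampled dose maps

`extract_parameters()` inverts the dose equation on a polar map of a
single source, the way dosimetry parameters are derived from Monte Carlo
dose distributions:

* $\Lambda = \dot D(r_0, \theta_0)/S_K$,
* $g(r) = \dot D(r,\theta_0)\, r^2 / \dot D(r_0,\theta_0) r_0^2$,
* $F(r,\theta) = \dot D(r,\theta)/\dot D(r,\theta_0)$ (geometry cancels
  within a radius).

A scoring lattice need not contain $(1\,\text{cm}, 90^\circ)$ exactly, so
the reference snaps to the nearest sample within `tol_r` = 0.05 cm and
`tol_theta` = 1°; the returned tables are normalized at the snapped node
and satisfy the container invariants by construction.

With noiseless input the inversion is exact to rounding. With the
relative (multiplicative) noise typical of tally outputs, the raw
per-radius ratio $\hat g(r)$ carries roughly $\sqrt 2$ times the
per-sample noise, and the chance that *every* node of a table stays
within a small band shrinks with table size. The standard remedy in the
dosimetry literature — tabulating a low-order polynomial fit of the
transverse profile instead of raw ratios — is available as
`smooth_g_order`: the inverse-square-corrected transverse data
$\dot D(r,\theta_0)\,r^2 \propto g(r)$ is fit with a polynomial of the
given order and the fitted curve is tabulated (renormalized at $r_0$).
The default remains the exact node-by-node inversion so that clean maps
round-trip bit-faithfully; smoothing is opt-in and should use an order
well below the number of sampled radii (order 3 against ~100 radii in
the package's own noisy-recovery checks).

`air_kerma_strength()` multiplies in-air kerma-rate samples by the
squared distance and averages with equal weights over a fit range. For an
ideal point source the product is constant, so any range works; the
default 5--100 cm avoids the near field, where the finite pellet breaks
the inverse-square law, and the far field, where sampling statistics
degrade. The per-sample products are returned so distance-independence
can be inspected rather than assumed.

## The legacy comparator

Older planning systems for Cs-137 treat each pellet as an isotropic point
source in water: exposure from the exposure-rate constant and the inverse
square law, a roentgen-to-dose f-factor, and a polynomial tissue
attenuation/scatter correction $T(r)$, superposed over active pellets
with no applicator or inter-pellet shielding. `legacy_parameters()`
defaults to literature constants for Cs-137 — $\Gamma = 3.28$ R cm²
mCi⁻¹ h⁻¹, $f = 0.962$ cGy/R, and the Meisberger third-order polynomial
(valid 0.5--10 cm, clamped with a warning outside). These reproduce the
*class* of algorithm, not any specific commercial implementation, whose
internal constants are proprietary.

For engine-vs-engine comparisons the two formalisms must first be made
physically commensurate: `calibrate_legacy()` scales the per-pellet
activity so a single isolated pellet matches the TG-43U1 model at
$(1\,\text{cm}, 90^\circ)$. After calibration, the residual differences
isolate exactly what the legacy formalism ignores: anisotropy and
shielding. The signature effect is at the applicator tip, where every
pellet is seen end-on ($\theta \approx 0$) and the anisotropy suppression
of each term compounds: with the packaged single-slot tables and a
10-active-pellet train the calibrated legacy engine overestimates the
on-axis dose 1 cm beyond the tip by about 10 %, the discrepancy decaying
monotonically to roughly ±1 % on the transverse plane
(`scripts/acceptance.R` recomputes these numbers). The magnitude grows
when each slot uses its own parameter set — deeper slots see more
intervening material — so the single-slot value is a lower bound on what
a full per-position library would show; the package supports such a
library (`source_library()`) but ships only the first slot's data.

## The synthetic generator

`synthetic_source_spec()` + `render_dose_map()` produce analytic dose
maps with known TG-43U1 structure: a quadratic radial shape
$g(r) = 1 + c_1 (r-1) + c_2 (r-1)^2$ (defaults $c_1 = -0.012$,
$c_2 = -4\times10^{-4}$, a gentle percent-per-cm fall-off), an
anisotropy dip $F(\theta) = 1 - a_0 |\cos\theta|^p$ (defaults
$a_0 = 0.1$, $p = 2$, a ~10 % polar suppression), and optional
multiplicative log-normal noise with a given coefficient of variation
(mean-corrected to 1, seeded, rendered without disturbing the caller's
RNG stream). Multiplicative noise is the right family because tally
uncertainty is relative.

What this emulates is the *statistical* character of scored dose maps;
what it deliberately does not emulate is the physics that makes real
pellet tables interesting — the radius-dependence of $F$, asymmetry about
$90^\circ$, applicator-material spectra. Passing recovery tests therefore
demonstrate that the extraction machinery is correct and noise-robust,
not that any particular physical table is right; the physical content
enters only through measured or simulated parameter files.

## Numerical choices and degenerate inputs

* Table containers reject non-monotone grids, non-positive values and
  broken normalization at construction; file loading names the offending
  row.
* Points inside an active pellet (within 0.125 cm of its center) are
  masked: an error for scalar queries, `NA` for grid/matrix queries, so
  dose grids render with holes rather than infinities. Points inside
  inactive spacers are not masked — no source sits there.
* Isodose extraction is marching squares with linear edge interpolation
  on the planar grid; levels outside the field's range return empty
  polyline lists. Contour vertices of an analytic inverse-square field
  deviate from the true circle by less than one grid spacing at the
  default resolution.
* Percent-difference maps are normalized to the first (reference) grid
  and masked where the reference is masked or zero.
* The Sk estimator is an unweighted mean; with strongly heteroscedastic
  samples a user can restrict the fit range instead.

## Problem sizes used in the package's own checks

The test-suite and the acceptance script exercise: trains up to 48
slots against an independently coded brute-force superposition (100
random configurations); noisy parameter recovery on a 96-radius × 11-angle
map at 1 % noise; dose grids at 0.125 cm spacing over ~40 × 40 cells for
contour geometry; and quarter-arc sweeps at 2.5 and 4 cm for the
tip-versus-transverse comparison. These sizes were chosen to make every
check sharp at interactive runtimes and are stated here so they can be
scaled up verbatim for more stringent offline validation.

## Known limitations

* Only the first slot's parameter tables ship with the package; all other
  slots fall back to them through the library default. Tip-region
  discrepancies versus isotropic engines are consequently understated.
* Point-source geometry function only; no line-source $G_L$ variant.
* Straight cylindrical applicators only — no tandem/ovoid curvature.
* No gamma-index analysis, DVHs, or DICOM-RT interfaces; grids and
  contours are exchanged as delimited text.
* The legacy engine is a faithful representative of its class, not a
  byte-level emulation of any commercial system.

## A worked comparison

```{r example, fig.width = 6, fig.height = 6, eval = FALSE}
m   <- cs137_pellet_model()
cfg <- train_configuration(rep(TRUE, 10))      # 10 active pellets
lp  <- calibrate_legacy(legacy_parameters(), m)

gt <- compute_grid(tg43_train_engine(cfg, m),  c(-3, 3), c(0, 0), c(-3, 6))
gl <- compute_grid(legacy_train_engine(cfg, lp), c(-3, 3), c(0, 0), c(-3, 6))

plot_isodose(gt, levels = c(2, 1, 0.5, 0.25), grid2 = gl,
             main = "TG-43U1 (solid) vs legacy point-source (dashed)")

pd <- percent_difference(gt, gl)
summary(pd$values[!pd$mask])
```
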