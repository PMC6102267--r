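---
title: "Measuring membrane-protein interactions by hydrodynamic trapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring membrane-protein interactions by hydrodynamic trapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement

A micropipette held a few micrometres above a supported lipid bilayer (SLB)
draws liquid inward. Molecules protruding from the bilayer feel a drag force
and accumulate under the pipette until, at steady state, the gradient of
their chemical potential balances the hydrodynamic force:

$$\frac{\partial \mu}{\partial r} = F_{\rm hydro},
\qquad F_{\rm hydro} = A_{\rm hydro}\,\sigma_{\rm hydro},$$

where $\sigma_{\rm hydro}(r)$ is the wall shear stress of the flow and
$A_{\rm hydro}$ the effective hydrodynamic area of one molecule. Integrating
along the surface gives

$$\mu(c) = \mu(c_0) + \int_0^{\epsilon_{\rm hydro}} A_{\rm hydro}(c)\,
d\epsilon, \qquad
\epsilon_{\rm hydro}(r) = \int_r^{\infty} \sigma_{\rm hydro}\, dr',$$

so a single steady-state image, radially averaged and converted to molecular
density, yields $\mu$ as a function of concentration over orders of
magnitude in $c$. The package implements this inference chain
(`find_trap_centre()`, `radial_average()`, `intensity_to_concentration()`,
`build_interaction_curve()`, `slope_a_hydro0()`, `mu_from_curve()`) together
with the two reference models the measured curves are compared against: the
two-dimensional hard-disk fluid and Monte Carlo simulations of grafted,
tilting, glycosylated bead-chain molecules.

## Units and conventions

* Energies are in units of $k_BT$ throughout; the absolute scale
  $k_BT = 4.11\times10^{-21}\,$J (25 °C) enters only when converting the
  trap energy density (J/m²) against molecular areas (nm²).
* Lengths: nm for molecules, µm for image coordinates; concentrations in
  molecules/µm²; coverage $\Phi = c\,\pi a^2$ is dimensionless.
* $\sigma_{\rm hydro}$ is stored as the magnitude of the inward stress, so
  $\epsilon_{\rm hydro} \ge 0$ and decreases outward; the minus sign of the
  defining integral is absorbed into this convention.

# The hard-disk reference (module `thermo`)

The excess chemical potential of hard disks at coverage $\Phi$ is the
truncated virial series
$$\mu^{ex}(\Phi) = k_BT\left(2B_2\Phi + \tfrac32 B_3\Phi^2 +
\tfrac43 B_4\Phi^3\right), \quad B_2 = 2,\; B_3 = 3.128,\; B_4 = 4.258,$$
deliberately truncated at $B_4$: that truncation *is* the reference model,
and no higher-order terms are added. Its low-coverage deviation from the
$B_2$-only form is $1.173\Phi + 1.419\Phi^2$ (6.2% at $\Phi = 0.05$), which
is why the interaction-curve slope is fitted below $\Phi \le 0.05$ by
default.

One subtlety matters when fitting measured curves: a trap-inferred
$\mu^{ex}$ is *zero at the baseline density* $c_0$ by construction, whereas
the virial series is absolute. `fit_hard_disk_radius(conc0 =)` therefore
references the model to the baseline coverage; omitting this biases the
fitted radius noticeably at baseline coverages of a percent or more.

The glycan area map
$$A_{\rm hd} = \frac{p_1 x^2 + p_2 x + 1}{p_1 x^2 / q + 1},
\qquad x = A_{\rm proj} - 1,$$
with $p_1 = 0.66$, $p_2 = 0.95$, relates the normalized projected area of a
glycosylated molecule to its effective hard-disk area. The plateau
$q = 9.82$ is geometric — the normalized projected area of a disk of radius
protein-radius + sugar-length, $((0.15+0.32)/0.15)^2$ — and is held fixed
during fitting (`fit_glyco_coefficients()`): it is a property of the
molecular geometry, not a free coefficient. On the physical domain
$1 \le A_{\rm proj} \le q$ the map is monotone and bounded by the plateau;
outside it the rational form overshoots slightly before levelling off, so
the package documents and tests the map on the physical domain only.

# The hydrodynamic-area model (module `hydro`)

For an isolated surface-anchored cylinder of radius $a$ and height $h_c$,
$$A_{\rm hydro}(0) = \left(0.65\,(h_c/a)^2 + 5.0\,(h_c/a) + 1\right)\pi a^2.$$
`effective_height()` inverts this in closed form (positive quadratic root in
$h_c/a$), and the pair round-trips to $10^{-10}$ relative. At finite
coverage molecules shield each other from the flow;
`a_hydro_of_coverage()` applies an attenuation $g(\Phi)$ with the
guaranteed contract $g(0)=1$, $g$ non-increasing, $0 < g \le 1$. The default
family is $(1-\Phi)^{\nu}$ with $\nu = 1$ ($\nu = 0$ disables shielding);
the precise functional form of shielding in the source experiments is not
published, so only the contract — not a particular curve — is relied on.

Real experiments obtain $\sigma_{\rm hydro}(r)$ from finite-element
simulations of the pipette flow. Those are out of scope here; the package
accepts tabulated stress profiles (`shear_profile()`, the escape hatch for
users with FEM output) and otherwise provides a documented parametric
kernel,
$$\sigma(r) = S\,\frac{r}{r_0}e^{-r/r_0}, \qquad
\epsilon(r) = S r_0 \left(1 + \frac{r}{r_0}\right)e^{-r/r_0},$$
with $r_0 = \text{tip radius} + \text{gap}$ and amplitude linear in the
applied pressure. The stagnation point at $r=0$, the monotone outward decay
and the pressure linearity are the physically load-bearing features; the
default shape coefficient (3.44×10⁻³) is set so that the intermediate study
pressure (−9.7 kPa) with the default geometry gives a peak trap energy of
10⁻⁴ J/m², the scale at which the reference concentration profiles were
recorded. The kernel exists to generate physically shaped trap energies for
synthesis and testing, not to reproduce any particular FEM solution.
Radial integration of tabulated stress uses the trapezoid rule on the
supplied grid, with a truncation warning if the stress has not decayed to
10⁻³ of its peak at the outer edge.

# Monte Carlo of grafted bead chains (module `mc`)

Molecules are rigid chains of spheres grafted to a hard planar wall
(centres constrained to $z \ge 0$), moving by single-molecule translations
in the periodic $x$/$y$ plane and rotations about the graft point
(Metropolis, symmetric proposals on orientations so the free-rotation
stationary tilt measure is $\sin\theta$). Sphere pairs on different
molecules interact through the WCA potential — the purely repulsive
Lennard-Jones form cut and shifted at $2^{1/6}\sigma$.

**Energy scale and the 1.075² coverage correction.** Soft WCA disks behave
as hard disks with a slightly larger radius. The analysis convention is
that this enlargement is 7.5%, and all nominal coverages are multiplied by
$1.075^2$ (`corrected_coverage()`) before comparison with hard-disk theory.
The WCA depth $\epsilon_{LJ}$ is therefore not free: it was calibrated by
simulating squat grafted spheres, measuring their Widom $\mu^{ex}(\Phi)$,
and fitting the virial equation of state with a free radius factor. The
factor equals 1.075 at $\epsilon_{LJ} = 26\,k_BT$ (five seeds,
1.0754 ± 0.0018), which is the package default (`wca_default_eps()`). The
Barker–Henderson effective diameter, often used for this purpose,
underestimates the EOS-matching diameter by about 2% here, which is why the
calibration is empirical.

**Tilt restraint.** The topmost sphere may be restrained by
$u = k_f (z - L_{\max})^2$ with $k_f$ in $k_BT/\text{Å}^2$; $k_f = 0$ leaves
free ±90° rotation and `rigid = TRUE` pins the molecule upright. The
mapping from $k_f$ to a tilt range depends strongly on the molecule's
length: for the 0.25 nm three-sphere rod, $k_f = 5\,k_BT/\text{Å}^2$ admits
95% of tilts within ±41°, not ±10°. The package therefore never hard-codes
an angle↔$k_f$ table; `kf_for_tilt()` solves the single-molecule Boltzmann
distribution $p(\theta) \propto \sin\theta\,
e^{-k_f(L\cos\theta - L)^2}$ for the spring constant that puts a stated
probability mass inside a stated angle, and `tilt_quantile()` inverts it.
Simulated tilt histograms are exposed in every run so the realized
distribution can always be checked against the analytic one.

**Widom insertion.** $\mu^{ex} = -\ln\langle e^{-\Delta U}\rangle$ over
ghost insertions into recorded production states: positions uniform on the
wall, orientations drawn from the restrained single-molecule Boltzmann
distribution (wall-conditioned by redraw). This measure makes
$\mu^{ex} \to 0$ exactly as $\Phi \to 0$ — the insertion free energy is
measured relative to an isolated molecule with the same restraint, which is
the quantity the trap experiment reports. Standard errors come from block
averaging (10 blocks) over the sampled states; an estimate with any empty
block is flagged unreliable, and zero successful insertions yields a lower
bound rather than a number.

**Run hygiene.** Move amplitudes are auto-tuned to 30–50% acceptance during
equilibration (default 30% of the run) and then frozen. Initial
configurations come from random sequential insertion with an energy
threshold, falling back to a lattice; an infeasible coverage fails with the
achievable maximum. The default production length is $10^5$ steps with 500
Widom sampling points of 50 insertions each — sizes chosen so a full
three-curve flexibility comparison completes on one CPU in minutes while
keeping the 1 kBT crossing coverage reproducible to a few percent between
seeds; the run length is a config field (`mc_config()`) for users who want
the reference-scale $10^6$ steps. Runs are bit-reproducible for a given
seed (the engine carries its own xoshiro256** stream, independent of R's
RNG).

**Flexibility factors.** The effect of rotation is summarized at the
coverage where $\mu^{ex} = 1\,k_BT$ (`coverage_at_1kT()`, linear
interpolation; the bracketing requirement is enforced). Two summaries are
provided: `effective_width_ratio()` = $\sqrt{\Phi^*_{\rm rigid} /
\Phi^*_{\rm flex}}$, the literal width ratio, and
`hard_disk_area_ratio()` = $\Phi^*_{\rm ref}/\Phi^*$, the ratio of
equivalent hard-disk areas. The amplification factors quoted for rotating
3:1 rods (≈1.4 / 1.7 / 2.3 for stiff / soft / free springs) are
reproduced by the *area* ratio with the spring constants
$k_f = 5 / 1 / 0\;k_BT/\text{Å}^2$ — the free-rotation case matches to
better than 1% — and that is the convention `scripts/acceptance.R` and the
acceptance tests use. The width (square-root) convention gives factors of
1.24 / 1.35 / 1.51 for the same systems and is kept available because both
conventions appear in the literature.

**Glycosylation geometry.** The model glycoprotein is three 0.3 nm spheres
stacked on the wall; each sugar is two 0.16 nm spheres extending
horizontally from an attachment sphere (default: the middle one), so the
sugar tip reaches 0.47 nm from the axis and the geometric plateau is
$(0.47/0.15)^2 = 9.82$. Default azimuths are evenly spread (sugars at
distinct angles, so their projections add exactly); a same-plane
arrangement (`azimuths = c(0, 180)`) is available, since published figures
for such model systems assume all sugars in one plane. `projected_area()`
computes the exact union of the circular projections (1D interval union on
a fine grid — exact in $y$, discretized in $x$).

# Synthetic data (module `synthdata`)

`forward_steady_state()` generates the ground truth the pipeline is tested
against. Because $A_{\rm hydro}$ may depend on coverage, the steady state
is defined by the differential form of the force balance,
$dc/d\epsilon = A_{\rm hydro}(c) / \mu'(c)$, integrated from the baseline
with `deSolve::lsoda` (rtol = atol = 10⁻⁹ on a 400-point energy grid); for
constant area this coincides with per-radius root finding and with the
closed form $c = c_0 e^{A\epsilon/k_BT}$ for ideal molecules, both of which
are tested. Coverages crossing a physicality cap (default 0.5) warn with
the saturating radius.

`render_image()` applies the camera model: counts = background +
(counts per molecule) × (molecules per pixel), with Poisson counting noise
and Gaussian read noise (both optional). Defaults (80 counts/molecule,
400 background, read SD 3, 512×512 at 0.22 µm/px) give roughly 3% shot
noise per pixel at a 300 µm⁻² baseline, which radial averaging reduces
below 1% per bin — the noise level at which the round-trip tests require 5%
parameter recovery. The generator does **not** emulate photobleaching,
crystallization at high density, optical blur, detector nonlinearity, or
drift; passing round-trip tests therefore demonstrate the correctness of
the inference chain under the stated camera model, not robustness to those
real-world effects. Scenario presets (`make_scenario()`) carry the four
study geometries (SA 2.8×5 nm; CD2/CD4/CD45 at radius 1.5 nm and heights
7.5/11/15 nm) with their theoretical areas; the experimentally fitted disk
radii ride along as metadata only, since they derive from unreleased
experimental curves.

# Two co-trapped species (module `pipeline`)

`two_species_steady_state()` integrates the coupled balances
$d\mu_i = A_i\,d\epsilon$ with
$\mu_i = \ln(c_i/c_{0,i}) + \mu^{ex}_{\rm HD}(\Phi_i) +
\pi(a_i+a_j)^2 c_j$: each species keeps its full virial self-term (so the
single-species limit is exact when the other baseline vanishes) and the
mixture coupling is truncated at the second virial, the mutual-exclusion
area. Optionally the species with the smaller hydrodynamic area is shielded
by the other's local coverage (default $g(\Phi) = (1-\Phi)^2$; the stronger
exponent reflects that a short molecule standing in a forest of tall ones
loses drag faster than the self-shielding of equals). This module is
deliberately qualitative — the second-virial mixture and the shielding
exponent are modelling choices — and is tested on limits, symmetry, and the
ring-shaped displacement of the smaller species, not on quantitative
profiles.

# Design choices that were genuinely open

* **Loss function for radius fits**: relative residuals (floored at
  0.05 kBT) by default, because measured $\mu^{ex}$ spans an order of
  magnitude and absolute least squares would fit only the high-coverage
  end. Absolute residuals are a switch (`relative = FALSE`), and
  `fit_interaction_models()` uses them when ranking candidate shapes on a
  common footing.
* **Interpolation direction**: the trap energy is interpolated onto the
  concentration bins, not vice versa, because the concentration bins carry
  the photon statistics.
* **Non-monotone curves**: a concentration that decreases with trap energy
  beyond 2% triggers isotonic pre-smoothing (`stats::isoreg`) before the
  chemical-potential integral, with a warning; raw values are retained in
  the output.
* **Low-coverage cutoff** for the slope fit: $\Phi \le 0.05$ under a
  provisional radius, reported with the result.
* **Plateau fixed in the glycan fit**: whether the original fit floated it
  is unknown; fixing it is the defensible choice because it is a geometric
  quantity.
* **Degenerate inputs** are statuses, not numbers: all-zero curves, flat
  interaction curves, boundary-pinned radii, plateau-collinear glycan
  points and unbracketed 1 kBT crossings all return explicit flags or
  errors.

# Known limitations

* The parametric flow kernel is a stand-in with the right shape and
  scalings, not a flow solution; quantitative work with real pipettes needs
  tabulated FEM stress profiles.
* The virial reference is truncated at $B_4$ and is not meant above
  $\Phi \approx 0.5$; the MC engine, not the series, is the reference at
  high coverage.
* The MC molecules are rigid (no internal flexibility) and uncharged, and
  the Widom estimator loses efficiency above $\mu^{ex} \approx$ 5–6 kBT
  where insertion acceptance collapses.
* The two-species model is second-virial and qualitative by design.
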