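---
title: "Multiplexed optical diffraction tomography: models, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiplexed optical diffraction tomography: models, algorithms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(holotomo)
```

Optical diffraction tomography (ODT) recovers the three-dimensional
refractive index (RI) of a sample from coherent transmission images taken
at many illumination angles. Classical acquisitions need on the order of a
hundred sequential views, capping the volumetric rate far below what fast
colloidal and microbial dynamics demand. `holotomo` implements a
multiplexed variant: a binary micromirror array (DMD) conjugate to the
objective's back focal plane displays several spot patterns at once, so a
single camera exposure carries tens of plane-wave views, and a model-based
reconstruction unmixes them. This vignette describes the models, the
numerical choices, and the places where the design was genuinely open.

## Fourier-plane pattern design

The DMD sits in a plane conjugate to the objective back focal (Fourier)
plane. A circular "spot" of diameter $d$ mirrors at position $r_p$,
modulated by a binary carrier at spatial frequency $f_p$ (a thresholded
cosine), diffracts a beam whose sample-plane parameters are

$$\delta r = \frac{f_l \lambda}{M}\,(f_p - f_c), \qquad
  f = \frac{M}{f_l \lambda}\,(r_p - r_c),$$

where $f_l$ is the objective focal length, $M$ the DMD-to-pupil
magnification, $\lambda$ the vacuum wavelength, and $(f_c, r_c)$ the
carrier frequency and DMD position aligned with the optical axis. Spot
*position* therefore sets the illumination *angle* and spot *carrier
frequency* sets the beam's lateral *position* — the basis for the two
multiplexing modes:

* **angle multiplexing** — several spots at different positions with a
  common carrier superpose beams at different angles on one sample region;
* **position multiplexing** — replicating every spot at additional carrier
  frequencies displaces beam copies laterally, extending the illuminated
  field of view.

`spot_to_beam()` / `beam_to_spot()` implement the (exactly inverse)
mappings, `render_dmd_frame()` rasterizes binary frames, and
`compose_position_multiplex()` adds carriers. The placement of $M$ and
$f_l\lambda$ in the two relations is fixed by dimensional analysis
(frequencies in cycles/µm, positions in µm).

Angle sets come from a Fermat spiral scaled to the illumination pupil
(`design_angle_set()`): quasi-uniform over the disc, deterministic, with a
mean nearest-neighbour spacing within a few percent of the uniform-disc
value $R\sqrt{\pi/N}$. `partition_angles()` distributes $N$ angles over
$\lceil N/M \rceil$ frames of $M$ beams: greedy farthest-point seeding on
the DMD face, then five sweeps of 300 random pairwise swaps, keeping a swap
iff it increases the loss — the average within-frame pairwise DMD distance,
capped at a configurable maximum (default: the pupil radius on the DMD).
Well-separated within-frame beams are what make the demultiplexing
initializer (below) work. When $M$ does not divide $N$, angles are
duplicated (never within one frame) to fill the last slots. Ties in the
farthest-point seeding resolve to the lowest index; the swap RNG is seeded,
so partitions are reproducible. Overlapping spot discs are rejected by
default because they corrupt each spot's carrier purity; an OR-union mode
exists for deliberate overlaps.

The DMD is modelled as an ideal binary amplitude mask on a square grid;
mirror-tilt diffraction physics is out of scope.

## Forward models

All propagation is scalar. The elementary operation is the angular
spectrum: each plane-wave component at lateral frequency $f$ advances over
a distance $z$ by $\exp\!\big(2\pi i z \sqrt{(n_0/\lambda)^2 -
|f|^2}\big)$, with evanescent components decaying for either direction of
$z$.

**BPM.** The paraxial beam propagation method alternates exact homogeneous
half-steps with thin phase screens $\exp\!\big(i k_0 (n - n_0)\,\Delta z /
\cos\theta\big)$. The obliquity factor $1/\cos\theta$ (the inverse axial
direction cosine of the single illuminating beam) corrects the slant path
of a tilted beam; it is undefined when several beams at different angles
are superposed, so `bpm_propagate()` refuses multiplexed illumination in
obliquity mode. That restriction is exactly why the non-paraxial model
below is the default for multiplexed work.

**SSNP.** The split-step non-paraxial scheme evolves the pair $(E,
\partial_z E)$. Free space is exact per Fourier component via the $2\times
2$ propagator with entries $\cos(k_z \Delta z)$, $\sin(k_z \Delta z)/k_z$,
$-k_z \sin(k_z \Delta z)$; each slice then kicks the derivative, $\Delta
(\partial_z E) = -k_0^2 (n^2 - n_0^2)\,\Delta z\, E$. The incident field
enters under a forward-only assumption ($\hat{E}' = i k_z \hat{E}$) and the
exit state is projected onto the forward-travelling component
$\tfrac12(\hat E - i \hat E'/k_z)$. Because no single obliquity factor is
assumed, the SSNP handles arbitrary beam superpositions.

*Stability.* The kicked two-component recursion is parametrically unstable
(a Mathieu-type resonance) wherever the per-slice axial phase $2\pi f_z
\Delta z$ crosses a multiple of $\pi$; with strong index contrast the
growth is exponential in depth. The implementation therefore retains only
the band whose axial phase sits strictly inside one stability window, and
`ssnp_propagate()` warns when the slice thickness puts the *normal* ray
near a resonance (i.e. $\Delta z$ near a multiple of $\lambda/(2 n_0)$).
For $\lambda = 0.785$ µm in oil, $\Delta z = 0.4$ µm keeps the usable band
out to 1.45 cycles/µm, beyond any detection NA used here. Slices thinner
than $\lambda/(2 n_0) \approx 0.26$ µm are unconditionally stable.
Validation against the Mie oracle shows ~0.2% total-field RMS error for
micrometre spheres at moderate contrast and <1% for 4-µm-thick objects at
$\Delta z = 0.3$–0.4 µm.

Defaults: `voxel_z` is the user's choice with the resonance warning above;
`padding_factor = 1` (periodic) for reconstruction, with optional padded
boundaries and Tukey edge apodization for simulation; components beyond
0.98 of the medium frequency are always suppressed.

**Mie oracle.** `mie_coefficients()` / `mie_scattered_field()` solve
scattering of a scalar plane wave by a homogeneous sphere with continuity
of $\psi$ and $\partial_r \psi$ — the scalar counterpart of the classic
electromagnetic series, and the consistent independent oracle for scalar
forward models. The series is truncated at $\lceil x + 4x^{1/3} + 2\rceil$
($x = k a$). Internal consistency is enforced by the optical theorem (the
partial-wave scattering cross-section matches $4\pi\,\mathrm{Im}\,f(0)/k$
to 0.1%), and the low-frequency limit reproduces the scalar monopole
closed form $f(0) \to k^2 a^3 (m^2-1)/3$. Multi-sphere scenes superpose
single-scattering fields — intended for dilute validation phantoms only;
dense media go through the SSNP. The oracle covers real sphere indices
(all validation phantoms are lossless).

## Holography

Off-axis holograms $|E + A e^{2\pi i f_\mathrm{ref}\cdot r}|^2$ are
demodulated by an exact real-space modulation to baseband followed by a
raised-cosine disc (10% edge) of the chosen band radius
(`demodulate_hologram()`); the $E\,\bar R$ sideband at $-f_\mathrm{ref}$
is the one recovered, so the signal field itself (not its conjugate) is
returned relative to a unit reference. For time series without sample-free
regions, `estimate_reference()` uses the complex time average, assuming RI
inhomogeneities average out over the recording; the residual temporal
variance is attached as a diagnostic and a near-zero value flags a static
object contaminating the background.

Phase unwrapping (`unwrap_phase_weighted()`) is transform-based weighted
least squares: wrapped forward differences feed a Neumann Poisson problem
solved by DCT, with Picard iteration mixing the weighted wrapped gradients
and the unweighted gradients of the current solution (tolerance $10^{-6}$,
at most 50 iterations). Weights default to squared field amplitude. The
least-squares solution is finally snapped to the input, so the output is
congruent to the wrapped phase modulo $2\pi$ at every pixel.

## Linear reconstruction and Rytov demultiplexing

With the scattering potential $V = k_0^2 (n^2 - n_0^2)$ and fields
referenced to the mid-volume plane, the first-order (Born/Rytov) relation
maps each 2-D frequency $f$ of one view onto the Ewald-sphere cap

$$\hat V\big(f - f_\mathrm{inc},\, f_z(f) - f_z(f_\mathrm{inc})\big)
  = -4\pi i\, f_z(f)\, \widehat{E_0 \psi}(f),$$

where $\psi = \ln|E/E_0| + i\,\mathrm{unwrap}\,\arg(E/E_0)$ is the Rytov
field. `grid_ewald_cap()` deposits caps by nearest-voxel gridding with
multiplicity averaging; unfilled voxels (the missing cone) stay at
background. Two numerical details matter in practice. First, the incident
frequency is snapped to the detector frequency grid for the deposit, so
the lateral scattering vector lands exactly on grid frequencies — an
off-grid carrier would shift each view's whole cap by up to half a bin, a
per-view phase ramp that speckles the volume. Second, the known
unscattered carriers are subtracted before the Fourier plane is split and
restored analytically per beam afterwards: off-grid unit-amplitude
carriers leak across the whole DFT plane at a level comparable to weak
scattered signals. Nearest-voxel rounding of the *axial* coordinate is
irreducible without a non-uniform FFT; it scrambles phases increasingly
far from the volume centre, which is why quality metrics are evaluated on
the interior (the initializer only needs low fidelity).

For a multiplexed frame, `demultiplex_rytov_initialize()` splits the
field's Fourier plane into the regions nearest each beam's carrier,
additionally capped by a disc of half the minimum inter-carrier distance
so regions stay isotropic (a single-beam frame keeps the whole detection
band, making 1× demultiplexing *exactly* classical Rytov ODT — a test
asserts bit-level agreement). Each region becomes a low-resolution
single-beam view; caps are gridded, averaged, inverse transformed, and the
physical projections $\mathrm{Re}(n) \ge n_0$, $\mathrm{Im}(n) \ge 0$
applied. As multiplexing grows, the region radius — hence the initializer
resolution — shrinks monotonically; for objects whose spectrum is wide
compared to the region radius, inter-beam crosstalk degrades the guess,
which is the known failure mode of the approach.

## Iterative reconstruction

`fista_solve()` minimizes, over the complex RI volume,

$$\sum_\mathrm{frames} \Big[ w_\mathrm{ps} \sum |E_\mathrm{model} -
E_\mathrm{meas}|^2 + w_\mathrm{pi} \sum \big(|E_\mathrm{model}| -
|E_\mathrm{meas}|\big)^2 \Big] \;+\; w_\mathrm{TV}\,\mathrm{TV}(n) +
w_{\ell_1} \|n - n_0\|_1,$$

subject to the physical constraints. Defaults are $w_\mathrm{ps} = 1$,
$w_\mathrm{pi} = 0$; the phase-insensitive term is invariant to a global
measurement phase and is recommended when unwrapping is unreliable.
Gradients come from the exact adjoint of the discrete forward model (a
reverse slice sweep reusing the stored per-slice fields); finite-difference
tests pin the adjoint to $10^{-4}$ relative accuracy per voxel. An optional
Tukey `edge_taper` down-weights residuals near the detector edges, where
FFT-based synthetic (and cropped experimental) fields carry wrap-around
artifacts the model should not be forced to fit.

The solver is standard FISTA: gradient step at the momentum point, then a
proximal step — isotropic TV by Chambolle dual projection (applied to real
and imaginary parts separately), complex soft-thresholding of $n - n_0$,
and the constraint projections, whose composition approximates the joint
proximal operator — then momentum $t_{k+1} = (1 + \sqrt{1 + 4 t_k^2})/2$
with extrapolation. Adaptive restart plus a monotone safeguard
keep the recorded objective non-increasing. The step size is the inverse
of a power-iteration Lipschitz estimate (finite-difference Hessian-vector
products at the initializer; seeded), halved by backtracking whenever the
quadratic majorization is violated. Divergence beyond ten times the
initial objective aborts with diagnostics. Batch handling is full-batch
(gradients averaged over frames).

### A desk-scale finding on multiplexing at fixed image count

A synthetic study (weak and strong sphere phantoms, 3×–19× multiplexing,
noiseless and noisy data, and data generated by the reconstruction's own
forward model) consistently found the fixed-image-count comparison — $NM$
angles in $N$ multiplexed images versus $N$ single-beam images — to favour
the single-beam set by a factor of 1.1–1.4 in interior RMSE at these
problem sizes: the demultiplexing initializer's resolution loss outweighed
the angular-coverage gain. The regression test therefore asserts the
weaker property that holds robustly (multiplexed quality within 1.5× of
single-beam RMSE while tripling the angular coverage without extra
exposures). Conditions closer to hardware scale (hundreds of angles,
camera-noise-limited SNR) may well reverse the comparison; at desk scale
they are out of reach.

## Synthetic scenes

`simulate_brownian_scene()` integrates Euler–Maruyama steps with per-axis
variance $2 D(h)\,\Delta t$. Near a no-slip wall the parallel diffusion
coefficient follows the leading-order law $D_\parallel(h) = D_0 \big(1 -
\tfrac{9}{16} R/h\big)$; the same leading-order form is applied axially as
a documented simplification (the true axial hindrance is stronger). With
height-dependent $D_z$, the Itô-consistent spurious drift $\partial_h D_z\,
\Delta t$ is included so the stationary height distribution under gravity
is exactly Boltzmann, $\propto \exp(-mgh/k_BT)$ with $m = \tfrac43 \pi R^3
(\rho_\mathrm{bead} - \rho_\mathrm{solvent})$ — a Kolmogorov–Smirnov test
against the truncated law on decorrelated snapshots verifies this.
Boundaries reflect at sphere contact with the coverslip and chamber top.
Defaults mimic micron-scale polystyrene beads ($n = 1.57$) in water
($n_0 = 1.333$) in 4–120 µm chambers at kilohertz-scale frame intervals.
Note the Euler–Maruyama reflection scheme carries an $O(\sqrt{D\,\Delta
t})$ boundary-layer bias; height-distribution statistics should be
simulated with steps small compared to the gravitational length.

`simulate_swimmer_scene()` translates a rod along a smoothly wandering
velocity direction (angular diffusion on the sphere) while the body axis
precesses about the velocity at the prescribed wobble angle; the ground
truth angle is kept in the scene metadata. Rods rasterize as cylinders
with hemispherical caps.

`render_hologram_series()` ties the generators to the imaging model:
superpose the frame's beams, form the transmitted field (Mie superposition
for dilute sphere scenes, SSNP for rasterized rods), apply the detection
pupil, add the tilted reference, and record intensity with Poisson shot
noise at a stated photon budget plus Gaussian read noise, all seeded and
bit-reproducible.

## Localization, tracking, and statistics

`localize_particles()` mirrors standard bead-localization practice:
difference-of-Gaussian filtering (sigmas 0.5× and 1.5× the expected radius),
a maximum filter with candidates where the two agree above threshold, and
a 3-D Gaussian least-squares fit in a 2×2×4 µm ROI with width/centre
bounds. `link_trajectories()` is greedy mutual-nearest-neighbour linking
with a displacement bound and gap memory; on well-separated scenes it
provably coincides with the exhaustive optimal assignment, which the tests
check against a brute-force oracle.

`msd_diffusion()` computes ensemble/time-averaged MSDs at stride-multiple
lags (non-overlapping windows by default, to limit correlation between
samples) and fits $\mathrm{MSD} = 2 d D \tau$ plus an offset absorbing
static localization error. `stepsize_cdf()` gives per-axis step CDFs with
Gaussian ML fits and the Kolmogorov–Smirnov distance.
`hindered_diffusion_fit()` bins single-step lateral MSDs by height and
fits the wall law by weighted least squares — linear in $(D_0, D_0 R)$, so
noiseless model data are recovered exactly. (The wall law's formal root
lies at $h = 9R/16$, below sphere contact and outside the expansion's
validity; the implementation clips $D$ at zero.)
`boltzmann_height_fit()` estimates the gravitational length by
truncated-exponential maximum likelihood and converts it to an effective
mass. One calibration subtlety is worth stating: at desk scale (a handful
of beads over tens of frames) the sampling noise of the finite random walk
itself spans tens of percent in any MSD-based D estimate, so end-to-end
tests judge the imaging loop against the same estimator applied to the
scene's ground-truth trajectories — isolating measurement fidelity (a few
percent) from trajectory-sampling noise, which no measurement can remove. `wobble_analysis()` accepts rod scenes (ground-truth axes) or RI
volume series, segmenting the latter by index threshold plus connected
components with the first principal axis as the body axis — a deliberate
replacement of interactive classifier-based segmentation; tracks shorter
than 50 frames or moving less than 4 µm are excluded, centroids are
smoothed by a centred 15-frame rolling mean, velocities use second-order
differences, and the wobble angle is the mean velocity/axis angle with the
axis sign disambiguated per frame.

## What the synthetic tests do and do not show

The generators emulate: multiplexed coherent plane-wave illumination,
Mie-accurate single scattering, shot/read noise, wall-hindered Brownian
motion with sedimentation, and wobbling swimmers. They do not emulate:
DMD mirror-tilt diffraction, speckle from instrument imperfections,
reference-arm aberrations or drift, hydrodynamic coupling between
particles, flagellar hydrodynamics, or dense multiple-scattering media
(dense scenes can be rasterized and propagated, but the Mie shortcut and
the single-scattering assumptions no longer apply). Passing tests
therefore validate the algorithms against their own stated physics, not
instrument-specific artifacts.

## Reproducibility and problem sizes

Every stochastic component takes an explicit seed (scene generation, noise,
partition swaps, the FISTA power iteration), and reruns are bit-identical.
The validation-sphere study in `scripts/acceptance.R` runs 49 views of a
10-µm sphere with holograms on a 256² grid at 0.125 µm, reconstructed on a
128² × 48 grid (0.25 µm lateral, 0.4 µm axial) with 12 FISTA iterations —
sizes chosen so the full study runs in minutes on a single CPU while the
recovered interior RI and diameter sit well inside the reported tolerance;
the test suite uses further-reduced replicas of the same pipelines.
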