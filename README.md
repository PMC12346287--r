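# holotomo

Multiplexed optical diffraction tomography (ODT) in R: Fourier-plane
pattern design for binary micromirror arrays, scalar-wave forward models,
off-axis holography, model-based 3D refractive-index reconstruction, and
particle-dynamics analysis — aimed at kilohertz-rate volumetric imaging of
colloids and microswimmers.

## The problem

ODT infers a sample's 3D refractive index n(r) from coherent transmission
images under many illumination angles. Sequential angle scanning caps the
volumetric rate at tens of hertz; fast processes (diffusing beads,
swimming bacteria) need orders of magnitude more. The approach implemented
here multiplexes tens of plane waves into each camera exposure by placing
a digital micromirror device (DMD) conjugate to the objective back focal
plane: a binary spot at DMD position r_p with carrier frequency f_p
produces a sample-plane beam with

    delta_r = (fl * lambda / M) (f_p - f_c),    f = (M / (fl * lambda)) (r_p - r_c),

so spot position encodes illumination angle and carrier frequency encodes
beam position. Angle multiplexing superposes views; position multiplexing
extends the field of view. The price is a harder inverse problem, solved
here by:

1. **Low-resolution Rytov demultiplexing** — split each hologram's Fourier
   plane into the regions nearest each beam's carrier, treat each region as
   a low-resolution single-beam view, and grid its Rytov field onto the
   Ewald sphere of the scattering potential V = k0^2 (n^2 - n0^2) to get an
   initial n(r).
2. **FISTA proximal-gradient refinement** — minimize the (phase-sensitive
   and/or phase-insensitive) data misfit of a multislice forward model,
   with total-variation and l1 regularization and the physical constraints
   Re(n) >= n0, Im(n) >= 0. The default forward model is the split-step
   non-paraxial scheme (SSNP), which — unlike obliquity-corrected beam
   propagation — is valid for superposed beams at different angles.

A scalar Mie partial-wave oracle generates exact validation data; scene
generators produce Brownian colloids (wall-hindered diffusion, Boltzmann
sedimentation) and wobbling rod swimmers, rendered to noisy off-axis
holograms; and a tracking stack (DoG + 3D Gaussian localization,
mutual-nearest-neighbour linking, MSD/step-CDF/hindered-diffusion/wobble
statistics) closes the loop.

## Worked example: designing the kilohertz pattern set

```r
library(holotomo)

geom <- system_geometry(illumination_na = 0.9, detection_na = 1.0,
                        background_index = 1.515, wavelength = 0.785)
angles <- design_angle_set(147, geom)          # Fermat-spiral direction set
illum  <- partition_angles(angles, 19, geom, seed = 1)
illum
#> <illumination_set> 8 frames, 152 beams (19x angle, 1x position multiplexing)

pitch <- geom$mirror_pitch
carriers <- lapply(list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)),
                   function(s) s / (4 * pitch))
khz <- compose_position_multiplex(illum, carriers, geom)
khz
#> <illumination_set> 8 frames, 608 beams (19x angle, 4x position multiplexing)
```

The 147 directions do not divide by 19, so five angles are duplicated to
fill the 8 x 19 = 152 slots; replicating every spot at four carrier
frequencies yields 608 plane waves per volume, 76 distinct beams per
exposure — the configuration used for kilohertz-rate imaging of diffusing
microspheres. `render_illumination()` rasterizes the binary DMD frames and
`write_dmd_frames()` exports them as multi-page TIFF.

A second common loop — simulate, reconstruct, track:

```r
model <- motion_model(diffusion_coefficient = 0.4, gravity = FALSE)
scene <- simulate_brownian_scene(model, n_particles = 6, n_frames = 96,
                                 dt = 0.02, seed = 21, chamber_height = 10,
                                 bead_index = 1.45, background_index = 1.333)
holos <- render_hologram_series(scene, illumination_set(lapply(design_angle_set(5, geom), list)),
                                grid = list(ny = 96, nx = 96, pixel_pitch = 1/6,
                                            wavelength = 0.785),
                                reference_frequency = c(1.1875, 1.1875),
                                detection_na = 0.95, photons = Inf, seed = 22)
```

after which `demodulate_hologram()`, `demultiplex_rytov_initialize()`,
`localize_particles()`, `link_trajectories()` and `msd_diffusion()`
recover the beads' diffusion coefficient from the holograms alone (see
`tests/testthat/test-acceptance.R` for the complete loop).

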