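# Shared fixtures for the test suite. Everything is generated in code; no
# binary fixtures.

# compact geometry used across tests (oil immersion, near-infrared)
test_geometry <- function(...) {
  system_geometry(illumination_na = 0.9, detection_na = 0.95,
                  background_index = 1.515, wavelength = 0.785, ...)
}

# small random weak phantom around n0
weak_phantom <- function(ny = 16, nx = 16, nz = 6, dn = 0.01, n0 = 1.515,
                         voxel_xy = 0.25, voxel_z = 0.4, seed = 11) {
  arr <- with_seed(seed, array(n0 + dn * stats::rnorm(ny * nx * nz) + 0i,
                               c(ny, nx, nz)))
  ri_volume(arr, voxel_xy, voxel_z, n0, 0.785)
}

# unit-amplitude plane-wave field helper on a small grid
test_plane_field <- function(f = c(0, 0), n = 64, pitch = 0.25,
                             n0 = 1.515, lam = 0.785) {
  plane_wave_field(plane_wave(f), n, n, pitch, lam, n0)
}

rel_err <- function(a, b) abs(a - b) / max(abs(b), 1e-300)
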