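# shared in-code fixtures; all synthetic, built at test time

# a reduced-resolution hindlimb phantom: same geometry, fewer voxels
small_phantom <- function(group = "wt", grid = c(48L, 48L, 7L), ...) {
  build_phantom(hindlimb_phantom(group, grid = grid, ...))
}

# single-compartment phantom with controllable truth values
uniform_phantom <- function(grid = c(24L, 24L, 3L), fat_fraction = 0,
                            t2_ms = 20, lambda = c(1.7, 1.7, 1.7),
                            principal_axis = c(0, 0, 1), b0_offset_hz = 0,
                            proton_density = 1, fov_mm = 20) {
  spec <- phantom_spec(
    grid = grid, fov_mm = fov_mm, slice_thickness_mm = 1,
    compartments = list(compartment(
      1L, "muscle", center_mm = c(0, 0), semi_axes_mm = c(8, 6),
      proton_density = proton_density, fat_fraction = fat_fraction,
      t2_ms = t2_ms, lambda_um2_ms = lambda, principal_axis = principal_axis,
      b0_offset_hz = b0_offset_hz)))
  build_phantom(spec)
}

# restricted two-singlet prior for focused spectral-fit tests
two_peak_prior <- function(f1_ppm = 0, f2_ppm, window = 0.2) {
  data.frame(name = c("P1", "P2"), ppm0 = c(f1_ppm, f2_ppm),
             ppm_window = window, mult = c(1L, 1L), damp0_hz = c(12, 12),
             damp_min_hz = 1, damp_max_hz = 80)
}
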