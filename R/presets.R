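#' Group parameter presets
#'
#' Generator presets encoding the two study conditions: wild-type (`"wt"`)
#' and the nemaline-myopathy transgenic model (`"tg"`). These are the group
#' means the simulators are parameterized with; the in vivo group contrasts
#' themselves (e.g. the absolute force deficit) are represented only here, as
#' generator inputs.
#'
#' @param group `"wt"` or `"tg"`.
#' @return named list of generator parameters.
#' @export
group_preset <- function(group = c("wt", "tg")) {
  group <- match.arg(group)
  if (group == "wt") {
    list(group = "wt",
         t2_ms = 18.8, lambda_um2_ms = c(1.95, 1.45, 1.07),
         fat_pct = 0.09, max_csa_mm2 = 37.2, volume_mm3 = 107,
         pcr_atp = 3.5, ph_rest = 7.06, tau_pcr_s = 148,
         f_max_mN = 300, max_dfdt_mN_per_ms = 3.15, hrt_ms = 262)
  } else {
    list(group = "tg",
         t2_ms = 19.8, lambda_um2_ms = c(1.88, 1.34, 1.00),
         fat_pct = 0.19, max_csa_mm2 = 32.0, volume_mm3 = 92,
         pcr_atp = 3.0, ph_rest = 7.08, tau_pcr_s = 159,
         f_max_mN = 210, max_dfdt_mN_per_ms = 2.42, hrt_ms = 148)
  }
}

#' Build the default hindlimb phantom for a study group
#'
#' Geometry: two disjoint muscle bellies (posterior and anterior) tapering
#' along the slice direction, a subcutaneous-fat annulus and a small bone
#' ellipse. The muscle taper is scaled so that the maximal analytic
#' cross-sectional area and the 4-slice volume match the group's anatomy
#' preset; microstructural truth (T2, fat fraction, tensor eigenvalues) comes
#' from the same preset. Muscle fibers run along the slice axis.
#'
#' @param group `"wt"` or `"tg"` (or a [group_preset()] list).
#' @param grid voxel grid, default 128 x 128 x 7.
#' @param fov_mm in-plane field of view, mm.
#' @param noise_sigma,rng_seed simulator defaults stored in the spec.
#' @param principal_axis muscle fiber direction (unit 3-vector).
#' @return a [phantom_spec()].
#' @export
hindlimb_phantom <- function(group = "wt", grid = c(128L, 128L, 7L), fov_mm = 20,
                             noise_sigma = 0, rng_seed = 1L,
                             principal_axis = c(0, 0, 1)) {
  p <- if (is.list(group)) group else group_preset(group)
  nz <- grid[3]
  # analytic total muscle area per slice, mm^2: tapers from the largest slice;
  # the 4 consecutive largest sum to the preset volume (1 mm slices)
  base <- c(37.2, 30.2, 22.6, 17.0, 12.0, 8.0, 5.0)
  if (nz != 7L) base <- stats::approx(seq(0, 1, length.out = 7), base,
                                      seq(0, 1, length.out = nz))$y
  areas <- base * (p$max_csa_mm2 / base[1])
  scl <- sqrt(areas / areas[1])
  post_a <- 0.6 * areas[1]; ant_a <- 0.4 * areas[1]
  semi <- function(area, ratio = 1.6) {
    b <- sqrt(area / (pi * ratio)); c(ratio * b, b)
  }
  muscle <- function(label, name, center, area) {
    compartment(label, name, center_mm = center, semi_axes_mm = semi(area),
                slice_scale = scl, proton_density = 1,
                fat_fraction = p$fat_pct / 100, t2_ms = p$t2_ms,
                lambda_um2_ms = p$lambda_um2_ms,
                principal_axis = principal_axis,
                b0_offset_hz = if (label == 1L) 10 else -8)
  }
  comps <- list(
    muscle(1L, "posterior_muscle", c(0, -2.6), post_a),
    muscle(2L, "anterior_muscle", c(0, 2.4), ant_a),
    compartment(3L, "subcutaneous_fat", center_mm = c(0, 0),
                semi_axes_mm = c(8.0, 7.5), inner_semi_axes_mm = c(7.2, 6.7),
                proton_density = 0.9, fat_fraction = 0.9, t2_ms = 35,
                lambda_um2_ms = c(0.4, 0.4, 0.4), b0_offset_hz = 30),
    compartment(4L, "bone", center_mm = c(4.5, 3.5), semi_axes_mm = c(0.8, 0.45),
                proton_density = 0.05, fat_fraction = 0, t2_ms = 5,
                lambda_um2_ms = c(0.3, 0.3, 0.3)))
  phantom_spec(grid = grid, fov_mm = fov_mm, slice_thickness_mm = 1,
               compartments = comps, noise_sigma = noise_sigma,
               rng_seed = rng_seed)
}
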