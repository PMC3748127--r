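#' Define a digital hindlimb phantom
#'
#' A phantom is a stack of axial slices over a square field of view, populated
#' by labelled tissue compartments (muscle, subcutaneous fat, bone). Each
#' compartment carries the per-voxel ground truth the simulators consume:
#' proton density, fat fraction, T2, a diffusion tensor given by its
#' eigenvalues and principal axis, and a B0 offset.
#'
#' @param grid integer vector `(nx, ny, nslices)` in voxels.
#' @param fov_mm in-plane field of view (square), mm.
#' @param slice_thickness_mm slice thickness, mm.
#' @param compartments list of [compartment()] objects.
#' @param noise_sigma default per-channel Gaussian noise sd used by simulators
#'   when they are not given an explicit value (signal units).
#' @param rng_seed default RNG seed for simulators.
#' @return an object of class `phantom_spec`.
#' @seealso [compartment()], [build_phantom()]
#' @export
phantom_spec <- function(grid = c(128L, 128L, 7L), fov_mm = 20,
                         slice_thickness_mm = 1, compartments,
                         noise_sigma = 0, rng_seed = 1L) {
  grid <- as.integer(grid)
  if (length(grid) != 3L || any(grid <= 0L)) stopf("grid must be 3 positive integers")
  if (fov_mm <= 0 || slice_thickness_mm <= 0) stopf("fov and slice thickness must be positive")
  if (!length(compartments)) stopf("at least one compartment is required")
  labs <- vapply(compartments, function(k) k$label, 1L)
  if (anyDuplicated(labs)) stopf("compartment labels must be unique")
  for (k in compartments) validate_compartment(k, grid, fov_mm)
  structure(list(grid = grid, fov_mm = fov_mm,
                 slice_thickness_mm = slice_thickness_mm,
                 compartments = compartments,
                 noise_sigma = noise_sigma, rng_seed = rng_seed),
            class = "phantom_spec")
}

#' Define a phantom tissue compartment
#'
#' Geometry is an ellipse or elliptical annulus per slice, optionally scaled
#' slice-by-slice (to taper the muscle belly along the leg).
#'
#' @param label integer label (> 0; 0 is background).
#' @param name compartment name, e.g. `"posterior_muscle"`.
#' @param center_mm in-plane center `(x, y)` in mm, FOV centered at 0.
#' @param semi_axes_mm ellipse semi-axes `(a, b)` in mm (outer, for annuli).
#' @param inner_semi_axes_mm if non-NULL, the compartment is the annulus
#'   between the inner and outer ellipse.
#' @param slice_scale per-slice multiplier applied to the semi-axes (length
#'   `nslices` or 1).
#' @param angle_deg in-plane rotation of the ellipse about its center,
#'   degrees counterclockwise.
#' @param proton_density proton density (arbitrary units, > 0 for signal).
#' @param fat_fraction fat fraction in `[0, 1]`.
#' @param t2_ms transverse relaxation time, ms (> 0).
#' @param lambda_um2_ms diffusion-tensor eigenvalues (l1 >= l2 >= l3 > 0), in
#'   1e-3 mm^2/s (= um^2/ms).
#' @param principal_axis unit 3-vector of the leading eigenvector (fiber
#'   direction); normalized internally.
#' @param b0_offset_hz local field offset, Hz.
#' @return an object of class `phantom_compartment`.
#' @export
compartment <- function(label, name, center_mm, semi_axes_mm,
                        inner_semi_axes_mm = NULL, slice_scale = 1,
                        angle_deg = 0,
                        proton_density = 1, fat_fraction = 0, t2_ms = 20,
                        lambda_um2_ms = c(1.7, 1.7, 1.7),
                        principal_axis = c(0, 0, 1), b0_offset_hz = 0) {
  ax <- principal_axis / sqrt(sum(principal_axis^2))
  structure(list(label = as.integer(label), name = name,
                 center_mm = center_mm, semi_axes_mm = semi_axes_mm,
                 inner_semi_axes_mm = inner_semi_axes_mm,
                 slice_scale = slice_scale, angle_deg = angle_deg,
                 proton_density = proton_density, fat_fraction = fat_fraction,
                 t2_ms = t2_ms, lambda_um2_ms = lambda_um2_ms,
                 principal_axis = ax, b0_offset_hz = b0_offset_hz),
            class = "phantom_compartment")
}

validate_compartment <- function(k, grid, fov_mm) {
  if (k$label <= 0L) stopf("compartment '%s': label must be > 0", k$name)
  if (k$fat_fraction < 0 || k$fat_fraction > 1)
    stopf("compartment '%s': fat_fraction must lie in [0, 1]", k$name)
  if (k$t2_ms <= 0) stopf("compartment '%s': t2_ms must be > 0", k$name)
  l <- k$lambda_um2_ms
  if (length(l) != 3L || any(l <= 0) || is.unsorted(rev(l)))
    stopf("compartment '%s': eigenvalues must satisfy l1 >= l2 >= l3 > 0", k$name)
  if (k$proton_density < 0) stopf("compartment '%s': proton_density must be >= 0", k$name)
  ns <- length(k$slice_scale)
  if (ns != 1L && ns != grid[3])
    stopf("compartment '%s': slice_scale must have length 1 or nslices", k$name)
  half <- fov_mm / 2
  ax_ext <- if ((k$angle_deg %||% 0) %% 180 == 0) k$semi_axes_mm
            else rep(max(k$semi_axes_mm), 2)
  ext <- abs(k$center_mm) + ax_ext * max(k$slice_scale)
  if (any(ext > half))
    stopf("compartment '%s': geometry extends outside the field of view", k$name)
  invisible(k)
}

# symmetric positive-definite tensor from eigenvalues + principal axis;
# returns the 6 unique components (xx, yy, zz, xy, xz, yz)
tensor_from_axis <- function(lambda, axis) {
  v1 <- axis / sqrt(sum(axis^2))
  u <- diag(3)[, which.min(abs(v1))]
  v2 <- u - sum(u * v1) * v1
  v2 <- v2 / sqrt(sum(v2^2))
  v3 <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  D <- lambda[1] * tcrossprod(v1) + lambda[2] * tcrossprod(v2) +
    lambda[3] * tcrossprod(v3)
  c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
}

#' Rasterize a phantom into a label volume with ground-truth maps
#'
#' Voxels are assigned the label of the compartment containing their center.
#' Two compartments claiming the same voxel is an error (the phantom geometry
#' must be disjoint).
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `ground_truth`: `label` (nx x ny x nz integer
#'   array), `maps` with per-voxel `pd`, `ff`, `t2`, `b0_hz` and `tensor`
#'   (nx x ny x nz x 6, components xx, yy, zz, xy, xz, yz in 1e-3 mm^2/s),
#'   `voxel_dims_mm`, and the originating `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$grid[1]; ny <- spec$grid[2]; nz <- spec$grid[3]
  dx <- spec$fov_mm / nx; dy <- spec$fov_mm / ny
  xs <- (seq_len(nx) - (nx + 1) / 2) * dx
  ys <- (seq_len(ny) - (ny + 1) / 2) * dy
  X <- matrix(xs, nx, ny)          # voxel-center coordinates, mm
  Y <- matrix(ys, nx, ny, byrow = TRUE)

  lab <- array(0L, c(nx, ny, nz))
  pd <- array(0, c(nx, ny, nz)); ff <- array(NA_real_, c(nx, ny, nz))
  t2 <- array(NA_real_, c(nx, ny, nz)); b0 <- array(0, c(nx, ny, nz))
  tensor <- array(NA_real_, c(nx, ny, nz, 6))

  inside <- function(k, z) {
    s <- if (length(k$slice_scale) == 1L) k$slice_scale else k$slice_scale[z]
    if (s <= 0) return(matrix(FALSE, nx, ny))
    th <- (k$angle_deg %||% 0) * pi / 180
    xr <- cos(th) * (X - k$center_mm[1]) + sin(th) * (Y - k$center_mm[2])
    yr <- -sin(th) * (X - k$center_mm[1]) + cos(th) * (Y - k$center_mm[2])
    a <- k$semi_axes_mm[1] * s; b <- k$semi_axes_mm[2] * s
    m <- (xr / a)^2 + (yr / b)^2 <= 1
    if (!is.null(k$inner_semi_axes_mm)) {
      ai <- k$inner_semi_axes_mm[1] * s; bi <- k$inner_semi_axes_mm[2] * s
      m <- m & ((xr / ai)^2 + (yr / bi)^2 > 1)
    }
    m
  }

  for (z in seq_len(nz)) {
    for (k in spec$compartments) {
      m <- inside(k, z)
      clash <- m & lab[, , z] != 0L
      if (any(clash)) {
        ij <- which(clash, arr.ind = TRUE)[1, ]
        stopf("compartments overlap at voxel (%d, %d, %d): labels %d and %d",
              ij[1], ij[2], z, lab[ij[1], ij[2], z], k$label)
      }
      lz <- lab[, , z]; lz[m] <- k$label; lab[, , z] <- lz
      assign_map <- function(arr, val) { az <- arr[, , z]; az[m] <- val; arr[, , z] <- az; arr }
      pd <- assign_map(pd, k$proton_density)
      ff <- assign_map(ff, k$fat_fraction)
      t2 <- assign_map(t2, k$t2_ms)
      b0 <- assign_map(b0, k$b0_offset_hz)
      D <- tensor_from_axis(k$lambda_um2_ms, k$principal_axis)
      for (c6 in 1:6) {
        az <- tensor[, , z, c6]; az[m] <- D[c6]; tensor[, , z, c6] <- az
      }
    }
  }

  structure(list(label = lab,
                 maps = list(pd = pd, ff = ff, t2 = t2, b0_hz = b0, tensor = tensor),
                 voxel_dims_mm = c(dx, dy, spec$slice_thickness_mm),
                 compartments = spec$compartments,
                 spec = spec),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d x %d x %d voxels (%.4g x %.4g x %.4g mm)\n",
              dim(x$label)[1], dim(x$label)[2], dim(x$label)[3],
              x$voxel_dims_mm[1], x$voxel_dims_mm[2], x$voxel_dims_mm[3]))
  for (k in x$compartments)
    cat(sprintf("  label %d: %s (%d voxels)\n", k$label, k$name,
                sum(x$label == k$label)))
  invisible(x)
}

#' Indices of the slices with the largest cross sections
#'
#' @param mask logical 3D array (muscle mask or label mask).
#' @param n number of slices to return.
#' @param consecutive if TRUE, return the window of `n` consecutive slices
#'   maximizing total area (used for volume); otherwise the top `n` slices by
#'   area (used for ROI averaging).
#' @return integer slice indices, increasing.
#' @export
largest_slices <- function(mask, n, consecutive = FALSE) {
  areas <- apply(mask, 3, sum)
  nz <- length(areas)
  n <- min(n, nz)
  if (consecutive) {
    tot <- vapply(seq_len(nz - n + 1L), function(i) sum(areas[i:(i + n - 1L)]), 0)
    i0 <- which.max(tot)
    return(i0:(i0 + n - 1L))
  }
  sort(order(areas, decreasing = TRUE)[seq_len(n)])
}
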