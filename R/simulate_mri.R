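#' Default diffusion-encoding directions
#'
#' Twelve unit vectors spread by electrostatic (antipodally symmetric Coulomb)
#' repulsion on the sphere, frozen so that acquisitions are reproducible. The
#' resulting tensor design matrix has full rank 6 with condition number < 1.6.
#'
#' @return a 12 x 3 matrix of unit row vectors.
#' @export
dti_directions <- function() {
  m <- matrix(c(
     0.072127,  0.993262, 0.090708,
    -0.603693,  0.152507, 0.782494,
     0.060746, -0.815883, 0.575018,
     0.855990,  0.184748, 0.482855,
     0.036542, -0.091118, 0.995169,
     0.703795, -0.708742, 0.048556,
     0.607407, -0.397718, 0.687661,
    -0.576421, -0.526358, 0.625048,
    -0.981902,  0.057102, 0.180575,
     0.709294,  0.703738, 0.040678,
    -0.355106,  0.734970, 0.577684,
     0.314649,  0.560521, 0.766037), ncol = 3, byrow = TRUE)
  m / sqrt(rowSums(m^2))
}

#' Dixon echo scheme
#'
#' Declares, for each of the three gradient-echo acquisitions, its echo time
#' and its nominal water-fat phase: in-phase, opposed-phase, in-phase. The
#' echoes are generated at idealized water-fat phase angles (0, pi, 2*pi); the
#' field-offset phase uses the literal echo times, which must be evenly
#' spaced so that the in-phase pair brackets the opposed echo symmetrically.
#'
#' @param te_ms the three echo times, ms (evenly spaced).
#' @return list with `te_ms` and `wf_phase` (radians per echo).
#' @export
dixon_scheme <- function(te_ms = c(1.5, 1.8, 2.1)) {
  if (length(te_ms) != 3L) stopf("a 3-point Dixon scheme needs exactly 3 echoes")
  if (abs(diff(diff(te_ms))) > 1e-9) stopf("Dixon echo times must be evenly spaced")
  list(te_ms = te_ms, wf_phase = c(0, pi, 2 * pi),
       phase_labels = c("in", "opposed", "in"))
}

#' Simulate a three-point Dixon acquisition
#'
#' Per voxel the complex echo-n signal is
#' `S_n = (W + F * exp(1i*theta_n)) * exp(2i*pi*psi*TE_n)` plus complex
#' Gaussian noise, with `W = pd*(1-FF)`, `F = pd*FF`, water-fat phase
#' `theta_n` in (0, pi, 2*pi) and `psi` the compartment B0 offset (Hz).
#'
#' @param gt a [build_phantom()] result.
#' @param scheme a [dixon_scheme()].
#' @param noise_sigma per-channel Gaussian noise sd (default from the spec).
#' @param seed RNG seed (default from the spec).
#' @return a `multiecho_volume` with complex `data` (nx x ny x nz x 3),
#'   `te_ms`, `phase_labels`, `noise_sigma`, `seed`.
#' @export
simulate_dixon <- function(gt, scheme = dixon_scheme(), noise_sigma = NULL,
                           seed = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  noise_sigma <- noise_sigma %||% gt$spec$noise_sigma
  seed <- seed %||% gt$spec$rng_seed
  if (is.null(scheme$wf_phase)) stopf("unknown Dixon phase scheme")
  dm <- dim(gt$label)
  pd <- gt$maps$pd
  ffm <- gt$maps$ff; ffm[is.na(ffm)] <- 0
  W <- pd * (1 - ffm); Fa <- pd * ffm
  psi <- gt$maps$b0_hz
  dat <- array(complex(real = 0), c(dm, 3))
  for (n in 1:3) {
    s <- (W + Fa * exp(1i * scheme$wf_phase[n])) *
      exp(2i * pi * psi * scheme$te_ms[n] / 1000)
    dat[, , , n] <- s
  }
  if (noise_sigma > 0) {
    dat <- with_seed(seed, dat + cnoise(length(dat), noise_sigma))
  }
  structure(list(data = dat, te_ms = scheme$te_ms,
                 phase_labels = scheme$phase_labels,
                 kind = "dixon", noise_sigma = noise_sigma, seed = seed),
            class = "multiecho_volume")
}

#' Simulate a multi-echo spin-echo T2 acquisition
#'
#' Magnitude signal `S(TE) = S0 * exp(-TE/T2)` per voxel, with `S0` the
#' water proton density (the acquisition is fat-suppressed, so the fat signal
#' contributes nothing). Complex Gaussian noise is added before taking the
#' magnitude, so noisy images are Rician distributed.
#'
#' @param gt a [build_phantom()] result.
#' @param tes_ms echo times, ms (all > 0).
#' @inheritParams simulate_dixon
#' @return a `multiecho_volume` with numeric magnitude `data`
#'   (nx x ny x nz x n_echo) and `te_ms`.
#' @export
simulate_multiecho_t2 <- function(gt, tes_ms = c(8, 12, 16, 20, 24),
                                  noise_sigma = NULL, seed = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  if (any(tes_ms <= 0)) stopf("all echo times must be > 0")
  noise_sigma <- noise_sigma %||% gt$spec$noise_sigma
  seed <- seed %||% gt$spec$rng_seed
  dm <- dim(gt$label)
  ffm <- gt$maps$ff; ffm[is.na(ffm)] <- 0
  s0 <- gt$maps$pd * (1 - ffm)
  t2 <- gt$maps$t2
  dat <- array(0, c(dm, length(tes_ms)))
  for (n in seq_along(tes_ms)) {
    s <- s0 * exp(-tes_ms[n] / t2)
    s[is.na(s)] <- 0
    dat[, , , n] <- s
  }
  if (noise_sigma > 0) {
    dat <- with_seed(seed, {
      Mod(dat + cnoise(length(dat), noise_sigma))
    })
  }
  structure(list(data = dat, te_ms = tes_ms, kind = "t2",
                 noise_sigma = noise_sigma, seed = seed),
            class = "multiecho_volume")
}

#' Simulate a diffusion-weighted (Stejskal-Tanner) acquisition
#'
#' Per voxel and direction g, `S = S0 * exp(-b * g' D g)` with D the
#' ground-truth tensor (1e-3 mm^2/s; b in s/mm^2). Fat signal is suppressed.
#' Complex Gaussian noise is added before the magnitude is taken.
#'
#' @param gt a [build_phantom()] result.
#' @param bval diffusion weighting for the encoded volumes, s/mm^2.
#' @param directions n x 3 matrix of unit gradient directions.
#' @param n_b0 number of unweighted (b = 0) volumes prepended.
#' @inheritParams simulate_dixon
#' @return a `diffusion_volume`: `data` (nx x ny x nz x (n_b0 + n_dir)),
#'   `bvals`, `directions` (rows aligned with the weighted volumes).
#' @export
simulate_dwi <- function(gt, bval = 450, directions = dti_directions(),
                         n_b0 = 1L, noise_sigma = NULL, seed = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  directions <- as.matrix(directions)
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-6)) stopf("diffusion directions must be unit vectors")
  noise_sigma <- noise_sigma %||% gt$spec$noise_sigma
  seed <- seed %||% gt$spec$rng_seed
  dm <- dim(gt$label)
  ffm <- gt$maps$ff; ffm[is.na(ffm)] <- 0
  s0 <- gt$maps$pd * (1 - ffm)
  nd <- nrow(directions)
  dat <- array(0, c(dm, n_b0 + nd))
  for (j in seq_len(n_b0)) dat[, , , j] <- s0
  Dx <- gt$maps$tensor
  for (j in seq_len(nd)) {
    g <- directions[j, ]
    # g' D g from the 6 unique components (xx, yy, zz, xy, xz, yz), in 1e-3 mm^2/s
    q <- Dx[, , , 1] * g[1]^2 + Dx[, , , 2] * g[2]^2 + Dx[, , , 3] * g[3]^2 +
      2 * (Dx[, , , 4] * g[1] * g[2] + Dx[, , , 5] * g[1] * g[3] +
             Dx[, , , 6] * g[2] * g[3])
    s <- s0 * exp(-bval * 1e-3 * q)
    s[is.na(s)] <- 0
    dat[, , , n_b0 + j] <- s
  }
  if (noise_sigma > 0) {
    dat <- with_seed(seed, Mod(dat + cnoise(length(dat), noise_sigma)))
  }
  structure(list(data = dat, bvals = c(rep(0, n_b0), rep(bval, nd)),
                 directions = directions, n_b0 = n_b0,
                 noise_sigma = noise_sigma, seed = seed),
            class = "diffusion_volume")
}
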