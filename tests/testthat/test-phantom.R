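test_that("phantom rasterization fills truth maps per compartment", {
  spec <- hindlimb_phantom("tg")
  expect_equal(prod(spec$grid), 128 * 128 * 7)
  # at full resolution the voxel volume is (20/128)^2 x 1 mm = 0.0244 mm^3
  expect_equal(round((spec$fov_mm / spec$grid[1])^2 * spec$slice_thickness_mm, 4),
               0.0244)
  gt <- small_phantom("tg")
  expect_equal(gt$voxel_dims_mm, c(20 / 48, 20 / 48, 1), tolerance = 1e-12)
  post <- gt$label == 1L
  expect_true(all(gt$maps$t2[post] == 19.8))
  expect_true(all(gt$maps$ff[post] == 0.19 / 100))
  # fat-free phantom: truth fat fraction identically zero where labelled
  gt0 <- uniform_phantom(fat_fraction = 0)
  expect_true(all(gt0$maps$ff[gt0$label == 1L] == 0))
  # tensor symmetric positive definite in labelled voxels
  i <- which(gt$label == 1L)[1]
  ij <- arrayInd(i, dim(gt$label))
  d6 <- gt$maps$tensor[ij[1], ij[2], ij[3], ]
  D <- matrix(c(d6[1], d6[4], d6[5], d6[4], d6[2], d6[6], d6[5], d6[6], d6[3]), 3)
  expect_equal(D, t(D))
  expect_true(all(eigen(D, symmetric = TRUE, only.values = TRUE)$values > 0))
})

test_that("overlapping compartments raise an error naming the voxel", {
  comps <- list(
    compartment(1L, "a", c(0, 0), c(4, 4)),
    compartment(2L, "b", c(1, 0), c(4, 4)))
  spec <- phantom_spec(grid = c(24L, 24L, 1L), fov_mm = 20,
                       compartments = comps)
  expect_error(build_phantom(spec), "overlap at voxel")
})

test_that("spec invariants are enforced", {
  expect_error(uniform_phantom(fat_fraction = 1.2), "fat_fraction")
  expect_error(uniform_phantom(t2_ms = -1), "t2_ms")
  expect_error(uniform_phantom(lambda = c(1, 2, 3)), "eigenvalues")
  expect_error(
    phantom_spec(grid = c(16L, 16L, 1L), fov_mm = 10, compartments = list(
      compartment(1L, "big", c(0, 0), c(8, 8)))),
    "field of view")
})

test_that("rasterized areas converge to analytic ellipse areas", {
  gt <- uniform_phantom(grid = c(128L, 128L, 1L))
  vox <- prod(gt$voxel_dims_mm[1:2])
  area <- sum(gt$label == 1L) * vox
  analytic <- pi * 8 * 6
  perim <- pi * (8 + 6)  # upper bound on |raster - analytic|: one voxel band
  expect_lt(abs(area - analytic), perim * gt$voxel_dims_mm[1])
})

test_that("simulators are deterministic given spec and seed", {
  gt <- uniform_phantom()
  a <- simulate_dixon(gt, noise_sigma = 0.05, seed = 42L)
  b <- simulate_dixon(gt, noise_sigma = 0.05, seed = 42L)
  expect_identical(a$data, b$data)
  c <- simulate_dixon(gt, noise_sigma = 0.05, seed = 43L)
  expect_false(identical(a$data, c$data))
})

test_that("Dixon signal model produces the expected echo magnitudes", {
  # pure water: same magnitude on all three echoes
  gt <- uniform_phantom(fat_fraction = 0)
  dx <- simulate_dixon(gt)
  m <- gt$label == 1L
  for (n in 2:3)
    expect_equal(Mod(dx$data[, , , n])[m], Mod(dx$data[, , , 1])[m],
                 tolerance = 1e-12)
  # half fat: opposed-phase echo cancels
  gt5 <- uniform_phantom(fat_fraction = 0.5)
  dx5 <- simulate_dixon(gt5)
  expect_true(all(Mod(dx5$data[, , , 2])[gt5$label == 1L] < 1e-12))
  # W = 80, F = 20 (pd 100, ff 0.2): opposed magnitude |W - F| = 60
  gt2 <- uniform_phantom(fat_fraction = 0.2, proton_density = 100)
  dx2 <- simulate_dixon(gt2)
  expect_equal(unique(round(Mod(dx2$data[, , , 2])[gt2$label == 1L], 9)), 60)
})

test_that("multi-echo T2 signal follows the monoexponential decay", {
  gt <- uniform_phantom(t2_ms = 18.8)
  me <- simulate_multiecho_t2(gt, tes_ms = c(8, 12, 16, 20, 24))
  m <- gt$label == 1L
  expect_equal(unique(me$data[, , , 1][m]), exp(-8 / 18.8), tolerance = 1e-12)
  # TE -> 0 limit returns S0
  me0 <- simulate_multiecho_t2(gt, tes_ms = c(1e-9, 8))
  expect_equal(unique(me0$data[, , , 1][m]), 1, tolerance = 1e-6)
  # noiseless signal exactly monoexponential: log-signal differences constant
  s <- sapply(1:5, function(n) me$data[, , , n][m][1])
  expect_equal(diff(log(s)), rep(-4 / 18.8, 4), tolerance = 1e-12)
  expect_error(simulate_multiecho_t2(gt, tes_ms = c(0, 8)), "echo times")
})

test_that("diffusion signal follows the Stejskal-Tanner closed form", {
  lam <- c(1.95, 1.45, 1.07)
  gt <- uniform_phantom(lambda = lam, principal_axis = c(1, 0, 0))
  dwi <- simulate_dwi(gt, bval = 450, directions = diag(3))
  m <- gt$label == 1L
  expect_equal(unique(dwi$data[, , , 1][m]), 1)  # b = 0 equals S0
  # g = (1,0,0): S/S0 = exp(-450e-3 * 1.95)
  expect_equal(unique(round(dwi$data[, , , 2][m], 12)),
               round(exp(-0.45 * 1.95), 12))
  # isotropic tensor: identical signal in all 12 directions
  gti <- uniform_phantom(lambda = c(1.5, 1.5, 1.5))
  di <- simulate_dwi(gti)
  sig <- sapply(1 + 1:12, function(j) di$data[, , , j][gti$label == 1L][1])
  expect_equal(max(sig) - min(sig), 0, tolerance = 1e-15)
  expect_error(simulate_dwi(gt, directions = matrix(c(1, 1, 0), 1)), "unit")
})

test_that("MRS bin amplitudes equal the kinetic model averaged over windows", {
  kin <- mrs_kinetics(pcr_end_stim_pct = 55, tau_deplete_s = 40,
                      tau_recovery_s = 148)
  prot <- mrs_protocol()
  ser <- simulate_mrs_series(kin, prot)
  expect_equal(nrow(ser$meta), 18L)
  # rest bins at 100%
  expect_equal(ser$meta$pcr_pct_true[ser$meta$phase == "rest"], 100)
  # quadrature oracle: numeric integration of the point kinetics over windows
  for (i in c(2, 5, 8, 14, 18)) {
    a <- ser$meta$t_start_s[i]; b <- a + ser$meta$width_s[i]
    q <- stats::integrate(function(t) pcr_fraction(kin, t, prot), a, b,
                          rel.tol = 1e-10)$value / (b - a)
    expect_equal(ser$meta$pcr_pct_true[i], 100 * q, tolerance = 1e-3)
  }
  # conservation: PCr + Pi constant in amplitude units, to machine precision
  pcr_amp <- ser$meta$pcr_pct_true
  pi_amp <- ser$meta$pi_pct_true * kin$pi_rest_frac
  expect_equal(pcr_amp + pi_amp, rep(100 + 100 * kin$pi_rest_frac, 18),
               tolerance = 1e-12)
})

test_that("force waveforms honour their closed-form kinetics", {
  # max dF/dt = F_peak * k at train onset
  sp <- force_protocol_spec(frequencies_hz = 150, noise_sigma = 0)
  rec <- simulate_force_protocol(sp)
  pk <- rec$schedule$trains$peak_true_mN
  f <- rec$force_mN
  expect_equal(max(diff(f)) * sp$sample_rate_hz, pk * sp$rise_k_per_s,
               tolerance = 1e-3)
  # fatigue: 360 s at 1.7 Hz gives 612 scheduled stimuli
  spf <- force_protocol_spec(mode = "fatigue")
  rf <- simulate_force_protocol(spf)
  expect_length(rf$schedule$stim_times_s, 612L)
})
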