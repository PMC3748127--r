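test_that("noiseless tensor fit recovers the ground truth exactly", {
  lam <- c(1.95, 1.45, 1.07)
  gt <- uniform_phantom(lambda = lam, principal_axis = c(1, 0, 0))
  tf <- fit_tensor(simulate_dwi(gt))
  m <- gt$label == 1L
  truth <- c(lam, 0, 0, 0)  # diagonal in this orientation
  for (c6 in 1:6) {
    comp <- tf$tensor[, , , c6]
    expect_lt(max(abs(comp[m] - truth[c6])), 1e-9)
  }
  # overdetermined 12-direction fit equals an exact 6-direction solve
  g6 <- dti_directions()[c(1, 3, 5, 7, 9, 11), ]
  tf6 <- fit_tensor(simulate_dwi(gt, directions = g6))
  expect_equal(tf$tensor[m], tf6$tensor[m], tolerance = 1e-9)
})

test_that("isotropic truth yields an isotropic fitted tensor", {
  gt <- uniform_phantom(lambda = c(1.5, 1.5, 1.5))
  tf <- fit_tensor(simulate_dwi(gt))
  met <- tensor_metrics(tf)
  m <- gt$label == 1L
  expect_lt(max(abs(met$lambda1[m] - 1.5)), 1e-9)
  expect_lt(max(abs(met$fa[m])), 1e-9)
})

test_that("rank-deficient or undersized direction sets are rejected", {
  gt <- uniform_phantom()
  # all in-plane directions cannot determine the z components
  ang <- seq(0, pi, length.out = 7)[1:6]
  flat <- cbind(cos(ang), sin(ang), 0)
  dwi <- simulate_dwi(gt, directions = flat)
  expect_error(fit_tensor(dwi), "rank")
  dwi2 <- simulate_dwi(gt, directions = diag(3))
  expect_error(fit_tensor(dwi2), ">= 6")
})

test_that("eigenvalue metrics match their closed forms", {
  lam <- c(1.95, 1.45, 1.07)
  expect_equal(adc_from_eigenvalues(lam), 1.49)
  fa <- sqrt(1.5) * sqrt(sum((lam - mean(lam))^2)) / sqrt(sum(lam^2))
  expect_equal(fa_from_eigenvalues(lam), fa, tolerance = 1e-12)
  expect_equal(round(fa, 2), 0.29)
  expect_equal(fa_from_eigenvalues(c(2, 2, 2)), 0)
  # metrics maps: eigenvalues sorted descending, adc = trace/3 exactly
  gt <- uniform_phantom(lambda = lam, principal_axis = c(0.6, 0.8, 0))
  met <- tensor_metrics(fit_tensor(simulate_dwi(gt)))
  m <- gt$label == 1L
  expect_true(all(met$lambda1[m] >= met$lambda2[m] &
                    met$lambda2[m] >= met$lambda3[m]))
  tr3 <- (gt$maps$tensor[, , , 1] + gt$maps$tensor[, , , 2] +
            gt$maps$tensor[, , , 3]) / 3
  expect_equal(met$adc[m], tr3[m], tolerance = 1e-9)
})

test_that("metrics are equivariant under rotation of the fiber axis", {
  lam <- c(1.95, 1.45, 1.07)
  axes <- list(c(0, 0, 1), c(1, 0, 0), c(1, 1, 1) / sqrt(3),
               c(0.2, -0.5, 0.84) / sqrt(sum(c(0.2, -0.5, 0.84)^2)))
  vals <- lapply(axes, function(ax) {
    gt <- uniform_phantom(lambda = lam, principal_axis = ax)
    met <- tensor_metrics(fit_tensor(simulate_dwi(gt)))
    m <- gt$label == 1L
    c(met$lambda1[m][1], met$lambda2[m][1], met$lambda3[m][1],
      met$adc[m][1], met$fa[m][1])
  })
  for (v in vals[-1]) expect_equal(v, vals[[1]], tolerance = 1e-6)
})

test_that("ROI means behave as arithmetic means over valid voxels", {
  gt <- uniform_phantom(lambda = c(1.88, 1.34, 1.00))
  met <- tensor_metrics(fit_tensor(simulate_dwi(gt)))
  roi <- gt$label == 1L
  mm <- roi_mean_metrics(met, roi)
  expect_equal(unname(mm["lambda1"]), 1.88, tolerance = 1e-9)
  expect_equal(unname(mm["adc"]), mean(c(1.88, 1.34, 1.00)), tolerance = 1e-9)
  # two-voxel ROI lambda1 {1.8, 2.0} -> 1.9
  met2 <- met
  met2$lambda1[] <- NA; met2$valid[] <- FALSE
  met2$lambda1[1, 1, 1] <- 1.8; met2$lambda1[2, 1, 1] <- 2.0
  met2$lambda2[1:2, 1, 1] <- 1; met2$lambda3[1:2, 1, 1] <- 1
  met2$adc[1:2, 1, 1] <- 1; met2$fa[1:2, 1, 1] <- 0
  met2$valid[1:2, 1, 1] <- TRUE
  roi2 <- array(FALSE, dim(gt$label)); roi2[1:2, 1, 1] <- TRUE
  expect_equal(unname(roi_mean_metrics(met2, roi2, n_slices = 1L)["lambda1"]),
               1.9)
  expect_error(roi_mean_metrics(met, array(FALSE, dim(gt$label))), "empty")
})

test_that("ROI eigenvalue recovery stays within 2% at SNR 100", {
  gt <- small_phantom("tg")
  post <- gt$label == 1L
  truth <- c(1.88, 1.34, 1.00)
  res <- sapply(1:5, function(s) {
    dwi <- simulate_dwi(gt, noise_sigma = 0.01, seed = s)
    roi_mean_metrics(tensor_metrics(fit_tensor(dwi)), post)[1:3]
  })
  expect_true(all(abs(res / truth - 1) < 0.02))
})
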