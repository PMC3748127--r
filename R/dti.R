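#' Diffusion-tensor estimation by linear least squares
#'
#' Per voxel, solves `ln(S_i / S0) = -b * g_i' D g_i` with design-matrix rows
#' `(gx^2, gy^2, gz^2, 2 gx gy, 2 gx gz, 2 gy gz)`. Multiple b = 0 volumes
#' are averaged into S0. Voxels with any nonpositive signal are flagged
#' invalid.
#'
#' @param dwi a `diffusion_volume` from [simulate_dwi()] or read from disk.
#' @return a `tensor_field`: `tensor` (nx x ny x nz x 6, components xx, yy,
#'   zz, xy, xz, yz in 1e-3 mm^2/s), `s0`, `valid`.
#' @export
fit_tensor <- function(dwi) {
  stopifnot(inherits(dwi, "diffusion_volume"))
  g <- dwi$directions
  if (nrow(g) < 6L) stopf("need >= 6 diffusion directions")
  b <- dwi$bvals[dwi$bvals > 0] * 1e-3        # work in 1e-3 mm^2/s units
  X <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3]) * b
  if (qr(X)$rank < 6L) stopf("rank-deficient direction set: cannot fit a tensor")
  dm <- dim(dwi$data)
  n_b0 <- dwi$n_b0
  nd <- nrow(g)
  S <- matrix(dwi$data, ncol = dm[4])
  s0 <- if (n_b0 == 1L) S[, 1] else rowMeans(S[, seq_len(n_b0), drop = FALSE])
  Sw <- S[, n_b0 + seq_len(nd), drop = FALSE]
  valid <- s0 > 0 & rowSums(Sw > 0) == nd
  Yl <- -log(pmax(Sw, .Machine$double.xmin) / pmax(s0, .Machine$double.xmin))
  P <- solve(crossprod(X), t(X))              # 6 x nd pseudo-inverse
  D <- Yl %*% t(P)                            # voxels x 6
  D[!valid, ] <- NA_real_
  dm3 <- dm[1:3]
  structure(list(tensor = array(D, c(dm3, 6)),
                 s0 = array(ifelse(valid, s0, NA_real_), dm3),
                 valid = array(valid, dm3)),
            class = "tensor_field")
}

#' Mean diffusivity from eigenvalues
#' @param lambda numeric vector or 3-column matrix of eigenvalues.
#' @return mean of the three eigenvalues (ADC).
#' @export
adc_from_eigenvalues <- function(lambda) {
  if (is.matrix(lambda)) rowMeans(lambda) else mean(lambda)
}

#' Fractional anisotropy from eigenvalues
#'
#' `FA = sqrt(3/2) * sqrt(sum((l_i - mean)^2)) / sqrt(sum(l_i^2))`.
#'
#' @inheritParams adc_from_eigenvalues
#' @export
fa_from_eigenvalues <- function(lambda) {
  if (!is.matrix(lambda)) lambda <- matrix(lambda, nrow = 1)
  m <- rowMeans(lambda)
  num <- sqrt(rowSums((lambda - m)^2))
  den <- sqrt(rowSums(lambda^2))
  fa <- sqrt(1.5) * num / den
  if (length(fa) == 1L) fa[[1]] else fa
}

# analytic eigenvalues of symmetric 3x3 tensors, vectorized over rows of the
# 6-component representation (xx, yy, zz, xy, xz, yz); returns descending
eig3_sym <- function(D6) {
  xx <- D6[, 1]; yy <- D6[, 2]; zz <- D6[, 3]
  xy <- D6[, 4]; xz <- D6[, 5]; yz <- D6[, 6]
  p1 <- xy^2 + xz^2 + yz^2
  q <- (xx + yy + zz) / 3
  p2 <- (xx - q)^2 + (yy - q)^2 + (zz - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  l1 <- l2 <- l3 <- q
  nz <- p > 0 & is.finite(p)
  if (any(nz)) {
    bxx <- (xx - q) / p; byy <- (yy - q) / p; bzz <- (zz - q) / p
    bxy <- xy / p; bxz <- xz / p; byz <- yz / p
    detB <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
      bxz * (bxy * byz - byy * bxz)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    l1[nz] <- (q + 2 * p * cos(phi))[nz]
    l3[nz] <- (q + 2 * p * cos(phi + 2 * pi / 3))[nz]
    l2[nz] <- (3 * q - l1 - l3)[nz]
  }
  cbind(l1, l2, l3)
}

#' Eigenvalue, ADC and FA maps from a tensor field
#'
#' Eigenvalues are sorted descending per voxel; `ADC = (l1 + l2 + l3)/3`;
#' FA as in [fa_from_eigenvalues()]. Negative eigenvalues produced by noise
#' are retained (not clamped, to avoid bias) but counted.
#'
#' @param field a [fit_tensor()] result.
#' @return a `dti_metrics`: maps `lambda1..lambda3`, `adc`, `fa`, `valid`,
#'   plus `n_negative_eigenvalues`.
#' @export
tensor_metrics <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  dm3 <- dim(field$valid)
  D <- matrix(field$tensor, ncol = 6)
  valid <- as.vector(field$valid) & rowSums(is.finite(D)) == 6
  L <- matrix(NA_real_, nrow(D), 3)
  if (any(valid)) L[valid, ] <- eig3_sym(D[valid, , drop = FALSE])
  adc <- rowMeans(L)
  fa <- rep(NA_real_, nrow(L))
  fa[valid] <- fa_from_eigenvalues(L[valid, , drop = FALSE])
  structure(list(lambda1 = array(L[, 1], dm3), lambda2 = array(L[, 2], dm3),
                 lambda3 = array(L[, 3], dm3), adc = array(adc, dm3),
                 fa = array(fa, dm3), valid = array(valid, dm3),
                 n_negative_eigenvalues = sum(L[valid, ] < 0)),
            class = "dti_metrics")
}

#' ROI means of the DTI metrics over the largest slices
#'
#' @param metrics a [tensor_metrics()] result.
#' @param roi logical 3D array.
#' @param n_slices number of largest slices averaged (3 by convention).
#' @return named numeric vector: lambda1, lambda2, lambda3, adc, fa.
#' @export
roi_mean_metrics <- function(metrics, roi, n_slices = 3L) {
  stopifnot(inherits(metrics, "dti_metrics"))
  if (!any(roi)) stopf("empty ROI")
  sl <- largest_slices(roi, n_slices)
  keep <- array(FALSE, dim(roi)); keep[, , sl] <- TRUE
  m <- roi & keep & metrics$valid
  if (!any(m)) stopf("no valid tensor voxels in ROI on the selected slices")
  c(lambda1 = mean(metrics$lambda1[m]), lambda2 = mean(metrics$lambda2[m]),
    lambda3 = mean(metrics$lambda3[m]), adc = mean(metrics$adc[m]),
    fa = mean(metrics$fa[m]))
}
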