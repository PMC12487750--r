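# Independent brute-force oracle for the mean recovery of a blurred sphere:
# paints the sphere indicator on a fine grid, convolves with a sampled
# Gaussian (separable shift-sum), optionally applies the reconstruction
# voxel aperture (box average), and takes the mean over fine-grid points
# inside the sphere. Shares no code with the package implementation.
brute_sphere_mean_rc <- function(diameter_mm, fwhm_mm, h = 0.5,
                                 voxel_box_mm = NULL) {
  R <- diameter_mm / 2
  sig <- fwhm_mm / 2.3548
  half <- R + 5 * sig + 2 + (if (is.null(voxel_box_mm)) 0 else voxel_box_mm)
  x <- seq(-half, half, by = h)
  n <- length(x)
  d2 <- outer(x^2, x^2, "+")
  A <- array(0, c(n, n, n))
  for (iz in seq_len(n)) A[, , iz] <- (d2 + x[iz]^2) < R^2
  shift_conv <- function(A, k, kr) {
    for (ax in 1:3) {
      out <- array(0, dim(A))
      for (j in seq_along(k)) {
        s <- j - kr - 1
        dst <- max(1, 1 - s):min(n, n - s)
        src <- dst + s
        if (ax == 1) out[dst, , ] <- out[dst, , ] + k[j] * A[src, , ]
        else if (ax == 2) out[, dst, ] <- out[, dst, ] + k[j] * A[, src, ]
        else out[, , dst] <- out[, , dst] + k[j] * A[, , src]
      }
      A <- out
    }
    A
  }
  if (sig > 0) {
    kr <- ceiling(4 * sig / h)
    k <- dnorm(seq(-kr, kr) * h, sd = sig)
    A <- shift_conv(A, k / sum(k), kr)
  }
  if (!is.null(voxel_box_mm)) {
    # symmetric sampled box of full width voxel_box_mm
    kr <- ceiling(voxel_box_mm / 2 / h)
    u <- seq(-kr, kr) * h
    k <- pmin(voxel_box_mm / 2 + h / 2, pmin(u + h / 2, voxel_box_mm / 2)) -
         pmax(-voxel_box_mm / 2, u - h / 2)
    k <- pmax(k, 0)
    A <- shift_conv(A, k / sum(k), kr)
  }
  inside <- array(FALSE, c(n, n, n))
  for (iz in seq_len(n)) inside[, , iz] <- (d2 + x[iz]^2) < R^2
  mean(A[inside])
}
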