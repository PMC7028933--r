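# Star-convex 3D tumor phantoms: a sphere of matched volume perturbed by
# band-limited spherical-harmonic radial noise (degrees 2..6), voxelized on
# an isotropic grid, with a correlated Gaussian intensity texture inside
# the mask. The irregularity amplitude controls surface roughness and
# hence the volume-to-surface ratio at fixed volume.

# real spherical-harmonic radial field S(theta, phi) on a lat-long grid,
# normalized to zero mean and unit sd under the area weights sin(theta)
sh_radial_field <- function(n_theta = 48, n_phi = 96, l_max = 6) {
  theta <- (seq_len(n_theta) - 0.5) * pi / n_theta
  phi <- (seq_len(n_phi) - 1) * 2 * pi / n_phi
  ct <- cos(theta)
  s <- matrix(0, n_theta, n_phi)
  for (l in 2:l_max) {
    P <- pracma::legendre(l, ct) # (l+1) x n_theta, rows m = 0..l
    for (m in 0:l) {
      a <- rnorm(1); b <- if (m > 0) rnorm(1) else 0
      # descending normalization keeps the spectrum band-limited but flat-ish
      norm <- sqrt((2 * l + 1) / (4 * pi)) /
        sqrt(prod(pmax(1, (l - m + 1):(l + m))))
      basis <- P[m + 1, ]
      ang <- if (m > 0) {
        outer(basis, a * cos(m * phi) + b * sin(m * phi))
      } else {
        outer(basis, rep(a, n_phi))
      }
      s <- s + norm * ang
    }
  }
  w <- matrix(sin(theta), n_theta, n_phi)
  mu <- sum(s * w) / sum(w)
  sdv <- sqrt(sum((s - mu)^2 * w) / sum(w))
  if (sdv == 0) sdv <- 1
  list(field = (s - mu) / sdv, theta = theta, phi = phi)
}

# separable Gaussian smoothing of a 3D array (circular boundaries)
smooth_field_3d <- function(x, sigma_vox) {
  if (sigma_vox <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma_vox))
  kern <- exp(-0.5 * ((-half):half / sigma_vox)^2)
  kern <- kern / sum(kern)
  array(.conv3d_sep_cpp(as.numeric(x), dim(x), kern), dim(x))
}

#' Render a star-convex tumor phantom
#'
#' A sphere of the requested volume is perturbed by band-limited
#' spherical-harmonic radial noise (relative amplitude `irregularity`) and
#' voxelized; the base radius is rescaled from the angular quadrature of
#' the perturbed boundary so the realized voxel volume matches the request
#' to within ~3% (voxelization residual only). The intensity field is
#' `base + amplitude * G` inside the mask, where G is a unit-variance
#' Gaussian field with the given correlation length; the background is a
#' flat darker level (the extractor only reads masked voxels).
#'
#' @param volume Target lesion volume, mm^3.
#' @param irregularity Relative amplitude of the radial perturbation
#'   (0 = perfect sphere; about 0.25 is strongly lobulated).
#' @param texture_corr Intensity correlation length, mm.
#' @param seed Integer seed (deterministic output).
#' @param spacing Isotropic voxel size, mm (default 0.1).
#' @param dim Grid size per axis (default 64).
#' @param base,amplitude Mean and sd of the lesion intensity.
#' @return A [labeled_volume()].
#' @export
render_phantom <- function(volume, irregularity = 0, texture_corr = 0.3,
                           seed = 1L, spacing = c(0.1, 0.1, 0.1),
                           dim = c(64, 64, 64), base = 100, amplitude = 15) {
  stopifnot(volume > 0, irregularity >= 0, length(spacing) == 3,
            length(dim) == 3)
  if (volume < prod(spacing)) {
    stop("requested volume is below one voxel", call. = FALSE)
  }
  set.seed(seed)
  sh <- sh_radial_field()
  shape <- 1 + irregularity * sh$field
  shape <- pmax(shape, 0.15) # keep the blob star-convex and nonempty
  # quadrature of the enclosed volume for a unit base radius:
  # V = (1/3) * Int shape^3 dOmega
  w <- sin(sh$theta)
  dphi <- 2 * pi / length(sh$phi)
  dtheta <- pi / length(sh$theta)
  v_unit <- sum(shape^3 * w) * dphi * dtheta / 3
  r0 <- (volume / v_unit)^(1 / 3)

  ctr <- (dim + 1) / 2
  r_max <- r0 * max(shape)
  if (any(r_max > (dim / 2 - 2) * spacing)) {
    stop("phantom does not fit the grid (volume or irregularity too large)",
         call. = FALSE)
  }
  half <- ceiling(r_max / spacing) + 1
  rng <- lapply(1:3, function(a) {
    seq(max(1, floor(ctr[a] - half[a])), min(dim[a], ceiling(ctr[a] + half[a])))
  })
  gx <- (rng[[1]] - ctr[1]) * spacing[1]
  gy <- (rng[[2]] - ctr[2]) * spacing[2]
  gz <- (rng[[3]] - ctr[3]) * spacing[3]
  gg <- expand.grid(x = gx, y = gy, z = gz)
  rho <- sqrt(gg$x^2 + gg$y^2 + gg$z^2)
  theta <- acos(pmin(1, pmax(-1, ifelse(rho > 0, gg$z / pmax(rho, 1e-12), 1))))
  phi <- atan2(gg$y, gg$x) %% (2 * pi)
  ti <- pmin(length(sh$theta), pmax(1, round(theta / dtheta + 0.5)))
  pj <- pmin(length(sh$phi), pmax(1, round(phi / dphi + 1)))
  r_dir <- r0 * shape[cbind(ti, pj)]
  inside <- rho <= r_dir

  mask <- array(FALSE, dim)
  sub <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  mask[sub[inside, , drop = FALSE]] <- TRUE

  # correlated intensity texture inside, darker noisy background outside
  nb <- vapply(rng, length, integer(1))
  noise <- array(rnorm(prod(nb)), nb)
  noise <- smooth_field_3d(noise, texture_corr / mean(spacing))
  noise <- (noise - mean(noise)) / max(sd(noise), 1e-12)
  img <- array(0.4 * base, dim) # flat background; only the lesion is textured
  vals <- base + amplitude * as.numeric(noise)
  img[sub[inside, , drop = FALSE]] <- vals[inside]

  labeled_volume(img, mask, spacing)
}
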