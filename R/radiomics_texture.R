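# Texture features (200): gray-level co-occurrence statistics at voxel
# distances 1 and 2 and run-length statistics, each over the 13 unique 3D
# directions and 4 fixed bin counts (8/16/32/64). Discretization is fixed
# bin count over the masked intensity range; statistics are computed per
# direction and averaged (unweighted) across directions.

tex_offsets <- function(distance = 1L) {
  o <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- apply(o, 1, function(v) {
    if (all(v == 0)) return(FALSE)
    # one representative per +/- pair: first nonzero component positive
    nz <- v[v != 0]
    nz[1] > 0
  })
  o[keep, , drop = FALSE] * as.integer(distance)
}

discretize_mask <- function(lv, nbins, crop = FALSE) {
  x <- lv$intensities[lv$mask]
  rng <- range(x)
  lab <- array(0L, dim(lv$mask))
  if (rng[1] == rng[2]) {
    lab[lv$mask] <- 1L
  } else {
    lab[lv$mask] <- pmin(nbins, floor(nbins * (x - rng[1]) /
                                        (rng[2] - rng[1])) + 1L)
  }
  if (crop) {
    idx <- which(lv$mask)
    d <- dim(lab)
    ai <- arrayInd(idx, d)
    lo <- apply(ai, 2, min)
    hi <- apply(ai, 2, max)
    lab <- lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  }
  lab
}

# degenerate closed forms for a single-gray-level region: contrast and all
# spread measures 0, homogeneity-type measures 1, correlation defined as 1
glcm_stat_vector <- function(P, stats_wanted) {
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(i * P); muy <- sum(j * P)
  sx <- sqrt(sum((i - mux)^2 * P)); sy <- sqrt(sum((j - muy)^2 * P))
  nz <- P[P > 0]
  ent <- -sum(nz * log2(nz))
  k_sum <- 2:(2 * ng)
  p_sum <- vapply(k_sum, function(k) sum(P[(i + j) == k]), numeric(1))
  k_diff <- 0:(ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), numeric(1))
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  pxy <- outer(px, py)
  hxy1 <- -sum(P[pxy > 0] * log2(pxy[pxy > 0]))
  hxy2 <- -sum(pxy[pxy > 0] * log2(pxy[pxy > 0]))
  da <- sum(k_diff * p_diff)
  all_stats <- c(
    autocorrelation = sum(i * j * P),
    joint_average = mux,
    cluster_prominence = sum((i + j - mux - muy)^4 * P),
    cluster_shade = sum((i + j - mux - muy)^3 * P),
    cluster_tendency = sum((i + j - mux - muy)^2 * P),
    contrast = sum((i - j)^2 * P),
    correlation = if (sx > 0 && sy > 0)
      (sum(i * j * P) - mux * muy) / (sx * sy) else 1,
    difference_average = da,
    difference_entropy = -sum(p_diff[p_diff > 0] * log2(p_diff[p_diff > 0])),
    difference_variance = sum((k_diff - da)^2 * p_diff),
    joint_energy = sum(P^2),
    joint_entropy = ent,
    imc1 = if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0,
    imc2 = sqrt(pmax(0, 1 - exp(-2 * (hxy2 - ent)))),
    idm = sum(P / (1 + (i - j)^2)),
    idmn = sum(P / (1 + ((i - j) / ng)^2)),
    id = sum(P / (1 + abs(i - j))),
    idn = sum(P / (1 + abs(i - j) / ng)),
    inverse_variance = sum(P[i != j] / (i[i != j] - j[i != j])^2),
    max_probability = max(P),
    sum_average = sum(k_sum * p_sum),
    sum_entropy = -sum(p_sum[p_sum > 0] * log2(p_sum[p_sum > 0])),
    sum_squares = sum((i - mux)^2 * P),
    dissimilarity = sum(abs(i - j) * P)
  )
  all_stats[stats_wanted]
}

glrlm_stat_vector <- function(M) {
  ns <- sum(M)
  if (ns == 0) {
    return(setNames(rep(0, length(glrlm_stats)), glrlm_stats))
  }
  p <- M / ns
  g <- seq_len(nrow(M)); l <- seq_len(ncol(M))
  pg <- rowSums(p); pl <- colSums(p)
  n_vox <- sum(M %*% l) # runs weighted by length = voxel count
  mug <- sum(g * pg); mul <- sum(l * pl)
  nzp <- p[p > 0]
  c(
    sre = sum(pl / l^2),
    lre = sum(pl * l^2),
    gln = sum(rowSums(M)^2) / ns,
    glnn = sum(pg^2),
    rln = sum(colSums(M)^2) / ns,
    rlnn = sum(pl^2),
    rp = ns / n_vox,
    glv = sum((g - mug)^2 * pg),
    rlv = sum((l - mul)^2 * pl),
    run_entropy = -sum(nzp * log2(nzp)),
    lglre = sum(pg / g^2),
    hglre = sum(pg * g^2),
    srlgle = sum(sweep(sweep(p, 1, g^2, `/`), 2, l^2, `/`)),
    srhgle = sum(sweep(sweep(p, 1, g^2, `*`), 2, l^2, `/`)),
    lrlgle = sum(sweep(sweep(p, 1, g^2, `/`), 2, l^2, `*`)),
    lrhgle = sum(sweep(sweep(p, 1, g^2, `*`), 2, l^2, `*`))
  )
}

#' Texture radiomic features (200)
#'
#' Gray-level co-occurrence (GLCM) statistics at voxel distance 1 (24
#' statistics) and distance 2 (10 statistics) plus run-length (GLRLM)
#' statistics (16), each computed per direction over the 13 unique 3D
#' offsets, averaged across directions, at 4 fixed bin counts (8/16/32/64).
#' A single-gray-level lesion takes the degenerate closed forms (contrast
#' 0, homogeneity 1, correlation 1).
#'
#' @param lv A [labeled_volume()].
#' @return One-row tibble with 200 columns prefixed `tex.`.
#' @export
extract_texture <- function(lv) {
  check_nonempty(lv)
  offs1 <- tex_offsets(1L)
  offs2 <- tex_offsets(2L)
  out <- numeric(0)
  d2_sel <- match(glcm_stats_d2, glcm_stats_d1)
  # crop to the lesion bounding box once; texture only sees masked voxels
  idx <- which(lv$mask)
  ai <- arrayInd(idx, dim(lv$mask))
  lo <- apply(ai, 2, min)
  hi <- apply(ai, 2, max)
  sub <- list(
    intensities = lv$intensities[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3],
                                 drop = FALSE],
    mask = lv$mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  )
  for (nb in tex_bins) {
    lab <- discretize_mask(sub, nb)
    dims <- dim(lab)
    maxrun <- max(dims)
    s1 <- rowMeans(.glcm_stats_cpp(lab, dims, nb, offs1))
    names(s1) <- sprintf("glcm_d1_b%d_%s", nb, glcm_stats_d1)
    s2 <- rowMeans(.glcm_stats_cpp(lab, dims, nb, offs2))[d2_sel]
    names(s2) <- sprintf("glcm_d2_b%d_%s", nb, glcm_stats_d2)
    s3 <- rowMeans(.glrlm_stats_cpp(lab, dims, nb, offs1, maxrun))
    names(s3) <- sprintf("glrlm_b%d_%s", nb, glrlm_stats)
    out <- c(out, s1, s2, s3)
  }
  names(out) <- paste0("tex.", names(out))
  stopifnot(length(out) == 200, all(is.finite(out)))
  row_tibble(out)
}
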