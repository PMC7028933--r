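# First-order (intensity-distribution) features over the masked voxels.
# 20 base statistics + a 41-point percentile grid (linear interpolation,
# type 7) + 17 histogram statistics at 5 fixed bin counts = 146 features.
# Degenerate conventions: a constant intensity field has entropy 0 and all
# dispersion statistics 0; skewness/kurtosis of a constant field are 0.

fo_skewness <- function(x) {
  s <- sd(x)
  if (is.na(s) || s == 0) return(0)
  n <- length(x)
  mean((x - mean(x))^3) / (s * sqrt((n - 1) / n))^3
}

fo_kurtosis <- function(x) {
  s <- sd(x)
  if (is.na(s) || s == 0) return(0)
  n <- length(x)
  mean((x - mean(x))^4) / (s * sqrt((n - 1) / n))^4 - 3
}

fo_histogram_stats <- function(x, nbins) {
  rng <- range(x)
  if (rng[1] == rng[2]) {
    p <- c(1, rep(0, nbins - 1))
    centers <- rep(rng[1], nbins)
  } else {
    idx <- pmin(nbins, floor(nbins * (x - rng[1]) / (rng[2] - rng[1])) + 1L)
    p <- tabulate(idx, nbins) / length(x)
    centers <- rng[1] + (seq_len(nbins) - 0.5) * (rng[2] - rng[1]) / nbins
  }
  nz <- p[p > 0]
  wmean <- sum(p * centers)
  wvar <- sum(p * (centers - wmean)^2)
  wsd <- sqrt(wvar)
  cum <- cumsum(p)
  wq <- function(q) centers[which(cum >= q)[1]]
  ord <- sort(p, decreasing = TRUE)
  gini <- sum(cumsum(sort(p)))  # concentration of the probability mass
  out <- c(
    entropy = -sum(nz * log2(nz)),
    entropy_norm = if (nbins > 1) -sum(nz * log2(nz)) / log2(nbins) else 0,
    uniformity = sum(p^2),
    max_prob = max(p),
    min_prob_nonzero = min(nz),
    n_nonempty = sum(p > 0),
    frac_nonempty = mean(p > 0),
    gini = gini,
    renyi2 = -log2(sum(p^2)),
    mode_center = centers[which.max(p)],
    wmean = wmean,
    wsd = wsd,
    wskew = if (wsd > 0) sum(p * (centers - wmean)^3) / wsd^3 else 0,
    wkurt = if (wsd > 0) sum(p * (centers - wmean)^4) / wsd^4 - 3 else 0,
    wmedian = wq(0.5),
    wiqr = wq(0.75) - wq(0.25),
    tail_high_frac = sum(p[centers >= rng[1] + 0.9 * (rng[2] - rng[1])])
  )
  names(out) <- sprintf("hist%d_%s", nbins, fo_hist_stats)
  out
}

#' First-order radiomic features (146)
#'
#' Intensity-distribution statistics over the masked voxels: 20 base
#' statistics (moments, order statistics, energies), percentiles on a 0-100
#' grid in steps of 2.5 (linear-interpolation convention), and 17 histogram
#' statistics at bin counts 8/16/32/64/128. `total_energy` scales the sum of
#' squared intensities by the voxel volume; `volume_ml` is the masked volume
#' in millilitres.
#'
#' @param lv A [labeled_volume()].
#' @return One-row tibble with 146 columns prefixed `fo.`.
#' @export
extract_first_order <- function(lv) {
  check_nonempty(lv)
  x <- lv$intensities[lv$mask]
  voxvol <- prod(lv$spacing)
  q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  base <- c(
    mean = mean(x), median = median(x), sd = sd(x), variance = var(x),
    skewness = fo_skewness(x), kurtosis = fo_kurtosis(x),
    min = min(x), max = max(x), range = max(x) - min(x),
    q1 = q[1], q3 = q[2], iqr = q[2] - q[1],
    mad = mean(abs(x - mean(x))), medad = median(abs(x - median(x))),
    rms = sqrt(mean(x^2)), energy = sum(x^2),
    total_energy = sum(x^2) * voxvol, cv = if (mean(x) != 0) sd(x) / mean(x) else 0,
    n_voxels = length(x), volume_ml = length(x) * voxvol / 1000
  )
  if (length(x) == 1) { # sd/var undefined for a single voxel: define as 0
    base[c("sd", "variance", "cv")] <- 0
  }
  pct <- quantile(x, fo_percentiles / 100, names = FALSE, type = 7)
  names(pct) <- sprintf("p%05.1f", fo_percentiles)
  hist_feats <- unlist(lapply(fo_bins, function(b) fo_histogram_stats(x, b)))
  out <- c(base, pct, hist_feats)
  names(out) <- paste0("fo.", names(out))
  stopifnot(length(out) == 146, all(is.finite(out)))
  row_tibble(out)
}
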