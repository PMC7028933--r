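# Curvature features (44): per-vertex principal curvatures k1 >= k2, mean
# curvature H = (k1 + k2) / 2 and Gaussian curvature K = k1 * k2 on the
# Taubin-smoothed boundary mesh, summarized by 11 statistics per field.
# Units: mm^-1 for k1/k2/H, mm^-2 for K.

curv_summary <- function(x, prefix) {
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  out <- c(
    mean = mean(x),
    sd = if (length(x) > 1) sd(x) else 0,
    min = min(x),
    max = max(x),
    median = q[2],
    q1 = q[1],
    q3 = q[3],
    skewness = fo_skewness(x),
    kurtosis = fo_kurtosis(x),
    range = max(x) - min(x),
    energy = mean(x^2)
  )
  names(out) <- sprintf("%s_%s", prefix, curv_stats)
  out
}

#' Curvature radiomic features (44)
#'
#' Discrete principal, mean and Gaussian curvatures on the smoothed
#' triangulated lesion boundary (see [mesh_curvature()]), each summarized by
#' 11 statistics (mean, sd, min, max, median, quartiles, skewness,
#' kurtosis, range, energy = mean square). For a sphere of radius r the mean
#' of the mean-curvature field approaches 1/r and the mean Gaussian
#' curvature 1/r^2.
#'
#' @param lv A [labeled_volume()].
#' @param mesh Optional precomputed [mask_mesh()] of `lv$mask` (reused by
#'   [extract_features()] to avoid meshing twice).
#' @return One-row tibble with 44 columns prefixed `curv.`.
#' @export
extract_curvature <- function(lv, mesh = NULL) {
  check_nonempty(lv)
  if (is.null(mesh)) mesh <- mask_mesh(lv$mask, lv$spacing)
  curv <- mesh_curvature(mesh)
  out <- c(curv_summary(curv$k1, "k1"),
           curv_summary(curv$k2, "k2"),
           curv_summary(curv$mean, "mean"),
           curv_summary(curv$gaussian, "gaussian"))
  names(out) <- paste0("curv.", names(out))
  stopifnot(length(out) == 44, all(is.finite(out)))
  row_tibble(out)
}
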