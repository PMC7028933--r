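#' Labeled 3D volume (intensity image + lesion mask + voxel spacing)
#'
#' @param intensities 3D numeric array of image intensities (arbitrary MR
#'   units).
#' @param mask 3D array of the same shape; nonzero = lesion.
#' @param spacing Physical voxel size per axis in mm (length 3, positive).
#' @return Object of class `labeled_volume`.
#' @export
labeled_volume <- function(intensities, mask, spacing = c(1, 1, 1)) {
  stopifnot(length(dim(intensities)) == 3)
  if (!identical(dim(intensities), dim(mask))) {
    stop("intensity and mask shapes differ", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be 3 positive numbers", call. = FALSE)
  }
  if (any(!is.finite(intensities))) {
    stop("intensities must be finite", call. = FALSE)
  }
  structure(list(intensities = intensities, mask = array(mask != 0, dim(mask)),
                 spacing = spacing),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat(sprintf("<labeled_volume> %s grid, %.3g x %.3g x %.3g mm voxels, %d lesion voxels\n",
              paste(dim(x$mask), collapse = "x"),
              x$spacing[1], x$spacing[2], x$spacing[3], sum(x$mask)))
  invisible(x)
}

check_nonempty <- function(lv) {
  if (!inherits(lv, "labeled_volume")) stop("need a labeled_volume", call. = FALSE)
  if (sum(lv$mask) == 0) stop("empty lesion mask", call. = FALSE)
  invisible(lv)
}

# ---------------------------------------------------------------------------
# roster bookkeeping: the frozen feature contract is 146 first-order,
# 33 shape, 200 texture and 44 curvature features (423 in total)

fo_hist_stats <- c("entropy", "entropy_norm", "uniformity", "max_prob",
                   "min_prob_nonzero", "n_nonempty", "frac_nonempty", "gini",
                   "renyi2", "mode_center", "wmean", "wsd", "wskew", "wkurt",
                   "wmedian", "wiqr", "tail_high_frac")
fo_bins <- c(8, 16, 32, 64, 128)
fo_base_stats <- c("mean", "median", "sd", "variance", "skewness", "kurtosis",
                   "min", "max", "range", "q1", "q3", "iqr", "mad", "medad",
                   "rms", "energy", "total_energy", "cv", "n_voxels",
                   "volume_ml")
fo_percentiles <- seq(0, 100, by = 2.5)

shape_names <- c("volume_voxel", "volume_mesh", "surface_area",
                 "surface_to_volume_ratio", "volume_to_surface_ratio",
                 "sphericity", "compactness1", "compactness2",
                 "spherical_disproportion", "equivalent_sphere_radius",
                 "equivalent_sphere_diameter", "max_3d_diameter",
                 "max_2d_diameter_axial", "max_2d_diameter_coronal",
                 "max_2d_diameter_sagittal", "pca_major_axis",
                 "pca_minor_axis", "pca_least_axis", "elongation", "flatness",
                 "bbox_extent_x", "bbox_extent_y", "bbox_extent_z",
                 "bbox_volume", "extent_fraction", "bidimensional_product",
                 "radial_mean", "radial_sd", "radial_max", "radial_min",
                 "radial_cv", "mesh_voxel_volume_ratio", "least_major_ratio")

glcm_stats_d1 <- c("autocorrelation", "joint_average", "cluster_prominence",
                   "cluster_shade", "cluster_tendency", "contrast",
                   "correlation", "difference_average", "difference_entropy",
                   "difference_variance", "joint_energy", "joint_entropy",
                   "imc1", "imc2", "idm", "idmn", "id", "idn",
                   "inverse_variance", "max_probability", "sum_average",
                   "sum_entropy", "sum_squares", "dissimilarity")
glcm_stats_d2 <- c("contrast", "correlation", "joint_entropy", "joint_energy",
                   "id", "idm", "cluster_shade", "cluster_tendency",
                   "max_probability", "dissimilarity")
glrlm_stats <- c("sre", "lre", "gln", "glnn", "rln", "rlnn", "rp", "glv",
                 "rlv", "run_entropy", "lglre", "hglre", "srlgle", "srhgle",
                 "lrlgle", "lrhgle")
tex_bins <- c(8, 16, 32, 64)

curv_fields <- c("k1", "k2", "mean", "gaussian")
curv_stats <- c("mean", "sd", "min", "max", "median", "q1", "q3", "skewness",
                "kurtosis", "range", "energy")

#' The frozen radiomic feature roster
#'
#' Names and categories of the 423 features emitted by [extract_features()]:
#' 146 first-order, 33 shape, 200 texture and 44 curvature features. Names
#' are prefixed by category (`fo.`, `shape.`, `tex.`, `curv.`) and are
#' stable across runs; the roster version is hashed into the attribute
#' `roster_version`.
#'
#' @return Tibble with columns `name` and `category`.
#' @export
feature_roster <- function() {
  fo <- c(fo_base_stats,
          sprintf("p%05.1f", fo_percentiles),
          as.vector(outer(fo_hist_stats, fo_bins,
                          function(s, b) sprintf("hist%d_%s", b, s))))
  tex <- unlist(lapply(tex_bins, function(b) {
    c(sprintf("glcm_d1_b%d_%s", b, glcm_stats_d1),
      sprintf("glcm_d2_b%d_%s", b, glcm_stats_d2),
      sprintf("glrlm_b%d_%s", b, glrlm_stats))
  }))
  curv <- as.vector(outer(curv_stats, curv_fields,
                          function(s, f) sprintf("%s_%s", f, s)))
  out <- tibble::tibble(
    name = c(paste0("fo.", fo), paste0("shape.", shape_names),
             paste0("tex.", tex), paste0("curv.", curv)),
    category = rep(c("first_order", "shape", "texture", "curvature"),
                   times = c(length(fo), length(shape_names), length(tex),
                             length(curv)))
  )
  stopifnot(!anyDuplicated(out$name), nrow(out) == 423)
  attr(out, "roster_version") <- sprintf("icbmri-roster-1/%d", nrow(out))
  out
}

row_tibble <- function(x) {
  tibble::as_tibble(as.list(x))
}

#' Extract the full 423-feature radiomic vector
#'
#' Concatenates the four category extractors in roster order:
#' [extract_first_order()] (146), [extract_shape()] (33),
#' [extract_texture()] (200) and [extract_curvature()] (44). Deterministic
#' given the input; all values are finite.
#'
#' @param lv A [labeled_volume()].
#' @return One-row tibble with 423 named columns.
#' @export
extract_features <- function(lv) {
  check_nonempty(lv)
  # crop to the lesion bounding box once; every feature is invariant to
  # translation and background padding
  idx <- which(lv$mask)
  ai <- arrayInd(idx, dim(lv$mask))
  lo <- apply(ai, 2, min)
  hi <- apply(ai, 2, max)
  lvc <- structure(list(
    intensities = lv$intensities[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3],
                                 drop = FALSE],
    mask = lv$mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
    spacing = lv$spacing), class = "labeled_volume")
  mesh <- mask_mesh(lvc$mask, lvc$spacing)
  out <- c(unlist(extract_first_order(lvc)),
           unlist(extract_shape(lvc, mesh)),
           unlist(extract_texture(lvc)),
           unlist(extract_curvature(lvc, mesh)))
  stopifnot(length(out) == 423)
  row_tibble(out)
}

#' Absolute longitudinal feature differences
#'
#' Element-wise `|f2 - f1|` between two feature rows extracted with the same
#' roster; output names are prefixed with `delta_`. The sign is discarded:
#' only the magnitude of the change between the two scans enters the model.
#'
#' @param f1,f2 One-row tibbles (or equal-length named numeric vectors) with
#'   identical names.
#' @return One-row tibble of absolute differences.
#' @export
delta_features <- function(f1, f2) {
  v1 <- unlist(f1); v2 <- unlist(f2)
  if (!identical(names(v1), names(v2))) {
    stop("feature rosters differ between the two time points", call. = FALSE)
  }
  out <- abs(v2 - v1)
  names(out) <- paste0("delta_", names(out))
  row_tibble(out)
}

#' Z-score normalization of a feature table
#'
#' Transforms every feature column to mean 0 and sample standard deviation 1
#' (denominator n - 1). Zero-variance columns map to 0 and are flagged. The
#' fitted per-column means and standard deviations are stored so the same
#' transformation can be applied to held-out rows
#' ([apply_normalization()]) or inverted ([denormalize()]).
#'
#' @param table Data frame; non-numeric columns (e.g. `animal_id`) pass
#'   through untouched.
#' @param state Normalization state from a previous fit (then applied as-is).
#' @return Tibble with attribute `norm_state` (tibble: `column`, `mean`,
#'   `sd`, `constant`).
#' @export
zscore_normalize <- function(table, state = NULL) {
  stopifnot(is.data.frame(table))
  num <- vapply(table, is.numeric, logical(1))
  if (is.null(state)) {
    if (nrow(table) < 2) stop("need >= 2 rows to fit normalization", call. = FALSE)
    cols <- names(table)[num]
    mu <- unname(vapply(table[cols], mean, numeric(1)))
    sdv <- unname(vapply(table[cols], sd, numeric(1)))
    state <- tibble::tibble(column = cols, mean = mu, sd = sdv,
                            constant = sdv == 0)
  }
  out <- apply_normalization(table, state)
  attr(out, "norm_state") <- state
  out
}

#' @rdname zscore_normalize
#' @export
apply_normalization <- function(table, state) {
  out <- tibble::as_tibble(table)
  for (i in seq_len(nrow(state))) {
    cl <- state$column[i]
    if (!cl %in% names(out)) stop("column ", cl, " missing", call. = FALSE)
    if (state$constant[i]) {
      out[[cl]] <- rep(0, nrow(out))
    } else {
      out[[cl]] <- (out[[cl]] - state$mean[i]) / state$sd[i]
    }
  }
  attr(out, "norm_state") <- state
  out
}

#' @rdname zscore_normalize
#' @export
denormalize <- function(table, state = attr(table, "norm_state")) {
  if (is.null(state)) stop("no normalization state", call. = FALSE)
  out <- tibble::as_tibble(table)
  for (i in seq_len(nrow(state))) {
    cl <- state$column[i]
    if (state$constant[i]) {
      out[[cl]] <- rep(state$mean[i], nrow(out))
    } else {
      out[[cl]] <- out[[cl]] * state$sd[i] + state$mean[i]
    }
  }
  attr(out, "norm_state") <- NULL
  out
}
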