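# Seeded synthetic cohorts: volume trajectories + 3-time-point phantoms
# with an injectable radiomic signal. The signal enters through surface
# irregularity: from MRI1 to MRI2 responders' lesions get smoother by
# `delta` and non-responders' rougher by `delta`, so the shift in the
# volume-to-surface ratio (and related shape/curvature features) carries
# the label, while the volumes themselves do not.

#' Specification of a synthetic cohort
#'
#' @param n_animals Number of animals.
#' @param responder_rate Target responder fraction in the ICB arm
#'   (default 0.476).
#' @param archetype_mix_r Mix of pseudoprogressors (G2) vs direct
#'   responders (G1) among responders, as c(G2, G1) (default 78:22... the
#'   observed 78:20 of 98 classifiable responders, normalized).
#' @param archetype_mix_nr Mix of progressors (G3) vs late progressors (G4)
#'   among non-responders; mirrors the responder mix by default so the
#'   MRI1/MRI2 growth dynamics are label-free.
#' @param delta Irregularity shift between MRI1 and MRI2 (responders
#'   smoother by `delta`, non-responders rougher; 0 = no image signal).
#' @param irregularity_mean,irregularity_sd Baseline surface irregularity.
#' @param irregularity_noise Label-independent jitter of the MRI2
#'   irregularity.
#' @param texture_corr Intensity correlation length, mm.
#' @param spacing,dim Phantom grid geometry (defaults 0.1 mm, 64^3).
#' @param arm_mix Named arm proportions (default all ICB).
#' @param control_responder_rate Responder rate in the control arm.
#' @param seed Integer seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_animals = 150, responder_rate = 0.476,
                        archetype_mix_r = c(G2 = 0.796, G1 = 0.204),
                        archetype_mix_nr = c(G3 = 0.796, G4 = 0.204),
                        delta = 0.08, irregularity_mean = 0.15,
                        irregularity_sd = 0.03, irregularity_noise = 0.015,
                        texture_corr = 0.3, spacing = c(0.1, 0.1, 0.1),
                        dim = c(64, 64, 64), arm_mix = c(ICB = 1),
                        control_responder_rate = 0.0548, seed = 1L) {
  stopifnot(n_animals >= 1, responder_rate >= 0, responder_rate <= 1,
            delta >= 0, abs(sum(arm_mix) - 1) < 1e-8,
            abs(sum(archetype_mix_r) - 1) < 1e-8,
            abs(sum(archetype_mix_nr) - 1) < 1e-8)
  structure(list(
    n_animals = as.integer(n_animals), responder_rate = responder_rate,
    archetype_mix_r = archetype_mix_r, archetype_mix_nr = archetype_mix_nr,
    delta = delta, irregularity_mean = irregularity_mean,
    irregularity_sd = irregularity_sd,
    irregularity_noise = irregularity_noise, texture_corr = texture_corr,
    spacing = spacing, dim = dim, arm_mix = arm_mix,
    control_responder_rate = control_responder_rate, seed = as.integer(seed)
  ), class = "cohort_spec")
}

animal_seed <- function(seed, i, salt = 0L) {
  as.integer((as.numeric(seed) * 7919 + i * 104729 + salt * 15485863) %%
               2147483647)
}

#' Generate a synthetic cohort
#'
#' Per animal: an arm, an archetype (responder archetypes at the target
#' responder rate), a three-point volume trajectory, and per-time-point
#' phantom parameters (irregularity carrying the injected signal). Labels
#' are the volumetric response calls recomputed from the realized volumes,
#' so re-running [classify_response()] on the returned volume table
#' reproduces them exactly. Images are rendered lazily: use
#' [cohort_feature_table()] to stream radiomic features or
#' [write_cohort()] / `outdir` to materialize NIfTI files.
#'
#' @param spec A [cohort_spec()].
#' @param outdir Optional directory; when given, [write_cohort()] is called.
#' @return Object of class `synthetic_cohort`: list with `animals` (tibble
#'   of trajectories, phantom parameters and seeds), `calls` (response
#'   calls) and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec(), outdir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_animals
  set.seed(spec$seed)
  arms <- sample(names(spec$arm_mix), n, replace = TRUE, prob = spec$arm_mix)
  rate <- ifelse(arms == "ICB", spec$responder_rate,
                 spec$control_responder_rate)
  is_resp <- runif(n) < rate
  archetype <- character(n)
  nr_r <- sum(is_resp)
  archetype[is_resp] <- sample(
    c("pseudoprogressor", "direct_responder"), nr_r, replace = TRUE,
    prob = spec$archetype_mix_r)
  archetype[!is_resp] <- sample(
    c("progressor", "late_progressor"), n - nr_r, replace = TRUE,
    prob = spec$archetype_mix_nr)

  a1 <- pmin(0.30, pmax(0.03, rnorm(n, spec$irregularity_mean,
                                    spec$irregularity_sd)))
  shift <- ifelse(is_resp, -spec$delta, +spec$delta)
  a2 <- pmin(0.35, pmax(0.02, a1 + shift + rnorm(n, 0, spec$irregularity_noise)))
  a3 <- pmin(0.35, pmax(0.02, a2 + rnorm(n, 0, spec$irregularity_noise)))

  traj <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    sample_trajectory(archetype_params(archetype[i]),
                      seed = animal_seed(spec$seed, i))
  }))

  animals <- tibble::tibble(
    animal_id = sprintf("A%03d", seq_len(n)),
    arm = arms,
    archetype = traj$archetype,
    v1 = traj$v1, v2 = traj$v2, v3 = traj$v3,
    irregularity_1 = a1, irregularity_2 = a2, irregularity_3 = a3,
    texture_corr = spec$texture_corr,
    render_seed = vapply(seq_len(n), function(i) animal_seed(spec$seed, i, 1L),
                         integer(1))
  )
  calls <- classify_response(animals[, c("animal_id", "arm", "v1", "v2", "v3")])
  out <- structure(list(animals = animals, calls = calls, spec = spec),
                   class = "synthetic_cohort")
  if (!is.null(outdir)) write_cohort(out, outdir)
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d animals, delta = %g, seed = %d\n",
              nrow(x$animals), x$spec$delta, x$spec$seed))
  print(table(x$calls$category))
  invisible(x)
}

#' Render the phantom of one animal at one time point
#'
#' @param cohort A `synthetic_cohort`.
#' @param animal Animal index or `animal_id`.
#' @param timepoint 1, 2 or 3 (MRI1/MRI2/MRI3).
#' @return A [labeled_volume()], or `NULL` for a vanished lesion (volume
#'   zero after complete response).
#' @export
cohort_phantom <- function(cohort, animal, timepoint) {
  stopifnot(inherits(cohort, "synthetic_cohort"), timepoint %in% 1:3)
  a <- cohort$animals
  i <- if (is.character(animal)) match(animal, a$animal_id) else animal
  stopifnot(!is.na(i), i >= 1, i <= nrow(a))
  vol <- a[[c("v1", "v2", "v3")[timepoint]]][i]
  if (vol <= 0) return(NULL)
  irr <- a[[paste0("irregularity_", timepoint)]][i]
  render_phantom(vol, irr, a$texture_corr[i],
                 seed = a$render_seed[i] + timepoint,
                 spacing = cohort$spec$spacing, dim = cohort$spec$dim)
}

#' Radiomic feature table of a synthetic cohort
#'
#' Streams over the animals: renders the phantom at each requested time
#' point, extracts the 423 features, and (for two time points) appends the
#' 423 absolute delta features, discarding images as it goes. The default
#' time points 1 and 2 give the 846-column baseline + delta design matrix
#' used for response prediction.
#'
#' @param cohort A `synthetic_cohort`.
#' @param timepoints Integer vector of time points (default `c(1, 2)`).
#' @param verbose Print progress every 25 animals.
#' @return Tibble: `animal_id`, `responder`, then feature columns.
#' @export
cohort_feature_table <- function(cohort, timepoints = c(1, 2),
                                 verbose = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  n <- nrow(cohort$animals)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    feats <- lapply(timepoints, function(tp) {
      lv <- cohort_phantom(cohort, i, tp)
      if (is.null(lv)) stop("cannot extract features from a vanished lesion",
                            call. = FALSE)
      extract_features(lv)
    })
    row <- feats[[1]]
    if (length(timepoints) >= 2) {
      names(row) <- paste0("t1_", names(row))
      row <- dplyr::bind_cols(row, delta_features(feats[[1]], feats[[2]]))
    }
    rows[[i]] <- row
    if (verbose && i %% 25 == 0) message("  rendered/extracted ", i, "/", n)
  }
  dplyr::bind_cols(
    tibble::tibble(animal_id = cohort$animals$animal_id,
                   responder = cohort$calls$responder),
    dplyr::bind_rows(rows)
  )
}

#' Write a synthetic cohort to disk (NIfTI + CSV + JSON)
#'
#' Writes per-animal, per-time-point image and mask NIfTI files, the volume
#' and response-call CSVs, and the spec as JSON.
#'
#' @param cohort A `synthetic_cohort`.
#' @param outdir Output directory (created if needed).
#' @param timepoints Time points to render (default `c(1, 2, 3)`; vanished
#'   lesions are skipped).
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(cohort, outdir, timepoints = c(1, 2, 3)) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$animals, file.path(outdir, "volumes.csv"),
                   row.names = FALSE)
  calls <- cohort$calls
  calls$growth_pattern <- as.character(calls$growth_pattern)
  calls$category <- as.character(calls$category)
  utils::write.csv(calls, file.path(outdir, "calls.csv"), row.names = FALSE)
  spec <- cohort$spec
  writeLines(
    paste0("{",
           sprintf('"n_animals": %d, "responder_rate": %g, "delta": %g, "seed": %d',
                   spec$n_animals, spec$responder_rate, spec$delta, spec$seed),
           "}"),
    file.path(outdir, "spec.json"))
  for (i in seq_len(nrow(cohort$animals))) {
    for (tp in timepoints) {
      lv <- cohort_phantom(cohort, i, tp)
      if (is.null(lv)) next
      id <- cohort$animals$animal_id[i]
      img <- RNifti::asNifti(lv$intensities)
      RNifti::pixdim(img) <- lv$spacing
      msk <- RNifti::asNifti(array(as.integer(lv$mask), dim(lv$mask)))
      RNifti::pixdim(msk) <- lv$spacing
      RNifti::writeNifti(img, file.path(outdir,
                                        sprintf("%s_mri%d.nii.gz", id, tp)))
      RNifti::writeNifti(msk, file.path(outdir,
                                        sprintf("%s_mri%d_mask.nii.gz", id, tp)))
    }
  }
  invisible(outdir)
}

#' Read an image + mask NIfTI pair as a labeled volume
#'
#' Voxel spacing is taken from the NIfTI header (`pixdim`).
#'
#' @param image_path,mask_path Paths to the intensity and mask images.
#' @return A [labeled_volume()].
#' @export
read_labeled_volume <- function(image_path, mask_path) {
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  labeled_volume(array(as.numeric(img), dim(img)),
                 array(as.numeric(msk) != 0, dim(msk)),
                 RNifti::pixdim(img)[1:3])
}
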