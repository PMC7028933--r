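# The seeded generators: trajectories, phantoms, cohorts, expression
# tables and repertoires.

test_that("trajectories realize their archetype's growth pattern by construction", {
  targets <- c(direct_responder = "G1", pseudoprogressor = "G2",
               progressor = "G3", late_progressor = "G4")
  for (arch in names(targets)) {
    for (seed in 1:5) {
      tr <- sample_trajectory(archetype_params(arch, cr_prob = 0), seed = seed)
      call <- classify_response(tibble::tibble(v1 = tr$v1, v2 = tr$v2,
                                               v3 = tr$v3))
      expect_equal(as.character(call$growth_pattern), unname(targets[arch]),
                   info = paste(arch, seed))
    }
  }
  # forced complete response
  tr <- sample_trajectory(archetype_params("direct_responder", cr_prob = 1),
                          seed = 2)
  expect_equal(tr$v3, 0)
  # determinism
  a <- sample_trajectory(archetype_params("pseudoprogressor"), seed = 9)
  b <- sample_trajectory(archetype_params("pseudoprogressor"), seed = 9)
  expect_identical(a, b)
})

test_that("phantoms match requested volume and degenerate to spheres", {
  lv0 <- render_phantom(2, irregularity = 0, seed = 4)
  expect_equal(sum(lv0$mask) * prod(lv0$spacing), 2, tolerance = 0.03)
  f0 <- extract_shape(render_phantom(4, irregularity = 0, seed = 4))
  expect_equal(f0$shape.sphericity, 1, tolerance = 0.05)
  # determinism
  lv0b <- render_phantom(2, irregularity = 0, seed = 4)
  expect_identical(lv0$intensities, lv0b$intensities)
  expect_error(render_phantom(0.0001), "below one voxel")
  expect_error(render_phantom(500), "does not fit")
})

test_that("irregularity monotonically lowers the volume-to-surface ratio", {
  amps <- c(0, 0.06, 0.12, 0.18, 0.24)
  vs <- vapply(amps, function(a) {
    mean(vapply(1:6, function(s) {
      lv <- render_phantom(2, a, seed = 50 + s)
      extract_shape(lv)$shape.volume_to_surface_ratio
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(vs) < 0))
})

test_that("cohort labels are reproducible from the volume table alone", {
  co <- generate_cohort(cohort_spec(n_animals = 40, seed = 13))
  again <- classify_response(co$animals[, c("animal_id", "arm", "v1", "v2",
                                            "v3")])
  expect_identical(as.character(co$calls$category),
                   as.character(again$category))
  expect_identical(co$calls$responder, again$responder)
  # determinism of the full cohort
  co2 <- generate_cohort(cohort_spec(n_animals = 40, seed = 13))
  expect_identical(co$animals, co2$animals)
})

test_that("the realized responder rate concentrates on the specified rate", {
  rates <- vapply(1:10, function(s) {
    co <- generate_cohort(cohort_spec(n_animals = 200, seed = 300 + s))
    mean(co$calls$responder)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.476), 0.05)
})

test_that("expression effects are recovered by the signature score", {
  # a true effect is detected in direction in nearly all seeds
  wins <- 0
  for (s in 1:10) {
    expr <- generate_expression(n_genes = 60, n_samples = 4,
                                effects = c(pro_inflammatory = 2,
                                            anti_inflammatory = 1),
                                seed = 400 + s)
    sets <- attr(expr, "gene_sets")
    sc <- signature_score(expr, sets$pro_inflammatory)
    r_mean <- mean(sc$score[grepl("^R", sc$sample)])
    nr_mean <- mean(sc$score[grepl("^NR", sc$sample)])
    if (r_mean > nr_mean) wins <- wins + 1
  }
  expect_gte(wins, 9)
  # no effect: group difference within the permutation null spread
  expr0 <- generate_expression(n_genes = 60, n_samples = 4, seed = 5)
  sets <- attr(expr0, "gene_sets")
  sc0 <- signature_score(expr0, sets$pro_inflammatory)
  obs <- abs(mean(sc0$score[1:4]) - mean(sc0$score[5:8]))
  perm <- replicate(200, {
    idx <- sample(8)
    abs(mean(sc0$score[idx[1:4]]) - mean(sc0$score[idx[5:8]]))
  })
  expect_lt(obs, mean(perm) + 2 * sd(perm))
})

test_that("repertoire concentration controls clonality as designed", {
  # uniform limit: top-10 share approaches 100 * min(10, R) / R
  even <- generate_repertoire(n_clones = 40, concentration = 5000,
                              total_templates = 200000, seed = 6)
  expect_equal(top_clones_share(even), 25, tolerance = 0.1)
  # low concentration gives the more clonal repertoire
  wins <- 0
  for (s in 1:10) {
    oligo <- generate_repertoire(n_clones = 50, concentration = 0.1,
                                 seed = 500 + s)
    poly <- generate_repertoire(n_clones = 50, concentration = 50,
                                seed = 500 + s)
    if (productive_clonality(oligo) > productive_clonality(poly)) {
      wins <- wins + 1
    }
  }
  expect_gte(wins, 9)
  # a planted motif across three samples is recovered
  reps <- generate_repertoire(n_clones = 30, concentration = 1,
                              n_samples = 3, shared_motif = TRUE, seed = 7)
  found <- shared_cdr3_motifs(reps)
  expect_gte(nrow(found), 1)
  expect_gte(max(found$n_samples), 2)
})

test_that("cohorts round-trip through NIfTI and CSV on disk", {
  co <- generate_cohort(cohort_spec(n_animals = 2, seed = 17))
  outdir <- file.path(tempdir(), "icbmri-cohort")
  write_cohort(co, outdir, timepoints = 1)
  vols <- utils::read.csv(file.path(outdir, "volumes.csv"))
  expect_equal(nrow(vols), 2)
  id <- co$animals$animal_id[1]
  lv <- read_labeled_volume(file.path(outdir, paste0(id, "_mri1.nii.gz")),
                            file.path(outdir, paste0(id, "_mri1_mask.nii.gz")))
  direct <- cohort_phantom(co, 1, 1)
  expect_equal(sum(lv$mask), sum(direct$mask))
  expect_equal(lv$spacing, direct$spacing, tolerance = 1e-6)
  expect_equal(max(abs(lv$intensities - direct$intensities)), 0,
               tolerance = 1e-5)
  unlink(outdir, recursive = TRUE)
})
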