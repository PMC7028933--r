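# Volumetric response classification, growth patterns, threshold
# derivation, diameter products and cohort summaries.

traj <- function(v1, v2, v3, arm = "ICB") {
  tibble::tibble(animal_id = "A", arm = arm, v1 = v1, v2 = v2, v3 = v3)
}

test_that("relative_change follows the percent-change formula and guards", {
  expect_equal(relative_change(10, 0), -100)
  expect_equal(relative_change(10, 10), 0)
  expect_equal(relative_change(10, 14), 40)
  expect_equal(relative_change(c(10, 20), c(5, 30)), c(-50, 50))
  expect_error(relative_change(0, 5), "baseline")
  expect_error(relative_change(10, Inf), "finite")
})

test_that("classify_response reproduces the category definitions", {
  cases <- list(
    list(v = c(10, 12, 0), cat = "CR", resp = TRUE, rescued = FALSE),
    list(v = c(10, 8, 3), cat = "PR", resp = TRUE, rescued = FALSE),  # -70%
    list(v = c(10, 20, 14), cat = "SD", resp = TRUE, rescued = TRUE), # +40/-30
    list(v = c(10, 20, 15), cat = "PD", resp = FALSE, rescued = FALSE),
    list(v = c(10, 11, 10), cat = "SD", resp = TRUE, rescued = FALSE),
    # PR via the MRI2->MRI3 route only
    list(v = c(10, 30, 10), cat = "PR", resp = TRUE, rescued = FALSE)
  )
  for (cs in cases) {
    call <- classify_response(traj(cs$v[1], cs$v[2], cs$v[3]))
    expect_equal(as.character(call$category), cs$cat,
                 info = paste(cs$v, collapse = "/"))
    expect_equal(call$responder, cs$resp)
    expect_equal(call$pseudoprogression_rescued, cs$rescued)
  }
})

test_that("threshold boundaries classify per the documented conventions", {
  # exactly -65% -> PR; just above -> SD
  expect_equal(as.character(classify_response(traj(10, 10, 3.5))$category), "PR")
  expect_equal(as.character(classify_response(traj(10, 10, 3.51))$category), "SD")
  # exactly +40% -> PD candidate; rescued iff MRI2->MRI3 <= -30 exactly
  expect_equal(as.character(classify_response(traj(10, 20, 14))$category), "SD")
  expect_equal(as.character(classify_response(traj(10, 20, 14.01))$category), "PD")
  expect_equal(as.character(classify_response(traj(10, 10, 14))$category), "PD")
  expect_equal(as.character(classify_response(traj(10, 10, 13.99))$category), "SD")
})

test_that("regrowth from a vanished lesion is classified from MRI1->MRI3 alone", {
  call <- classify_response(traj(10, 0, 15))
  expect_equal(as.character(call$category), "PD")
  expect_equal(as.character(call$growth_pattern), "indeterminate")
  call2 <- classify_response(traj(10, 0, 6)) # -40%: no rescue route exists
  expect_equal(as.character(call2$category), "SD")
})

test_that("classification is total and monotone in the final volume", {
  # totality: a dense sweep of (v2/v1, v3/v1) space yields exactly one
  # category everywhere
  f21 <- seq(0.05, 3, length.out = 60)
  f31 <- seq(0, 3, length.out = 60)
  grid <- expand.grid(f21 = f21, f31 = f31)
  calls <- classify_response(tibble::tibble(v1 = 10, v2 = 10 * grid$f21,
                                            v3 = 10 * grid$f31))
  expect_false(anyNA(calls$category))
  # monotonicity: with v1, v2 fixed, growing v3 never improves the category
  rank_of <- c(PD = 1, SD = 2, PR = 3, CR = 4)
  for (v2 in c(5, 10, 20)) {
    v3 <- seq(0, 40, by = 0.25)
    cat <- classify_response(tibble::tibble(v1 = 10, v2 = v2, v3 = v3))$category
    r <- rank_of[as.character(cat)]
    expect_true(all(diff(r) <= 0), info = paste("v2 =", v2))
  }
})

test_that("growth patterns follow the sign convention, zeros folded down", {
  expect_equal(as.character(classify_response(traj(10, 12, 8))$growth_pattern), "G2")
  expect_equal(as.character(classify_response(traj(10, 8, 6))$growth_pattern), "G1")
  expect_equal(as.character(classify_response(traj(10, 8, 9))$growth_pattern), "G4")
  expect_equal(as.character(classify_response(traj(10, 12, 13))$growth_pattern), "G3")
  # zero change counts as the non-growth branch by default
  expect_equal(as.character(classify_response(traj(10, 10, 10))$growth_pattern), "G1")
  # strict mode leaves zeros unclassified
  strict <- classify_response(traj(10, 10, 8), strict_growth = TRUE)
  expect_equal(as.character(strict$growth_pattern), "indeterminate")
})

test_that("planimetric-to-volumetric conversion matches the spherical closed form", {
  expect_equal(planimetric_to_volumetric(0), 0)
  expect_equal(planimetric_to_volumetric(0.25), 1.25^1.5 - 1, tolerance = 1e-12)
  expect_equal(planimetric_to_volumetric(-0.5), 0.5^1.5 - 1, tolerance = 1e-12)
  # strictly increasing, and the inverse round-trips
  x <- seq(-0.9, 2, by = 0.01)
  y <- planimetric_to_volumetric(x)
  expect_true(all(diff(y) > 0))
  expect_equal(volumetric_to_planimetric(y), x, tolerance = 1e-12)
  expect_error(planimetric_to_volumetric(-1), "area_fraction")
  th <- derive_volumetric_thresholds()
  expect_equal(th$rounded_pct, c(40, -65))
  expect_equal(th$exact_pct, c(39.7542486, -64.6446609), tolerance = 1e-6)
})

test_that("fisher_exact_2x2 equals enumeration for all tables with small margins", {
  expect_equal(fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2)), 34 / 70,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(1, 0, 0, 1), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  for (a in 0:4) for (b in 0:4) for (cc in 0:4) for (d in 0:4) {
    tab <- matrix(c(a, cc, b, d), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_2x2(tab), fisher_enum_oracle(tab),
                 tolerance = 1e-7, info = paste(a, b, cc, d))
  }
  # spot-check against the standard implementation on larger tables
  for (tab in list(matrix(c(12, 5, 3, 9), 2), matrix(c(101, 111, 4, 69), 2))) {
    expect_equal(fisher_exact_2x2(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-7)
  }
  expect_error(fisher_exact_2x2(matrix(c(1.5, 1, 1, 1), 2)), "integer")
})

test_that("summarize_cohort conserves counts and computes rates and Fisher p", {
  set.seed(7)
  vols <- tibble::tibble(
    animal_id = sprintf("A%02d", 1:40),
    arm = rep(c("ICB", "control"), c(25, 15)),
    v1 = runif(40, 5, 15), v2 = runif(40, 2, 30), v3 = runif(40, 0, 40)
  )
  calls <- classify_response(vols)
  s <- summarize_cohort(calls)
  expect_equal(sum(s$by_arm$n), 40)
  expect_equal(s$by_arm$CR + s$by_arm$PR + s$by_arm$SD + s$by_arm$PD,
               s$by_arm$n)
  expect_equal(sum(s$contingency), 40)
  expect_equal(s$fisher_p, fisher_enum_oracle(s$contingency), tolerance = 1e-7)
  expect_true(all(s$by_arm$response_rate >= 0 & s$by_arm$response_rate <= 100))
  expect_error(summarize_cohort(calls[0, ]), "arm")
  g <- glance(s)
  expect_equal(g$n_animals, 40)
})

test_that("bidimensional_product matches the caliper convention", {
  # digitized sphere, diameter 20 mm, 1 mm voxels
  mask <- sphere_mask(10, 1)
  expect_equal(bidimensional_product(mask, c(1, 1, 1)), 400, tolerance = 0.05)
  # single voxel
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  expect_equal(bidimensional_product(one, c(1, 1, 1)), 1)
  # axis-aligned 10 x 4 x 2 box
  box <- array(FALSE, c(14, 8, 6)); box[3:12, 3:6, 3:4] <- TRUE
  expect_equal(bidimensional_product(box, c(1, 1, 1)), 40)
  expect_error(bidimensional_product(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("volume tables round-trip through CSV", {
  vols <- tibble::tibble(animal_id = c("A1", "A2"), arm = "ICB",
                         v1 = c(5, 8), v2 = c(7, 6), v3 = c(9, 1))
  path <- tempfile(fileext = ".csv")
  utils::write.csv(vols, path, row.names = FALSE)
  back <- read_volume_table(path)
  expect_equal(back$v3, vols$v3)
  expect_s3_class(classify_response(back), "tbl_df")
})
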