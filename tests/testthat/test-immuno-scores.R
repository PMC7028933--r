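# Gene-signature scores, immunogram z-scores, TCR clonality, shared CDR3
# motifs and LDH specific lysis.

test_that("signature_score is the geometric mean with the stated conventions", {
  expr <- tibble::tibble(gene = c("Il6", "Tnf"), s1 = c(4, 9), s2 = c(5, 5))
  sc <- signature_score(expr, c("Il6", "Tnf"), pseudocount = 0)
  expect_equal(sc$score[sc$sample == "s1"], 6)
  expect_equal(sc$score[sc$sample == "s2"], 5) # idempotent on equal values
  # homogeneity: scaling all genes scales the score
  expr2 <- dplyr::mutate(expr, s1 = s1 * 3, s2 = s2 * 3)
  sc2 <- signature_score(expr2, c("Il6", "Tnf"), pseudocount = 0)
  expect_equal(sc2$score, 3 * sc$score, tolerance = 1e-12)
  # monotone in every member gene
  expr3 <- expr; expr3$s1[1] <- 10
  expect_gt(signature_score(expr3, c("Il6", "Tnf"), 0)$score[1], sc$score[1])
  expect_error(signature_score(expr, c("Il6", "Nope")), "not in table")
  zero <- tibble::tibble(gene = "g", s1 = 0)
  expect_error(signature_score(zero, "g", pseudocount = 0), "zero expression")
  expect_equal(signature_score(zero, "g", pseudocount = 1)$score, 1)
})

test_that("immunogram standardizes log2 fold changes across features", {
  fx <- tibble::tibble(feature = c("a", "b"), r = c(2, 1), nr = c(1, 2))
  ig <- immunogram(fx)
  expect_equal(ig$log2_fc, c(1, -1))
  expect_equal(ig$z, c(1, -1) / sqrt(2), tolerance = 1e-12)
  expect_equal(sum(ig$z), 0, tolerance = 1e-10)
  # all-equal fold changes: all-zero output, flagged
  same <- tibble::tibble(feature = c("a", "b", "c"), r = c(2, 4, 8),
                         nr = c(1, 2, 4))
  ig2 <- immunogram(same)
  expect_equal(ig2$z, c(0, 0, 0))
  expect_true(attr(ig2, "constant"))
  expect_error(immunogram(dplyr::mutate(fx, nr = c(0, 2))), "positive")
})

test_that("top_clones_share handles ties, scaling and small repertoires", {
  rep10 <- tibble::tibble(cdr3_aa = sprintf("C%02d", 1:10), count = rep(5L, 10))
  expect_equal(top_clones_share(rep10), 100)
  rep20 <- tibble::tibble(cdr3_aa = sprintf("C%02d", 1:20), count = rep(5L, 20))
  expect_equal(top_clones_share(rep20), 50)
  rep3 <- tibble::tibble(cdr3_aa = c("A", "B", "C"), count = c(50L, 30L, 20L))
  expect_equal(top_clones_share(rep3), 100)
  # invariance to relabeling and total-count scaling
  expect_equal(top_clones_share(dplyr::mutate(rep20, count = count * 7L)), 50)
  shuffled <- rep20[sample(20), ]
  expect_equal(top_clones_share(shuffled), 50)
  expect_error(top_clones_share(rep3[0, ]), "empty")
})

test_that("productive_clonality follows 1 - H/ln(R)", {
  uniform <- tibble::tibble(cdr3_aa = sprintf("C%02d", 1:8), count = rep(3L, 8))
  expect_equal(productive_clonality(uniform), 0, tolerance = 1e-12)
  single <- tibble::tibble(cdr3_aa = "CASSLGQYF", count = 12L)
  expect_equal(productive_clonality(single), 1)
  two <- tibble::tibble(cdr3_aa = c("A", "B"), count = c(3L, 1L))
  h <- -(0.75 * log(0.75) + 0.25 * log(0.25))
  expect_equal(productive_clonality(two), 1 - h / log(2), tolerance = 1e-10)
  expect_equal(productive_clonality(two), 0.18872, tolerance = 1e-4)
  # any concentration of mass increases clonality above the uniform value
  skewed <- tibble::tibble(cdr3_aa = sprintf("C%02d", 1:8),
                           count = c(17L, rep(1L, 7)))
  expect_gt(productive_clonality(skewed), productive_clonality(uniform))
  expect_true(productive_clonality(skewed) <= 1)
})

test_that("shared_cdr3_motifs clusters by Hamming distance within length strata", {
  reps <- tibble::tibble(
    sample = c("s1", "s2"),
    cdr3_aa = c("CASSLGQY", "CASSLGQY")
  )
  hit <- shared_cdr3_motifs(reps)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$n_samples, 2)
  one_sub <- tibble::tibble(sample = c("s1", "s2"),
                            cdr3_aa = c("CASSLGQY", "CASSLGNY"))
  expect_equal(nrow(shared_cdr3_motifs(one_sub)), 1)
  far <- tibble::tibble(sample = c("s1", "s2"),
                        cdr3_aa = c("CASSLGQY", "CATTLGNY")) # distance 3
  expect_equal(nrow(shared_cdr3_motifs(far)), 0)
  # different lengths never cluster
  lens <- tibble::tibble(sample = c("s1", "s2"),
                         cdr3_aa = c("CASSLGQY", "CASSLGQYF"))
  expect_equal(nrow(shared_cdr3_motifs(lens)), 0)
  # within-sample-only clusters are not reported
  within <- tibble::tibble(sample = c("s1", "s1"),
                           cdr3_aa = c("CASSLGQY", "CASSLGNY"))
  expect_equal(nrow(shared_cdr3_motifs(within)), 0)
})

test_that("shared_cdr3_motifs equals brute-force all-pairs clustering", {
  set.seed(21)
  reps <- generate_repertoire(n_clones = 60, concentration = 0.5,
                              n_samples = 3, shared_motif = TRUE, seed = 8)
  got <- shared_cdr3_motifs(reps)
  # brute force: graph over unique sequences, edges = equal length and
  # Hamming distance <= 1; report components spanning >= 2 samples
  seqs <- unique(reps[, c("sample", "cdr3_aa")])
  u <- unique(seqs$cdr3_aa)
  adj <- matrix(FALSE, length(u), length(u))
  for (i in seq_along(u)) for (j in seq_along(u)) {
    if (i < j && nchar(u[i]) == nchar(u[j])) {
      d <- sum(strsplit(u[i], "")[[1]] != strsplit(u[j], "")[[1]])
      adj[i, j] <- adj[j, i] <- d <= 1
    }
  }
  comp <- seq_along(u)
  repeat {
    changed <- FALSE
    for (i in seq_along(u)) for (j in which(adj[i, ])) {
      if (comp[j] > comp[i]) { comp[j] <- comp[i]; changed <- TRUE }
      if (comp[i] > comp[j]) { comp[i] <- comp[j]; changed <- TRUE }
    }
    if (!changed) break
  }
  spanning <- sum(vapply(unique(comp), function(cc) {
    length(unique(seqs$sample[seqs$cdr3_aa %in% u[comp == cc]])) >= 2
  }, logical(1)))
  expect_equal(nrow(got), spanning)
  expect_gte(nrow(got), 1) # the planted motif is always found
})

test_that("specific_lysis applies the background-corrected ratio", {
  expect_equal(specific_lysis(0.9, 0, 0, 0.9), 1)
  expect_equal(specific_lysis(0.3, 0.1, 0.2, 0.9), 0)
  expect_equal(specific_lysis(0.8, 0.1, 0.2, 0.9), 0.5 / 0.7, tolerance = 1e-12)
  # scale invariance under a common OD rescaling
  expect_equal(specific_lysis(1.6, 0.2, 0.4, 1.8, 0.1),
               specific_lysis(0.8, 0.1, 0.2, 0.9, 0.05), tolerance = 1e-12)
  expect_error(specific_lysis(0.5, 0.1, 0.4, 0.4), "maximum-lysis")
  expect_error(specific_lysis(-0.1, 0, 0, 1), "finite")
})
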