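# Synthetic expression tables and TCR repertoires for exercising the
# immunology statistics without any sequencing download.

#' Generate a synthetic expression table with gene-set effects
#'
#' Log-normal counts; genes belonging to a designated set receive a
#' multiplicative group effect in the affected group, emulating a pro- vs
#' anti-inflammatory contrast between responder and non-responder samples.
#'
#' @param n_genes Number of genes.
#' @param n_samples Samples per group (two groups, `R` and `NR`).
#' @param gene_sets Named list of gene index vectors (defaults to a
#'   "pro_inflammatory" and an "anti_inflammatory" set of 10 genes each).
#' @param effects Named numeric vector of fold changes applied to each set
#'   in group `R` (1 = no effect).
#' @param base_meanlog,base_sdlog Baseline log-normal parameters.
#' @param noise_sdlog Per-observation log-normal noise.
#' @param seed Integer seed.
#' @return Tibble with a `gene` column and one column per sample
#'   (`R1..Rn`, `NR1..NRn`); attributes `gene_sets` (names) and `groups`.
#' @export
generate_expression <- function(n_genes = 200, n_samples = 4,
                                gene_sets = NULL,
                                effects = c(pro_inflammatory = 1,
                                            anti_inflammatory = 1),
                                base_meanlog = log(100), base_sdlog = 0.5,
                                noise_sdlog = 0.3, seed = 1L) {
  stopifnot(n_genes >= 1, n_samples >= 1)
  set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  if (is.null(gene_sets)) {
    gene_sets <- list(pro_inflammatory = genes[1:10],
                      anti_inflammatory = genes[11:20])
  }
  base <- rlnorm(n_genes, base_meanlog, base_sdlog)
  samples <- c(paste0("R", seq_len(n_samples)), paste0("NR", seq_len(n_samples)))
  groups <- rep(c("R", "NR"), each = n_samples)
  mat <- matrix(0, n_genes, length(samples),
                dimnames = list(genes, samples))
  for (s in seq_along(samples)) {
    mu <- base
    if (groups[s] == "R") {
      for (set_name in names(effects)) {
        idx <- match(gene_sets[[set_name]], genes)
        mu[idx] <- mu[idx] * effects[[set_name]]
      }
    }
    mat[, s] <- rlnorm(n_genes, log(mu), noise_sdlog)
  }
  out <- tibble::as_tibble(mat, rownames = "gene")
  attr(out, "gene_sets") <- gene_sets
  attr(out, "groups") <- setNames(groups, samples)
  out
}

random_cdr3 <- function(n, len_range = c(10, 16)) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  lens <- seq(len_range[1], len_range[2])
  vapply(seq_len(n), function(i) {
    len <- lens[sample.int(length(lens), 1)] # avoid scalar-sample surprise
    paste0("CASS", paste(sample(aa, len - 5, replace = TRUE), collapse = ""),
           "F")
  }, character(1))
}

#' Generate synthetic TCR repertoires
#'
#' Clone counts follow a Dirichlet-multinomial: clone frequencies are drawn
#' from a symmetric Dirichlet with the given concentration (low
#' concentration = oligoclonal, high = even) and counts from a multinomial
#' over `total_templates`. Optionally a length-matched CDR3 motif (pairwise
#' Hamming distance at most 1 from a common seed sequence) is planted into
#' every repertoire.
#'
#' @param n_clones Distinct clones per repertoire.
#' @param concentration Dirichlet concentration parameter (per clone).
#' @param n_samples Number of repertoires.
#' @param total_templates Total template count per repertoire.
#' @param shared_motif Plant a shared motif across all samples?
#' @param seed Integer seed.
#' @return Tibble with columns `sample`, `cdr3_aa`, `count`.
#' @export
generate_repertoire <- function(n_clones = 100, concentration = 1,
                                n_samples = 1, total_templates = 10000,
                                shared_motif = FALSE, seed = 1L) {
  stopifnot(n_clones >= 1, concentration > 0, n_samples >= 1)
  set.seed(seed)
  motif_seed <- if (shared_motif) random_cdr3(1, c(14, 14)) else NULL
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  out <- lapply(seq_len(n_samples), function(s) {
    seqs <- random_cdr3(n_clones)
    if (shared_motif) {
      # one substitution at a fixed interior position, so the planted
      # variants stay within pairwise Hamming distance 1 of each other
      v <- strsplit(motif_seed, "")[[1]]
      pos <- 8
      v[pos] <- sample(setdiff(aa, v[pos]), 1)
      seqs[1] <- paste(v, collapse = "")
    }
    g <- rgamma(n_clones, shape = concentration, rate = 1)
    if (sum(g) == 0) g <- rep(1, n_clones)
    counts <- as.integer(rmultinom(1, total_templates, g / sum(g)))
    keep <- counts > 0
    tibble::tibble(sample = sprintf("S%02d", s), cdr3_aa = seqs[keep],
                   count = counts[keep])
  })
  dplyr::bind_rows(out)
}
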