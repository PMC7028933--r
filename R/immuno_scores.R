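# Small immunology statistics: geometric-mean gene-signature scores,
# immunogram z-scores, TCR clonality metrics, shared CDR3 motif detection,
# and LDH specific-lysis correction.

#' Geometric-mean gene-signature score
#'
#' `exp(mean(log(x + pseudocount)))` over the member genes of a signature,
#' per sample. The default pseudocount of 1 keeps zero counts finite
#' (count-scale data); set it to 0 for strictly positive inputs.
#'
#' @param expr Data frame with a `gene` column and one numeric column per
#'   sample (genes x samples), or a numeric matrix with gene rownames.
#' @param gene_set Character vector of member genes (must exist in `expr`).
#' @param pseudocount Non-negative offset added before the log.
#' @return Tibble with columns `sample` and `score`.
#' @examples
#' expr <- tibble::tibble(gene = c("Il6", "Tnf"), s1 = c(4, 9), s2 = c(1, 1))
#' signature_score(expr, c("Il6", "Tnf"), pseudocount = 0) # s1: sqrt(36) = 6
#' @export
signature_score <- function(expr, gene_set, pseudocount = 1) {
  stopifnot(length(gene_set) >= 1, pseudocount >= 0)
  if (is.matrix(expr)) {
    expr <- tibble::as_tibble(expr, rownames = "gene")
  }
  if (!"gene" %in% names(expr)) stop("`expr` needs a `gene` column", call. = FALSE)
  missing <- setdiff(gene_set, expr$gene)
  if (length(missing)) {
    stop("genes not in table: ", paste(head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  sub <- expr[match(gene_set, expr$gene), setdiff(names(expr), "gene"),
              drop = FALSE]
  vals <- as.matrix(sub)
  if (any(vals < 0)) stop("expression values must be >= 0", call. = FALSE)
  if (any(vals + pseudocount <= 0)) {
    stop("zero expression with zero pseudocount (log undefined)", call. = FALSE)
  }
  tibble::tibble(
    sample = colnames(vals),
    score = unname(exp(colMeans(log(vals + pseudocount))))
  )
}

#' Immunogram z-scores of responder/non-responder fold changes
#'
#' Per feature, the responder/non-responder fold change is log2-transformed
#' and then standardized across features (sample standard deviation). The
#' output feeds a radar-chart display; all-equal fold changes give all-zero
#' z-scores (flagged in the `constant` attribute).
#'
#' @param features Data frame with columns `feature`, `r` (responder mean)
#'   and `nr` (non-responder mean), both positive.
#' @return Tibble with columns `feature`, `log2_fc`, `z`.
#' @export
immunogram <- function(features) {
  stopifnot(is.data.frame(features),
            all(c("feature", "r", "nr") %in% names(features)),
            nrow(features) >= 2)
  if (any(features$r <= 0) || any(features$nr <= 0)) {
    stop("group means must be positive", call. = FALSE)
  }
  lfc <- log2(features$r / features$nr)
  s <- sd(lfc)
  z <- if (s > 0) (lfc - mean(lfc)) / s else rep(0, length(lfc))
  out <- tibble::tibble(feature = features$feature, log2_fc = lfc, z = z)
  attr(out, "constant") <- s == 0
  out
}

check_repertoire <- function(rep) {
  stopifnot(is.data.frame(rep))
  if (!all(c("cdr3_aa", "count") %in% names(rep))) {
    stop("repertoire needs columns cdr3_aa, count", call. = FALSE)
  }
  if (nrow(rep) == 0) stop("empty repertoire", call. = FALSE)
  if (any(rep$count <= 0) || any(rep$count != round(rep$count))) {
    stop("clone counts must be positive integers", call. = FALSE)
  }
  invisible(rep)
}

#' Cumulative share of the top clones
#'
#' Percentage of all productive templates carried by the `m` most frequent
#' clones. Ties at the boundary are resolved deterministically: clones are
#' ordered by decreasing count and then lexicographically by CDR3 sequence,
#' and exactly `m` clones are included.
#'
#' @param rep Repertoire data frame with columns `cdr3_aa`, `count`.
#' @param m Number of top clones (default 10).
#' @return Percentage in (0, 100].
#' @export
top_clones_share <- function(rep, m = 10) {
  check_repertoire(rep)
  ord <- order(-rep$count, rep$cdr3_aa)
  take <- head(ord, m)
  100 * sum(rep$count[take]) / sum(rep$count)
}

#' Productive clonality of a TCR repertoire
#'
#' `1 - H / ln(R)` where `H` is the Shannon entropy of the clone frequency
#' distribution and `R` the number of distinct clones; 0 for a perfectly
#' even repertoire, approaching 1 for an oligoclonal one. A single-clone
#' repertoire is defined as 1 (maximally clonal).
#'
#' @param rep Repertoire data frame with columns `cdr3_aa`, `count`.
#' @return Clonality in [0, 1].
#' @export
productive_clonality <- function(rep) {
  check_repertoire(rep)
  counts <- tapply(rep$count, rep$cdr3_aa, sum)
  r <- length(counts)
  if (r == 1) return(1)
  p <- counts / sum(counts)
  h <- -sum(p * log(p))
  1 - h / log(r)
}

#' Shared CDR3 motif clusters across repertoires
#'
#' Single-linkage clusters of equal-length CDR3 amino-acid sequences with
#' pairwise Hamming distance at most `max_mismatch` ("alterations of 1 or
#' less AA" for the default), reported only when a cluster spans at least
#' `min_samples` distinct repertoires. Length strata are handled
#' independently (substitutions only, no indels).
#'
#' @param repertoires Data frame with columns `sample`, `cdr3_aa` (and
#'   optionally `count`), or a named list of repertoire data frames.
#' @param max_mismatch Maximum Hamming distance within a cluster edge.
#' @param min_samples Minimum number of distinct samples a reported cluster
#'   must span (default 2).
#' @return Tibble with columns `cluster`, `cdr3_aa`, `samples` (list
#'   column), `n_sequences`, `n_samples`; zero rows when nothing is shared.
#' @export
shared_cdr3_motifs <- function(repertoires, max_mismatch = 1,
                               min_samples = 2) {
  if (is.list(repertoires) && !is.data.frame(repertoires)) {
    nm <- names(repertoires)
    if (is.null(nm)) nm <- paste0("sample", seq_along(repertoires))
    repertoires <- dplyr::bind_rows(
      lapply(seq_along(repertoires), function(i) {
        tibble::tibble(sample = nm[i],
                       cdr3_aa = repertoires[[i]]$cdr3_aa)
      }))
  }
  stopifnot(all(c("sample", "cdr3_aa") %in% names(repertoires)))
  seqs <- dplyr::distinct(repertoires, .data$sample, .data$cdr3_aa)
  uniq <- unique(seqs$cdr3_aa)
  if (length(uniq) == 0) return(empty_motif_table())

  comp <- integer(length(uniq))
  names(comp) <- uniq
  next_comp <- 0L
  for (len in unique(nchar(uniq))) {
    strat <- uniq[nchar(uniq) == len]
    ns <- length(strat)
    if (ns == 1) {
      next_comp <- next_comp + 1L
      comp[strat] <- next_comp
      next
    }
    # pairwise Hamming distances within the stratum
    mat <- do.call(rbind, strsplit(strat, ""))
    parent <- seq_len(ns)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (i in seq_len(ns - 1)) {
      di <- rowSums(mat[(i + 1):ns, , drop = FALSE] !=
                      matrix(mat[i, ], ns - i, len, byrow = TRUE))
      for (j in which(di <= max_mismatch)) {
        ri <- find(i); rj <- find(i + j)
        if (ri != rj) parent[rj] <- ri
      }
    }
    roots <- vapply(seq_len(ns), find, integer(1))
    ids <- match(roots, unique(roots))
    comp[strat] <- next_comp + ids
    next_comp <- next_comp + max(ids)
  }

  seqs$component <- comp[seqs$cdr3_aa]
  out <- seqs |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(
      cdr3_aa = list(sort(unique(.data$cdr3_aa))),
      samples = list(sort(unique(.data$sample))),
      n_sequences = length(unique(.data$cdr3_aa)),
      n_samples = length(unique(.data$sample)),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_samples >= min_samples) |>
    dplyr::arrange(dplyr::desc(.data$n_samples), dplyr::desc(.data$n_sequences))
  if (nrow(out) == 0) return(empty_motif_table())
  out$cluster <- seq_len(nrow(out))
  out[, c("cluster", "cdr3_aa", "samples", "n_sequences", "n_samples")]
}

empty_motif_table <- function() {
  tibble::tibble(cluster = integer(), cdr3_aa = list(), samples = list(),
                 n_sequences = integer(), n_samples = integer())
}

#' LDH specific lysis relative to the maximum-lysis control
#'
#' Corrects the experimental optical density for spontaneous effector and
#' target LDH release and the culture-medium background, and reports the
#' ratio to the background-corrected maximum-lysis control:
#' `(experimental - effector_spont - target_spont + background) /
#' (target_max - target_spont)`. With raw (background-containing) OD
#' readings the background cancels exactly once in the numerator, which is
#' why it is added back.
#'
#' @param experimental OD of the effector + target co-culture.
#' @param effector_spont OD of effectors alone (spontaneous release).
#' @param target_spont OD of targets alone (spontaneous release).
#' @param target_max OD of the full-lysis target control.
#' @param background OD of the culture medium (default 0: already
#'   subtracted).
#' @return Specific lysis as a fraction of the maximum-lysis control
#'   (vectorized).
#' @export
specific_lysis <- function(experimental, effector_spont, target_spont,
                           target_max, background = 0) {
  args <- cbind(experimental, effector_spont, target_spont, target_max,
                background)
  if (any(args < 0) || any(!is.finite(args))) {
    stop("OD readings must be finite and >= 0", call. = FALSE)
  }
  denom <- target_max - target_spont
  if (any(denom <= 0)) {
    stop("maximum-lysis control must exceed target spontaneous release",
         call. = FALSE)
  }
  (experimental - effector_spont - target_spont + background) / denom
}
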