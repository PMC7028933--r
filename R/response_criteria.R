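#' Percent change in lesion volume between two MRI time points
#'
#' The basic quantity of the volumetric response criteria,
#' `%V = 100 * (v_to - v_from) / v_from`.
#'
#' @param v_from Baseline lesion volume(s), mm^3; must be strictly positive.
#' @param v_to Follow-up lesion volume(s), mm^3; must be non-negative.
#' @return Numeric vector of percent changes.
#' @examples
#' relative_change(10, 14) # +40
#' @export
relative_change <- function(v_from, v_to) {
  stopifnot(is.numeric(v_from), is.numeric(v_to))
  if (any(!is.finite(v_from)) || any(!is.finite(v_to))) {
    stop("volumes must be finite", call. = FALSE)
  }
  if (any(v_from <= 0)) {
    stop("baseline volume must be > 0 (undefined baseline)", call. = FALSE)
  }
  if (any(v_to < 0)) stop("volumes must be non-negative", call. = FALSE)
  100 * (v_to - v_from) / v_from
}

#' Volumetric response-criteria thresholds
#'
#' Container for the percent-change cutoffs of the volumetric response
#' classification: complete response at exactly -100, partial response at or
#' below `pr`, progressive disease at or above `pd`, and pseudoprogression
#' rescue (unconfirmed progression reclassified as stable disease) when the
#' MRI2 to MRI3 change is at or below `rescue`. Defaults are the volumetric
#' translation of the planimetric RANO cutoffs under a spherical-tumor
#' assumption (see [derive_volumetric_thresholds()]).
#'
#' @param pr Partial-response threshold, percent (default -65).
#' @param pd Progressive-disease threshold, percent (default +40).
#' @param rescue Pseudoprogression rescue threshold on the MRI2->MRI3 change,
#'   percent (default -30).
#' @return An object of class `response_config`.
#' @export
response_config <- function(pr = -65, pd = 40, rescue = -30) {
  stopifnot(is.numeric(pr), is.numeric(pd), is.numeric(rescue))
  if (!(pr < 0 && pr > -100)) stop("`pr` must lie in (-100, 0)", call. = FALSE)
  if (!(pd > 0)) stop("`pd` must be positive", call. = FALSE)
  if (!(rescue < 0)) stop("`rescue` must be negative", call. = FALSE)
  structure(list(cr = -100, pr = pr, pd = pd, rescue = rescue),
            class = "response_config")
}

#' @export
print.response_config <- function(x, ...) {
  cat("Volumetric response thresholds (% change MRI3-MRI1):\n")
  cat(sprintf("  CR = %g, PR <= %g, PD >= %+g, rescue (MRI3-MRI2) <= %g\n",
              x$cr, x$pr, x$pd, x$rescue))
  invisible(x)
}

response_levels <- c("CR", "PR", "SD", "PD")
growth_levels <- c("G1", "G2", "G3", "G4", "indeterminate")

validate_volumes <- function(volumes) {
  required <- c("v1", "v2", "v3")
  missing <- setdiff(required, names(volumes))
  if (length(missing)) {
    stop("`volumes` must contain columns ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  v1 <- volumes$v1; v2 <- volumes$v2; v3 <- volumes$v3
  if (any(!is.finite(v1)) || any(!is.finite(v2)) || any(!is.finite(v3))) {
    stop("volumes must be finite", call. = FALSE)
  }
  if (any(v1 <= 0)) stop("baseline volume v1 must be > 0", call. = FALSE)
  if (any(v2 < 0) || any(v3 < 0)) {
    stop("volumes must be non-negative", call. = FALSE)
  }
  invisible(volumes)
}

#' Classify serial volume trajectories into CR/PR/SD/PD response calls
#'
#' Applies the volumetric translation of the RANO/iRANO criteria to
#' three-time-point lesion-volume trajectories (baseline MRI1, on-therapy
#' MRI2, post-therapy MRI3):
#'
#' * CR when the MRI1->MRI3 change is exactly -100% (zero residual volume);
#' * PR when the MRI1->MRI3 or the MRI2->MRI3 change is at or below the PR
#'   threshold (-65% by default);
#' * PD when the MRI1->MRI3 change is at or above the PD threshold (+40% by
#'   default), unless the lesion regressed by at least the rescue amount
#'   (30% by default) between MRI2 and MRI3, in which case the progression is
#'   treated as pseudoprogression and the animal is called SD;
#' * SD otherwise.
#'
#' Animals with CR, PR or SD are grouped as responders; PD animals are
#' non-responders. Growth patterns are the sign patterns of the MRI1->MRI2
#' and MRI2->MRI3 changes (see [classify_growth_pattern()]).
#'
#' Boundary conventions: exactly the PR threshold classifies PR, exactly the
#' PD threshold is a PD candidate (then subject to rescue), exactly the
#' rescue threshold rescues. A lesion that regrew from zero volume at MRI2
#' has an undefined MRI2->MRI3 change; its category is computed from the
#' MRI1->MRI3 change alone and the growth pattern is `indeterminate`.
#'
#' @param volumes Data frame with numeric columns `v1`, `v2`, `v3` (lesion
#'   volumes in mm^3 at MRI1/MRI2/MRI3) and optionally `animal_id` and `arm`.
#' @param config A [response_config()].
#' @param strict_growth Logical; if `TRUE`, a zero percent change yields an
#'   `indeterminate` growth pattern instead of being folded into the
#'   non-growth branch.
#' @return The input as a tibble with appended columns `pct_v31`, `pct_v21`,
#'   `pct_v32`, `category` (factor CR/PR/SD/PD), `responder`,
#'   `pseudoprogression_rescued` and `growth_pattern`.
#' @examples
#' calls <- classify_response(tibble::tibble(v1 = 10, v2 = 20, v3 = 14))
#' calls$category # SD via pseudoprogression rescue
#' @export
classify_response <- function(volumes, config = response_config(),
                              strict_growth = FALSE) {
  stopifnot(inherits(config, "response_config"), is.data.frame(volumes))
  validate_volumes(volumes)
  v1 <- volumes$v1; v2 <- volumes$v2; v3 <- volumes$v3

  pct31 <- 100 * (v3 - v1) / v1
  pct21 <- 100 * (v2 - v1) / v1
  pct32 <- ifelse(v2 > 0, 100 * (v3 - v2) / pmax(v2, .Machine$double.xmin), NA_real_)
  pct32[v2 == 0 & v3 == 0] <- 0 # stayed at complete response

  rescued <- logical(length(v1))
  category <- character(length(v1))
  is_cr <- v3 == 0
  is_pr <- !is_cr & (pct31 <= config$pr | (!is.na(pct32) & pct32 <= config$pr))
  is_pd_cand <- !is_cr & !is_pr & pct31 >= config$pd
  rescue_ok <- is_pd_cand & !is.na(pct32) & pct32 <= config$rescue
  category[is_cr] <- "CR"
  category[is_pr] <- "PR"
  category[is_pd_cand & !rescue_ok] <- "PD"
  category[is_pd_cand & rescue_ok] <- "SD"
  rescued[is_pd_cand & rescue_ok] <- TRUE
  category[category == ""] <- "SD"

  out <- tibble::as_tibble(volumes)
  out$pct_v31 <- pct31
  out$pct_v21 <- pct21
  out$pct_v32 <- pct32
  out$category <- factor(category, levels = response_levels)
  out$responder <- out$category != "PD"
  out$pseudoprogression_rescued <- rescued
  out$growth_pattern <- classify_growth_pattern(pct21, pct32,
                                                strict = strict_growth)
  out
}

#' Growth pattern from the signs of the serial volume changes
#'
#' G1: regression at both intervals (direct response); G2: growth
#' MRI1->MRI2 then regression MRI2->MRI3 (pseudoprogression-like);
#' G3: growth at both intervals (progression); G4: regression then growth
#' (late progression). By default a change of exactly 0% is folded into the
#' non-growth branch so every trajectory receives a pattern; with
#' `strict = TRUE` zeros (and undefined changes) are `indeterminate`.
#'
#' @param pct21 Percent change MRI1->MRI2.
#' @param pct32 Percent change MRI2->MRI3 (`NA` when undefined).
#' @param strict Logical; strict sign convention (see above).
#' @return Factor with levels G1, G2, G3, G4, indeterminate.
#' @export
classify_growth_pattern <- function(pct21, pct32, strict = FALSE) {
  stopifnot(length(pct21) == length(pct32))
  pat <- rep("indeterminate", length(pct21))
  ok <- !is.na(pct21) & !is.na(pct32)
  if (strict) {
    ok <- ok & pct21 != 0 & pct32 != 0
    up21 <- pct21 > 0
    up32 <- pct32 > 0
  } else {
    up21 <- pct21 > 0
    up32 <- pct32 > 0
  }
  pat[ok & !up21 & !up32] <- "G1"
  pat[ok & up21 & !up32] <- "G2"
  pat[ok & up21 & up32] <- "G3"
  pat[ok & !up21 & up32] <- "G4"
  factor(pat, levels = growth_levels)
}

#' Convert a planimetric (diameter-product) change to a volumetric change
#'
#' Under a spherical-tumor assumption the RANO bidimensional diameter
#' product scales as d^2 and the volume as d^3, so a fractional area change
#' `a` corresponds to a fractional volume change `(1 + a)^(3/2) - 1`.
#'
#' @param area_fraction Fractional change of the diameter product (> -1).
#' @return Fractional volume change.
#' @seealso [volumetric_to_planimetric()], [derive_volumetric_thresholds()]
#' @examples
#' planimetric_to_volumetric(0.25)  # ~= 0.3975
#' @export
planimetric_to_volumetric <- function(area_fraction) {
  stopifnot(is.numeric(area_fraction))
  if (any(area_fraction <= -1)) {
    stop("`area_fraction` must be > -1", call. = FALSE)
  }
  (1 + area_fraction)^(3 / 2) - 1
}

#' @rdname planimetric_to_volumetric
#' @param volume_fraction Fractional change of the volume (> -1).
#' @export
volumetric_to_planimetric <- function(volume_fraction) {
  stopifnot(is.numeric(volume_fraction))
  if (any(volume_fraction <= -1)) {
    stop("`volume_fraction` must be > -1", call. = FALSE)
  }
  (1 + volume_fraction)^(2 / 3) - 1
}

#' Derive the volumetric PD/PR thresholds from the planimetric RANO cutoffs
#'
#' Converts the clinical 25% diameter-product increase (progression) and 50%
#' decrease (partial response) to volumetric percent changes under the
#' spherical assumption and rounds to the nearest `round_to` percent. The
#' rounding happens only here, never during classification.
#'
#' @param pd_area_increase Planimetric progression cutoff as a fraction
#'   (default 0.25).
#' @param pr_area_decrease Planimetric partial-response cutoff as a fraction
#'   (default 0.50).
#' @param round_to Rounding grain in percent (default 5; use `NULL` to skip).
#' @return Tibble with columns `threshold`, `planimetric_pct`, `exact_pct`,
#'   `rounded_pct`.
#' @export
derive_volumetric_thresholds <- function(pd_area_increase = 0.25,
                                         pr_area_decrease = 0.50,
                                         round_to = 5) {
  exact <- 100 * planimetric_to_volumetric(c(pd_area_increase,
                                             -pr_area_decrease))
  rounded <- if (is.null(round_to)) exact else round_to * round(exact / round_to)
  tibble::tibble(
    threshold = c("pd", "pr"),
    planimetric_pct = 100 * c(pd_area_increase, -pr_area_decrease),
    exact_pct = exact,
    rounded_pct = rounded
  )
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Point-probability convention: the two-sided p-value is the sum of the
#' hypergeometric probabilities of all tables with the observed margins
#' whose point probability does not exceed that of the observed table
#' (within a relative tolerance of 1e-7 to absorb floating-point ties).
#'
#' @param tab 2x2 matrix (or coercible) of non-negative integer counts.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2)) # 34/70
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("`tab` must be 2x2", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab)) || any(!is.finite(tab))) {
    stop("table entries must be non-negative integers", call. = FALSE)
  }
  m <- sum(tab[1, ]) # row 1 margin
  n <- sum(tab[2, ])
  k <- sum(tab[, 1]) # column 1 margin
  if (m + n == 0) return(1)
  x <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(x, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Summarize response calls per treatment arm
#'
#' Per-arm category counts and response rates plus a responder-by-arm
#' contingency table with a two-sided Fisher exact p-value (computed for the
#' first two arms when more are present).
#'
#' @param calls A data frame of response calls as returned by
#'   [classify_response()], with an `arm` column.
#' @return An object of class `cohort_summary`: a list with `by_arm`
#'   (tibble of counts and `response_rate` in percent), `contingency`
#'   (responder x arm matrix) and `fisher_p`.
#' @examples
#' calls <- classify_response(tibble::tibble(
#'   v1 = c(10, 10, 10, 10), v2 = c(8, 14, 12, 15), v3 = c(2, 20, 3, 18),
#'   arm = c("ICB", "ICB", "control", "control")
#' ))
#' summarize_cohort(calls)
#' @export
summarize_cohort <- function(calls) {
  stopifnot(is.data.frame(calls))
  if (!"arm" %in% names(calls)) stop("`calls` needs an `arm` column", call. = FALSE)
  if (!all(c("category", "responder") %in% names(calls))) {
    stop("`calls` must come from classify_response()", call. = FALSE)
  }
  if (any(table(calls$arm) < 1) || nrow(calls) == 0) {
    stop("every arm needs at least one animal", call. = FALSE)
  }
  by_arm <- calls |>
    dplyr::count(.data$arm, .data$category, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L) |>
    dplyr::mutate(
      n = .data$CR + .data$PR + .data$SD + .data$PD,
      responders = .data$CR + .data$PR + .data$SD,
      response_rate = 100 * .data$responders / .data$n
    )
  arms <- unique(as.character(calls$arm))
  contingency <- matrix(0L, 2, length(arms),
                        dimnames = list(c("responder", "non_responder"), arms))
  for (a in arms) {
    sub <- calls[as.character(calls$arm) == a, ]
    contingency["responder", a] <- sum(sub$responder)
    contingency["non_responder", a] <- sum(!sub$responder)
  }
  fisher_p <- if (length(arms) >= 2) {
    fisher_exact_2x2(contingency[, 1:2])
  } else {
    NA_real_
  }
  structure(list(by_arm = by_arm, contingency = contingency,
                 fisher_p = fisher_p),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort response summary\n")
  print(x$by_arm)
  if (!is.na(x$fisher_p)) {
    cat(sprintf("Fisher exact (responder x arm, first two arms): p = %.4g\n",
                x$fisher_p))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cohort_summary <- function(x, ...) {
  x$by_arm
}

#' @exportS3Method generics::glance
glance.cohort_summary <- function(x, ...) {
  tibble::tibble(
    n_arms = nrow(x$by_arm),
    n_animals = sum(x$by_arm$n),
    fisher_p = x$fisher_p
  )
}

#' Read a cohort volume table from CSV/TSV
#'
#' Expects columns `animal_id`, `arm`, `v1`, `v2`, `v3` (volumes in mm^3).
#'
#' @param path File path; the delimiter is inferred from the extension.
#' @return Tibble of trajectories.
#' @export
read_volume_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  validate_volumes(df)
  tibble::as_tibble(df)
}
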