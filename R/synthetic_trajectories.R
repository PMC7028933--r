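# Seeded synthetic volume trajectories. Four archetypes mirror the observed
# growth patterns: direct response (G1), pseudoprogression then response
# (G2), progression (G3) and late progression (G4). The MRI1->MRI2 growth
# factor distributions are shared between the two "growing" archetypes
# (G2/G3) and between the two "shrinking" ones (G1/G4), so that the
# baseline and on-therapy scans carry no label information by themselves —
# any classifier signal must come from deliberately injected image features
# (or, at delta = 0, from nowhere).

#' Archetype parameters for trajectory simulation
#'
#' Log-normal growth-factor distributions (median, log-sd) for the
#' MRI1->MRI2 (`f21`) and MRI2->MRI3 (`f32`) volume ratios, with the sign
#' of each interval fixed by truncation at 1, plus a complete-response
#' probability (direct responders only).
#'
#' @param archetype One of "direct_responder", "pseudoprogressor",
#'   "progressor", "late_progressor".
#' @param cr_prob Optional override of the complete-response probability.
#' @return Object of class `archetype_params`.
#' @export
archetype_params <- function(archetype = c("direct_responder",
                                           "pseudoprogressor",
                                           "progressor",
                                           "late_progressor"),
                             cr_prob = NULL) {
  archetype <- match.arg(archetype)
  p <- switch(archetype,
    direct_responder = list(f21_median = 0.70, f21_sdlog = 0.25, f21_up = FALSE,
                            f32_median = 0.35, f32_sdlog = 0.25, f32_up = FALSE,
                            cr_prob = 0.15, pattern = "G1"),
    pseudoprogressor = list(f21_median = 1.70, f21_sdlog = 0.25, f21_up = TRUE,
                            f32_median = 0.30, f32_sdlog = 0.25, f32_up = FALSE,
                            cr_prob = 0, pattern = "G2"),
    progressor       = list(f21_median = 1.70, f21_sdlog = 0.25, f21_up = TRUE,
                            f32_median = 1.80, f32_sdlog = 0.25, f32_up = TRUE,
                            cr_prob = 0, pattern = "G3"),
    late_progressor  = list(f21_median = 0.70, f21_sdlog = 0.25, f21_up = FALSE,
                            f32_median = 3.40, f32_sdlog = 0.30, f32_up = TRUE,
                            cr_prob = 0, pattern = "G4")
  )
  if (!is.null(cr_prob)) p$cr_prob <- cr_prob
  structure(c(list(archetype = archetype), p), class = "archetype_params")
}

# lognormal sample truncated to > 1 (up) or < 1 (down), by rejection
rtrunc_lnorm <- function(n, median, sdlog, up, max_tries = 1000) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (t in seq_len(max_tries)) {
      x <- rlnorm(1, meanlog = log(median), sdlog = sdlog)
      if ((up && x > 1) || (!up && x < 1)) break
      if (t == max_tries) {
        stop("archetype parameters inconsistent with the target sign pattern",
             call. = FALSE)
      }
    }
    out[i] <- x
  }
  out
}

#' Sample one volume trajectory from an archetype
#'
#' Draws a baseline volume and the two growth factors; by construction
#' (truncation of the growth factors at 1) the realized growth pattern
#' equals the archetype's target pattern. The MRI3 volume is capped at
#' `v3_cap` so that progressing lesions still fit the phantom grid.
#'
#' @param params An [archetype_params()].
#' @param seed Integer seed (deterministic output).
#' @param v1_median,v1_sdlog Baseline volume distribution (mm^3).
#' @param v1_range Truncation bounds for the baseline volume.
#' @param v3_cap Upper cap for the final volume (mm^3).
#' @return Tibble row with `v1`, `v2`, `v3`, `archetype`.
#' @export
sample_trajectory <- function(params, seed = 1L, v1_median = 1.3,
                              v1_sdlog = 0.3, v1_range = c(0.5, 4),
                              v3_cap = 20) {
  stopifnot(inherits(params, "archetype_params"))
  set.seed(seed)
  repeat {
    v1 <- rlnorm(1, log(v1_median), v1_sdlog)
    if (v1 >= v1_range[1] && v1 <= v1_range[2]) break
  }
  f21 <- rtrunc_lnorm(1, params$f21_median, params$f21_sdlog, params$f21_up)
  f32 <- rtrunc_lnorm(1, params$f32_median, params$f32_sdlog, params$f32_up)
  v2 <- v1 * f21
  v3 <- min(v2 * f32, v3_cap)
  if (params$cr_prob > 0 && runif(1) < params$cr_prob) v3 <- 0
  tibble::tibble(v1 = v1, v2 = v2, v3 = v3, archetype = params$archetype)
}
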