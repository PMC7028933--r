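# ggplot2 displays for the main result types.

#' Spider plot of volume trajectories colored by response call
#'
#' @param calls Output of [classify_response()] (needs `animal_id`).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(calls) {
  stopifnot(is.data.frame(calls), "category" %in% names(calls))
  if (!"animal_id" %in% names(calls)) {
    calls$animal_id <- sprintf("A%03d", seq_len(nrow(calls)))
  }
  long <- calls |>
    dplyr::select("animal_id", "category", "v1", "v2", "v3") |>
    tidyr::pivot_longer(c("v1", "v2", "v3"), names_to = "mri",
                        values_to = "volume") |>
    dplyr::mutate(mri = as.integer(sub("v", "", .data$mri)))
  ggplot2::ggplot(long, ggplot2::aes(.data$mri, .data$volume,
                                     group = .data$animal_id,
                                     color = .data$category)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::scale_x_continuous(breaks = 1:3,
                                labels = c("MRI1", "MRI2", "MRI3")) +
    ggplot2::labs(x = NULL, y = expression(volume ~ (mm^3)),
                  color = "response") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cohort_summary <- function(object, ...) {
  long <- object$by_arm |>
    tidyr::pivot_longer(dplyr::any_of(c("CR", "PR", "SD", "PD")),
                        names_to = "category", values_to = "count") |>
    dplyr::mutate(category = factor(.data$category,
                                    levels = c("CR", "PR", "SD", "PD")))
  ggplot2::ggplot(long, ggplot2::aes(.data$arm, .data$count,
                                     fill = .data$category)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::scale_y_continuous(labels = function(x) 100 * x) +
    ggplot2::labs(x = NULL, y = "% of animals", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.evaluation_report <- function(object, ...) {
  preds <- object$predictions
  thr <- sort(unique(c(-Inf, preds$prob, Inf)), decreasing = TRUE)
  roc <- dplyr::bind_rows(lapply(thr, function(t) {
    tibble::tibble(
      tpr = mean(preds$prob[preds$truth == 1] >= t),
      fpr = mean(preds$prob[preds$truth == 0] >= t)
    )
  }))
  ggplot2::ggplot(roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = 2, color = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUROC = %.3f", object$auroc)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.icb_boost <- function(object, top = 20, ...) {
  imp <- head(feature_importance(object), top)
  imp$feature <- factor(imp$feature, levels = rev(imp$feature))
  ggplot2::ggplot(imp, ggplot2::aes(.data$importance, .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "relative importance", y = NULL) +
    ggplot2::theme_minimal()
}
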