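# broom-style accessors and ggplot2 visualizations for the fitted objects.

#' @describeIn train_cv Per-fold accuracies as a tibble.
#' @param x,object An `lb_cv` object.
#' @param ... Unused.
#' @export
tidy.lb_cv <- function(x, ...) {
  tibble(fold = seq_along(x$fold_accuracies),
         accuracy = x$fold_accuracies)
}

#' @describeIn train_cv One-row cross-validation summary.
#' @export
glance.lb_cv <- function(x, ...) {
  tibble(k = x$k, mean_accuracy = x$mean_accuracy,
         sd_accuracy = x$sd_accuracy, auc = x$auc,
         n_features = length(x$features))
}

#' @export
print.lb_cv <- function(x, ...) {
  cat(sprintf(
    "<lb_cv> %d-fold CV: accuracy %.3f +/- %.3f, AUC %.3f (%d features)\n",
    x$k, x$mean_accuracy, x$sd_accuracy, x$auc, length(x$features)
  ))
  invisible(x)
}

#' @describeIn train_cv ROC curve of pooled held-out decision values.
#' @export
autoplot.lb_cv <- function(object, ...) {
  ggplot2::ggplot(object$roc_points,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_path(color = "#2166ac", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = "LB classification ROC (pooled held-out folds)",
      subtitle = sprintf("accuracy %.2f +/- %.2f, AUC %.2f",
                         object$mean_accuracy, object$sd_accuracy,
                         object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_final Model weights as a tibble (`feature, weight`),
#'   sorted by weight.
#' @param x,object An `lb_model`.
#' @param ... Unused.
#' @export
tidy.lb_model <- function(x, ...) {
  arrange(tibble(feature = x$features, weight = unname(x$w)),
          desc(.data$weight))
}

#' @describeIn fit_final One-row model summary.
#' @export
glance.lb_model <- function(x, ...) {
  tibble(n_features = length(x$features), intercept = x$b,
         w_norm = sqrt(sum(x$w^2)), C = x$C, n_train = x$n_train)
}

#' @export
print.lb_model <- function(x, ...) {
  cat(sprintf(
    "<lb_model> linear SVC over %d features (trained on %d rows)\n",
    length(x$features), x$n_train
  ))
  invisible(x)
}

#' @describeIn fit_final Diverging bar chart of model weights (positive =
#'   LB-predictive).
#' @export
autoplot.lb_model <- function(object, ...) {
  td <- tidy(object)
  td$feature <- factor(td$feature, levels = rev(td$feature))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$weight, y = .data$feature,
                                   fill = .data$weight > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac",
                                          `FALSE` = "#b2182b")) +
    ggplot2::labs(x = "Weight (positive = LB-predictive)", y = NULL,
                  title = "Linear SVC feature weights") +
    ggplot2::theme_minimal()
}

#' Plot the donor burden distribution by class
#'
#' Histogram of per-donor mutation counts colored by LB/HB class (log10
#' scale), the usual view of a median burden split.
#'
#' @param burdens Tibble from [split_burden_classes()].
#' @return A ggplot.
#' @export
plot_burden <- function(burdens) {
  stopifnot("burden_class" %in% names(burdens))
  ggplot2::ggplot(burdens,
                  ggplot2::aes(x = .data$n_mutations,
                               fill = .data$burden_class)) +
    ggplot2::geom_histogram(bins = 40, position = "identity", alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_fill_manual(values = c(LB = "#2166ac", HB = "#b2182b"),
                               name = "Class") +
    ggplot2::labs(x = "Somatic mutations per donor (log scale)",
                  y = "Donors", title = "Donor mutational burden split") +
    ggplot2::theme_minimal()
}

#' Plot score against log rank
#'
#' Hyperplane-distance (or standardized) score of ranked mutations against
#' log10 rank, colored coding/non-coding when annotation is available.
#'
#' @param scored Scored-mutation tibble ([score_mutations()] /
#'   [standardize_scores()]).
#' @return A ggplot.
#' @export
plot_score_rank <- function(scored) {
  score <- if ("std_score" %in% names(scored)) "std_score" else "raw_distance"
  p <- ggplot2::ggplot(scored,
                       ggplot2::aes(x = log10(.data$rank),
                                    y = .data[[score]]))
  if ("coding" %in% names(scored)) {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(color = ifelse(.data$coding %in% TRUE, "coding",
                                  "non-coding")),
      size = 0.6, alpha = 0.6
    ) +
      ggplot2::scale_color_manual(values = c(coding = "#1b7837",
                                             `non-coding` = "grey50"),
                                  name = NULL)
  } else {
    p <- p + ggplot2::geom_point(size = 0.6, alpha = 0.6, color = "grey30")
  }
  p + ggplot2::labs(x = "log10 rank", y = "Score",
                    title = "Mutation scores by rank") +
    ggplot2::theme_minimal()
}

#' @describeIn summarize_panel Consequence composition chart colored by
#'   impact tier.
#' @param object A `panel_summary`.
#' @param ... Unused.
#' @export
autoplot.panel_summary <- function(object, ...) {
  cc <- object$consequences
  if (nrow(cc) == 0) {
    abort("Panel summary has no consequence annotation to plot.")
  }
  cc$consequence <- factor(cc$consequence,
                           levels = rev(cc$consequence[order(cc$n)]))
  has_imp <- "impact" %in% names(cc)
  p <- ggplot2::ggplot(cc, ggplot2::aes(x = .data$n,
                                        y = .data$consequence))
  if (has_imp) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$impact)) +
      ggplot2::scale_fill_manual(values = c(
        HIGH = "#b2182b", MODERATE = "#ef8a62", LOW = "#fddbc7",
        MODIFIER = "#67a9cf"
      ), name = "Impact")
  } else {
    p <- p + ggplot2::geom_col(fill = "#67a9cf")
  }
  p + ggplot2::labs(x = "Panel mutations", y = NULL,
                    title = "Panel composition by consequence") +
    ggplot2::theme_minimal()
}

#' Plot the allele-fraction distribution of detected cfDNA variants
#'
#' Histogram of detected allele fractions with the germline bound marked.
#'
#' @param detected Detected-variant tibble with `allele_fraction`.
#' @param germline_af_max Germline bound to mark (default 0.20).
#' @return A ggplot.
#' @export
plot_af_distribution <- function(detected, germline_af_max = 0.20) {
  ggplot2::ggplot(detected, ggplot2::aes(x = .data$allele_fraction)) +
    ggplot2::geom_histogram(bins = 50, fill = "#2166ac") +
    ggplot2::geom_vline(xintercept = germline_af_max,
                        linetype = "dashed", color = "#b2182b") +
    ggplot2::labs(x = "Allele fraction", y = "Variants",
                  title = "Detected cfDNA variant allele fractions",
                  subtitle = sprintf("germline bound at %.0f%%",
                                     100 * germline_af_max)) +
    ggplot2::theme_minimal()
}
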