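# broom-style tidiers and ggplot2 autoplot methods for the package's
# result objects.

#' @export
#' @method tidy principal_curve_fit
tidy.principal_curve_fit <- function(x, ...) {
  tibble(row = seq_along(x$lambda), lambda = x$lambda,
         pds = (x$lambda - min(x$lambda)) /
           max(x$total_length, .Machine$double.eps))
}

#' @export
#' @method glance principal_curve_fit
glance.principal_curve_fit <- function(x, ...) {
  tibble(d = x$d, total_length = x$total_length, sse = x$sse,
         converged = x$converged, n_iterations = x$n_iterations)
}

#' @export
#' @method tidy pds_tbl
tidy.pds_tbl <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(as.data.frame(x)), -"sample_id",
                      names_to = "pathway", values_to = "pds")
}

#' @export
#' @method glance pds_tbl
glance.pds_tbl <- function(x, ...) {
  d <- pds_diagnostics(x)
  tibble(n_samples = nrow(x), n_pathways = sum(!d$dropped),
         n_dropped = sum(d$dropped),
         n_converged = sum(d$converged, na.rm = TRUE))
}

#' @export
#' @method tidy consensus_selection
tidy.consensus_selection <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' @export
#' @method glance consensus_selection
glance.consensus_selection <- function(x, ...) {
  tibble(n_features = nrow(x), n_retained = sum(x$retained),
         n_folds = attr(x, "n_folds"))
}

#' @export
#' @method tidy pds_classifier
tidy.pds_classifier <- function(x, ...) {
  if (x$kind != "logistic") {
    abort("coefficient tidying is only defined for logistic models")
  }
  tibble(term = c("(Intercept)", names(x$fit$coefficients)),
         estimate = c(x$fit$intercept, unname(x$fit$coefficients)))
}

#' @export
#' @method glance pds_classifier
glance.pds_classifier <- function(x, ...) {
  tibble(kind = x$kind, n_features = length(x$features),
         lambda = x$lambda, seed = x$seed)
}

#' @export
#' @method tidy evaluation_report
tidy.evaluation_report <- function(x, ...) {
  tidyr::pivot_longer(
    as_tibble(as.data.frame(x))[c("dataset", "auc", "sensitivity",
                                  "specificity", "mcc", "f1")],
    -"dataset", names_to = "metric", values_to = "value")
}

#' @export
#' @method glance evaluation_report
glance.evaluation_report <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' @export
#' @method tidy pds_run
tidy.pds_run <- function(x, ...) {
  as_tibble(as.data.frame(x$reports))
}

#' @export
#' @method glance pds_run
glance.pds_run <- function(x, ...) {
  tibble(classifier = x$config$classifier, baseline = x$baseline,
         n_retained = length(x$features),
         train_auc = x$reports$auc[x$reports$dataset == "train"][1])
}

#' ROC curve of an evaluation report
#'
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot evaluation_report
autoplot.evaluation_report <- function(object, ...) {
  roc <- attr(object, "roc")
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("%s (AUC = %.3f)", object$dataset[1],
                                  object$auc[1])) +
    ggplot2::theme_minimal()
}

#' ROC curves of a pipeline run, one per dataset
#'
#' @param object A `pds_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot pds_run
autoplot.pds_run <- function(object, ...) {
  roc <- dplyr::bind_rows(lapply(names(object$rocs), function(nm) {
    dplyr::bind_cols(tibble(dataset = nm), object$rocs[[nm]])
  }))
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    colour = .data$dataset)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' PDS distributions per pathway and class
#'
#' Boxplots of the pathway dysregulation scores, split by case/control
#' status, for visual inspection of which pathways separate the
#' classes.
#'
#' @param object A `pds_tbl` from [compute_pds()].
#' @param labels Label table (`sample_id`, `class`); optional.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot pds_tbl
autoplot.pds_tbl <- function(object, labels = NULL, ...) {
  long <- tidy.pds_tbl(object)
  if (!is.null(labels)) {
    long <- dplyr::left_join(
      long, dplyr::select(as_tibble(labels), "sample_id", "class"),
      by = "sample_id")
    p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$pathway,
                                            y = .data$pds,
                                            fill = .data$class))
  } else {
    p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$pathway,
                                            y = .data$pds))
  }
  p + ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "Pathway dysregulation score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' Consensus selection frequencies
#'
#' @param object A `consensus_selection`.
#' @param ... Unused.
#' @return A ggplot of per-feature fold-selection counts.
#' @export
#' @method autoplot consensus_selection
autoplot.consensus_selection <- function(object, ...) {
  d <- as_tibble(as.data.frame(object))
  d <- d[d$frequency > 0, , drop = FALSE]
  d$feature <- stats::reorder(d$feature, d$frequency)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$feature, y = .data$frequency,
                                  fill = .data$retained)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Folds selected") +
    ggplot2::theme_minimal()
}
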