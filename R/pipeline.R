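# End-to-end orchestration: train/test splits, pathway and metabolite
# models, sensitivity analysis, classifier comparison.

#' Pipeline configuration
#'
#' Collects every tunable knob of the pipeline with its default.  One
#' `seed` drives the split, the cross-validation folds, and the
#' stochastic learners, so a full run is a deterministic function of
#' (data, config).
#'
#' @param min_size Minimum measured members per usable pathway.
#' @param variance_kept,pc_cap,spar,tol,max_iter,fit_on,log_transform
#'   PDS controls, see [compute_pds()].
#' @param n_folds,stale_limit Consensus CFS controls, see
#'   [consensus_select()].
#' @param mi_bins Mutual-information bin count.
#' @param ridge_lambda Ridge penalty of the logistic fits.
#' @param threshold Probability cutoff for the confusion metrics.
#' @param classifier Headline classifier kind.
#' @param train_fraction Per-class training fraction of the split.
#' @param stage_filter Optional subset of `c("I","II","III","IV")`:
#'   restrict training cases to these tumor stages (controls are always
#'   kept), e.g. `c("I", "II")` for an early-stage model.
#' @param seed Master integer seed.
#' @return A `pds_config` list.
#' @export
pds_config <- function(min_size = 3L, variance_kept = 0.9, pc_cap = 5L,
                       spar = 0.75, tol = 1e-4, max_iter = 50L,
                       fit_on = "all", log_transform = TRUE,
                       n_folds = 10L, stale_limit = 5L,
                       mi_bins = 4L, ridge_lambda = 1e-4, threshold = 0.5,
                       classifier = "logistic", train_fraction = 0.8,
                       stage_filter = NULL, seed = 1L) {
  structure(list(min_size = min_size, variance_kept = variance_kept,
                 pc_cap = pc_cap, spar = spar, tol = tol,
                 max_iter = max_iter, fit_on = fit_on,
                 log_transform = log_transform, n_folds = n_folds,
                 stale_limit = stale_limit, mi_bins = mi_bins,
                 ridge_lambda = ridge_lambda, threshold = threshold,
                 classifier = classifier, train_fraction = train_fraction,
                 stage_filter = stage_filter, seed = as.integer(seed)),
            class = "pds_config")
}

#' Class-stratified train/test split
#'
#' Each class is shuffled with the seed and split with round-to-nearest
#' training counts: 132 cases and 76 controls at 80 % give 106 + 61
#' training and 26 + 15 test samples.
#'
#' @param labels Label table (`sample_id`, `class`).
#' @param train_fraction Training fraction per class (default 0.8).
#' @param seed Integer seed for the shuffle.
#' @return Tibble (`sample_id`, `class`, `split`) with
#'   `split %in% c("train", "test")`; per class,
#'   `n_train = round(train_fraction * n)` (half-up).
#' @export
split_cohort <- function(labels, train_fraction = 0.8, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction <= 1)
  y01 <- as_case01(labels$class)
  if (length(unique(y01)) < 2L) abort("both classes must be present")
  if (min(table(y01)) < 2L) abort("each class needs at least 2 samples")
  set.seed(seed)
  split <- character(nrow(labels))
  for (cl in c(1L, 0L)) {
    idx <- which(y01 == cl)
    n_train <- floor(train_fraction * length(idx) + 0.5)
    shuffled <- sample(idx)
    split[shuffled] <- c(rep("train", n_train),
                         rep("test", length(idx) - n_train))
  }
  if (!any(split == "test")) warn("empty test set (train_fraction = 1?)")
  tibble(sample_id = as.character(labels$sample_id),
         class = labels$class, split = split)
}

# Internal: subset an abundance/label pair to given sample ids.
subset_samples <- function(abundance, labels, ids) {
  list(abundance = abundance[match(ids, abundance$sample_id), , drop = FALSE],
       labels = labels[match(ids, labels$sample_id), , drop = FALSE])
}

# Internal: z-scored (median-imputed) metabolite feature table for the
# baseline model; mirrors the PDS preprocessing (including the log
# transform of positive intensities) without reduction.
zscore_features <- function(abundance, log_transform = TRUE) {
  m <- feature_matrix(abundance)
  if (log_transform && all(m > 0, na.rm = TRUE)) m <- log(m)
  for (j in seq_len(ncol(m))) {
    miss <- is.na(m[, j])
    if (all(miss)) m[, j] <- 0
    else if (any(miss)) m[miss, j] <- median(m[!miss, j])
  }
  sds <- apply(m, 2L, sd)
  keep <- sds > 0
  z <- scale(m[, keep, drop = FALSE])
  dplyr::bind_cols(tibble(sample_id = rownames(m)),
                   as_tibble(as.data.frame(z)))
}

# Internal: consensus CFS + classifier + per-dataset evaluation on
# already-built feature tables.  `tests` is a named list of
# (features tibble, y) pairs.
fit_and_evaluate <- function(X_train, y_train, tests, config) {
  sel <- consensus_select(X_train, y_train, n_folds = config$n_folds,
                          seed = config$seed,
                          stale_limit = config$stale_limit)
  feats <- retained_features(sel)
  model <- train_classifier(X_train, y_train, kind = config$classifier,
                            features = feats,
                            lambda = config$ridge_lambda,
                            seed = config$seed)
  for (nm in names(tests)) {
    missing <- setdiff(feats, colnames(selection_matrix(tests[[nm]]$X)))
    if (length(missing) > 0L) {
      abort(paste0("retained feature '", missing[1],
                   "' is not usable in test set '", nm, "'"))
    }
  }
  reports <- list(evaluate_classifier(model, X_train, y_train,
                                      threshold = config$threshold,
                                      dataset = "train"))
  for (nm in names(tests)) {
    reports[[length(reports) + 1L]] <-
      evaluate_classifier(model, tests[[nm]]$X, tests[[nm]]$y,
                          threshold = config$threshold, dataset = nm)
  }
  rocs <- lapply(reports, attr, "roc")
  reports <- dplyr::bind_rows(reports)
  names(rocs) <- reports$dataset
  list(model = model, selection = sel, reports = reports, rocs = rocs)
}

# Internal: build the feature table for one dataset (PDS or baseline
# metabolite z-scores), with the dataset's own controls.
dataset_features <- function(abundance, labels, pathways, config,
                             baseline = FALSE) {
  lab <- align_labels(labels, as.character(abundance$sample_id))
  X <- if (baseline) {
    zscore_features(abundance, log_transform = config$log_transform)
  } else {
    compute_pds(abundance, lab, pathways,
                min_size = config$min_size,
                variance_kept = config$variance_kept,
                pc_cap = config$pc_cap, spar = config$spar,
                tol = config$tol, max_iter = config$max_iter,
                fit_on = config$fit_on,
                log_transform = config$log_transform)
  }
  list(X = X, y = lab$class)
}

#' Run the pathway-based diagnostic pipeline
#'
#' End-to-end study design on pre-split data: compute the PDS matrix of
#' the training set, select pathway features by consensus CFS on the
#' training set only, fit the classifier on the training set only, and
#' evaluate on the training set plus each test set.  Each test set's
#' PDS matrix is computed independently within that dataset, using its
#' own controls, and the retained pathway features are then extracted
#' from it; a retained pathway missing from a test set's usable
#' pathways is an error naming that pathway.
#'
#' With `baseline = TRUE` the identical selection + classification
#' machinery runs on z-scored metabolite columns instead of PDS
#' columns: the metabolite-based comparison model.
#'
#' @param train List with `abundance` and `labels` (the training
#'   dataset).
#' @param test_sets Named list of similar lists; each needs at least two
#'   controls of its own.
#' @param pathways Pathway map tibble ([read_gmt()]).
#' @param config A [pds_config()].
#' @param baseline Use metabolite columns instead of PDS columns.
#' @return An object of class `pds_run`: list with `model`
#'   (`pds_classifier`), `selection` (`consensus_selection`),
#'   `features`, `mi` (mutual-information ranking of the retained
#'   features on the training data), `reports` (tibble, one row per
#'   dataset), `rocs`, and `config`.
#' @export
run_model <- function(train, test_sets = list(), pathways,
                      config = pds_config(), baseline = FALSE) {
  stopifnot(is.list(train), !is.null(train$abundance), !is.null(train$labels))
  if (length(test_sets) > 0L && is.null(names(test_sets))) {
    names(test_sets) <- paste0("test", seq_along(test_sets))
  }
  train_lab <- train$labels
  if (!is.null(config$stage_filter)) {
    keep <- as_case01(train_lab$class) == 0L |
      train_lab$stage %in% config$stage_filter
    ids <- as.character(train_lab$sample_id)[keep]
    train <- subset_samples(train$abundance, train_lab, ids)
  }
  tr <- dataset_features(train$abundance, train$labels, pathways, config,
                         baseline = baseline)
  tests <- lapply(test_sets, function(ts) {
    dataset_features(ts$abundance, ts$labels, pathways, config,
                     baseline = baseline)
  })
  res <- fit_and_evaluate(tr$X, tr$y, tests, config)
  feats <- res$model$features
  mi <- if (length(feats) > 0L) {
    rank_features_mi(selection_matrix(tr$X)[, feats, drop = FALSE],
                     tr$y, bins = config$mi_bins)
  } else tibble(feature = character(0), mi = numeric(0))
  structure(list(model = res$model, selection = res$selection,
                 features = feats, mi = mi, reports = res$reports,
                 rocs = res$rocs, config = config, baseline = baseline,
                 train_features = tr, test_features = tests),
            class = "pds_run")
}

#' @export
print.pds_run <- function(x, ...) {
  cat(sprintf("<pds_run> %s model, %d retained feature(s)%s\n",
              x$config$classifier, length(x$features),
              if (x$baseline) " [metabolite baseline]" else ""))
  print(as.data.frame(x$reports[, c("dataset", "n", "auc", "sensitivity",
                                    "specificity", "mcc", "f1")]),
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Metabolite-based baseline model
#'
#' Convenience wrapper: [run_model()] with `baseline = TRUE`, i.e. the
#' identical consensus CFS + classifier machinery applied to z-scored
#' metabolite columns for a head-to-head comparison with the
#' pathway-based model.
#'
#' @inheritParams run_model
#' @return A `pds_run`.
#' @export
run_baseline_metabolite_model <- function(train, test_sets = list(),
                                          pathways,
                                          config = pds_config()) {
  run_model(train, test_sets, pathways, config, baseline = TRUE)
}

#' Pathway-count sensitivity analysis
#'
#' Re-runs feature selection and classification on a random subset of
#' the usable pathways (default: half of them) within exactly the same
#' training samples, and reports the per-dataset AUC change against the
#' full-pathway run.  The PDS matrices are reused; only the candidate
#' feature pool shrinks.
#'
#' @param run A full-pathway `pds_run` (pathway-based, not baseline).
#' @param fraction Fraction of usable pathways to keep, in `(0, 1)`.
#' @param round_mode `"nearest"` (default), `"floor"`, or `"ceil"` for
#'   the kept-pathway count; at 0.5 of 101 pathways these give 51, 50,
#'   and 51.
#' @param seed Integer seed for the pathway draw.
#' @param keep Optional explicit pathway subset (overrides the random
#'   draw; `fraction` is then ignored).
#' @return List with `kept_pathways`, the reduced-run `pds_run`
#'   (`reduced`), and `comparison`: tibble (`dataset`, `auc_full`,
#'   `auc_reduced`, `delta_auc`).
#' @export
sensitivity_analysis <- function(run, fraction = 0.5,
                                 round_mode = c("nearest", "floor", "ceil"),
                                 seed = 1L, keep = NULL) {
  stopifnot(inherits(run, "pds_run"))
  if (run$baseline) abort("sensitivity analysis applies to pathway runs")
  round_mode <- match.arg(round_mode)
  pool <- setdiff(colnames(selection_matrix(run$train_features$X)),
                  "sample_id")
  if (length(pool) < 4L) abort("at least 4 usable pathways are required")
  if (is.null(keep)) {
    if (fraction <= 0 || fraction >= 1) {
      abort("fraction must lie strictly between 0 and 1")
    }
    n_keep <- switch(round_mode,
                     nearest = floor(fraction * length(pool) + 0.5),
                     floor = floor(fraction * length(pool)),
                     ceil = ceiling(fraction * length(pool)))
    set.seed(seed)
    keep <- sort(sample(pool, n_keep))
  } else {
    keep <- intersect(pool, keep)
    if (length(keep) == 0L) abort("no kept pathway is usable")
  }
  subset_X <- function(X) {
    dplyr::select(as_tibble(X), dplyr::all_of(c("sample_id", keep)))
  }
  tests <- lapply(run$test_features, function(ts) {
    list(X = subset_X(ts$X), y = ts$y)
  })
  res <- fit_and_evaluate(subset_X(run$train_features$X),
                          run$train_features$y, tests, run$config)
  reduced <- structure(
    list(model = res$model, selection = res$selection,
         features = res$model$features, mi = NULL, reports = res$reports,
         rocs = res$rocs, config = run$config, baseline = FALSE,
         train_features = list(X = subset_X(run$train_features$X),
                               y = run$train_features$y),
         test_features = tests),
    class = "pds_run")
  comparison <- dplyr::inner_join(
    dplyr::select(run$reports, dataset = "dataset", auc_full = "auc"),
    dplyr::select(res$reports, dataset = "dataset", auc_reduced = "auc"),
    by = "dataset")
  comparison$delta_auc <- comparison$auc_reduced - comparison$auc_full
  list(kept_pathways = keep, reduced = reduced, comparison = comparison)
}

#' Compare the three classifier kinds on the same features
#'
#' Trains logistic regression, SVM, and random forest on the same
#' retained features and reports the metric suite per classifier and
#' dataset.
#'
#' @inheritParams run_model
#' @return Tibble of evaluation rows with a leading `classifier` column.
#' @export
compare_classifiers <- function(train, test_sets = list(), pathways,
                                config = pds_config()) {
  out <- list()
  for (kind in c("logistic", "svm", "random_forest")) {
    cfg <- config
    cfg$classifier <- kind
    run <- run_model(train, test_sets, pathways, cfg)
    out[[kind]] <- dplyr::bind_cols(tibble(classifier = kind), run$reports)
  }
  dplyr::bind_rows(out)
}
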