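# From abundance submatrix to pathway dysregulation scores.

#' Preprocess a pathway submatrix for curve fitting
#'
#' Optional log transform of positive intensities, per-metabolite
#' median imputation of missing values, z-scoring over all samples,
#' then projection onto the leading principal components: the smallest
#' dimension whose cumulative explained variance reaches
#' `variance_kept`, capped at `min(n_metabolites, n_samples - 1,
#' pc_cap)`.
#'
#' Mass-spectrometry intensities are approximately log-normal, so the
#' higher-level [compute_pds()] log-transforms by default; this
#' low-level numeric routine leaves it off unless asked.
#'
#' @param x Numeric matrix (samples x metabolites), `NA` = missing.
#' @param variance_kept Cumulative explained-variance target (default
#'   0.90).
#' @param pc_cap Hard cap on the retained dimension (default 5).
#' @param log_transform Log the values before imputation (requires all
#'   observed values strictly positive; default `FALSE` here).
#' @return Numeric matrix of principal-component scores (samples x d)
#'   with attribute `"explained_variance"` (per retained component).
#' @export
preprocess_pathway_submatrix <- function(x, variance_kept = 0.9, pc_cap = 5L,
                                         log_transform = FALSE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 6L) abort("at least 6 samples are required")
  if (log_transform) {
    if (any(x <= 0, na.rm = TRUE)) {
      abort("log_transform requires strictly positive intensities")
    }
    x <- log(x)
  }
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (all(miss)) {
      abort(paste0("metabolite column ", j, " entirely missing"))
    }
    if (any(miss)) x[miss, j] <- median(x[!miss, j])
  }
  sds <- apply(x, 2L, sd)
  if (all(sds == 0)) {
    abort("degenerate pathway: all metabolites have zero variance",
          class = "pdsdiag_degenerate")
  }
  if (any(sds == 0)) {
    warn(sprintf("dropping %d zero-variance metabolite(s)", sum(sds == 0)))
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  z <- scale(x)
  p <- prcomp(z, center = FALSE, scale. = FALSE)
  # standardize component signs (largest-magnitude loading positive) so
  # the reduced coordinates do not depend on sample order
  for (j in seq_len(ncol(p$rotation))) {
    pivot <- which.max(abs(p$rotation[, j]))
    if (p$rotation[pivot, j] < 0) p$x[, j] <- -p$x[, j]
  }
  ev <- p$sdev^2 / sum(p$sdev^2)
  d_max <- min(ncol(z), n - 1L, pc_cap)
  cum <- cumsum(ev)
  d <- which(cum >= variance_kept - 1e-12)[1]
  if (is.na(d)) d <- d_max
  d <- max(1L, min(d, d_max))
  out <- p$x[, seq_len(d), drop = FALSE]
  attr(out, "explained_variance") <- ev[seq_len(d)]
  out
}

#' Compute the pathway dysregulation score matrix
#'
#' For every usable pathway, the measured-member submatrix is imputed,
#' z-scored and reduced (see [preprocess_pathway_submatrix()]), a
#' smoothed principal curve is fitted, and each sample is scored by its
#' normalized arc-length projection, oriented so controls sit near the
#' curve start.  The result is the samples-by-pathways PDS matrix in
#' `[0, 1]`: the pipeline's central exchange object.
#'
#' By default the curve is fitted on all samples and the controls are
#' used only to orient it; `fit_on = "controls"` instead fits the curve
#' on controls only and projects every sample onto it.
#'
#' @param abundance Samples-by-metabolites data frame (first column
#'   `sample_id`, metabolite columns named by HMDB ID, `NA` = missing).
#' @param labels Data frame with columns `sample_id` and `class`
#'   (`"case"`/`"control"`); at least two controls.
#' @param pathways Either a pathway map from [read_gmt()] or a mapped
#'   set from [map_pathways()].
#' @param min_size Minimum measured members per pathway (used when
#'   `pathways` is an unmapped pathway map).
#' @param log_transform Log the intensities before z-scoring (default
#'   `TRUE`; requires strictly positive observed values, the normal
#'   situation for MS abundance data).
#' @param variance_kept,pc_cap Dimension-reduction controls, see
#'   [preprocess_pathway_submatrix()].
#' @param spar,tol,max_iter Curve-fitting controls, see
#'   [fit_principal_curve()].
#' @param fit_on `"all"` (default) or `"controls"`.
#' @return A tibble (class `pds_tbl`) with `sample_id` plus one column
#'   per surviving pathway, every entry in `[0, 1]` with per-pathway min
#'   0 and max 1.  Per-pathway fit diagnostics (dimension, sse,
#'   convergence, orientation, drop reasons) are attached as attribute
#'   `"diagnostics"`; see [pds_diagnostics()].
#' @export
compute_pds <- function(abundance, labels, pathways, min_size = 3L,
                        variance_kept = 0.9, pc_cap = 5L, spar = 0.75,
                        tol = 1e-4, max_iter = 50L,
                        fit_on = c("all", "controls"),
                        log_transform = TRUE) {
  fit_on <- match.arg(fit_on)
  m <- feature_matrix(abundance)
  # canonical sample order: the scores are computed on id-sorted rows and
  # mapped back, so permuting the input rows permutes the output exactly
  input_ids <- rownames(m)
  m <- m[order(input_ids), , drop = FALSE]
  lab <- align_labels(labels, rownames(m))
  is_control <- as_case01(lab$class) == 0L
  if (sum(is_control) < 2L) abort("at least 2 control samples are required")
  mapped <- if (inherits(pathways, "mapped_pathways")) pathways
            else map_pathways(abundance, pathways, min_size = min_size)
  use <- mapped[mapped$usable, , drop = FALSE]
  if (nrow(use) == 0L) abort("no usable pathway")
  scores <- list()
  diag_rows <- list()
  for (i in seq_len(nrow(use))) {
    pw <- use$pathway[i]
    cols <- use$metabolites[[i]]
    res <- tryCatch({
      red <- preprocess_pathway_submatrix(m[, cols, drop = FALSE],
                                          variance_kept, pc_cap,
                                          log_transform = log_transform)
      if (fit_on == "controls") {
        fit <- fit_principal_curve(red[is_control, , drop = FALSE],
                                   spar = spar, tol = tol,
                                   max_iter = max_iter)
        lam <- if (fit$d == 1L) red[, 1] else
          project_polyline(red, fit$curve_points)$lambda
      } else {
        fit <- fit_principal_curve(red, spar = spar, tol = tol,
                                   max_iter = max_iter)
        lam <- fit$lambda
      }
      pds <- score_pathway(lam, is_control)
      list(pds = pds, d = ncol(red), fit = fit,
           orientation = attr(pds, "orientation"))
    }, pdsdiag_degenerate = function(e) e)
    if (inherits(res, "error")) {
      diag_rows[[pw]] <- tibble(
        pathway = pw, n_metabolites = length(cols), d = NA_integer_,
        sse = NA_real_, n_iterations = NA_integer_, converged = NA,
        orientation = NA_real_, dropped = TRUE,
        reason = conditionMessage(res))
    } else {
      scores[[pw]] <- as.numeric(res$pds)
      diag_rows[[pw]] <- tibble(
        pathway = pw, n_metabolites = length(cols), d = res$d,
        sse = res$fit$sse, n_iterations = res$fit$n_iterations,
        converged = res$fit$converged, orientation = res$orientation,
        dropped = FALSE, reason = NA_character_)
    }
  }
  if (length(scores) == 0L) {
    abort("no pathway survived PDS computation")
  }
  back <- match(input_ids, rownames(m))
  out <- tibble(sample_id = input_ids)
  for (pw in names(scores)) out[[pw]] <- scores[[pw]][back]
  attr(out, "diagnostics") <- dplyr::bind_rows(diag_rows)
  class(out) <- c("pds_tbl", class(out))
  out
}

# Internal: align a label table to a given sample order.
align_labels <- function(labels, sample_ids) {
  stopifnot(is.data.frame(labels),
            all(c("sample_id", "class") %in% names(labels)))
  idx <- match(sample_ids, as.character(labels$sample_id))
  if (anyNA(idx)) {
    abort(paste0("no label for sample ", sample_ids[which(is.na(idx))[1]]))
  }
  labels[idx, , drop = FALSE]
}

#' Per-pathway fit diagnostics of a PDS matrix
#'
#' @param pds A `pds_tbl` from [compute_pds()].
#' @return Tibble with one row per attempted pathway: reduced dimension,
#'   projection sse, iteration count, convergence and orientation flags,
#'   and the drop reason for pathways that failed.
#' @export
pds_diagnostics <- function(pds) {
  d <- attr(pds, "diagnostics")
  if (is.null(d)) abort("not a pds_tbl: no diagnostics attribute")
  d
}

#' Write a PDS matrix and its diagnostics
#'
#' @param pds A `pds_tbl`.
#' @param path Output CSV path; diagnostics go to `<path>.diagnostics.tsv`.
#' @return `path`, invisibly.
#' @export
write_pds <- function(pds, path) {
  readr::write_csv(as_tibble(as.data.frame(pds)), path, progress = FALSE)
  readr::write_tsv(pds_diagnostics(pds),
                   paste0(path, ".diagnostics.tsv"), progress = FALSE)
  invisible(path)
}
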