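# Correlation-based feature selection (CFS) over PDS (or metabolite)
# columns, with best-first search and cross-validation consensus.

# Internal: absolute feature-class and feature-feature Pearson
# correlations; zero-variance features get correlation 0 by convention.
cfs_correlations <- function(X, y01) {
  suppressWarnings({
    rcf <- abs(as.numeric(cor(X, y01)))
    rff <- abs(cor(X))
  })
  rcf[is.na(rcf)] <- 0
  rff[is.na(rff)] <- 0
  diag(rff) <- 1
  list(rcf = rcf, rff = rff)
}

merit_value <- function(rcf, rff, subset) {
  k <- length(subset)
  if (k == 0L) return(0)
  mcf <- mean(rcf[subset])
  mff <- if (k > 1L) {
    s <- rff[subset, subset, drop = FALSE]
    mean(s[lower.tri(s)])
  } else 0
  k * mcf / sqrt(k + k * (k - 1) * mff)
}

#' CFS merit of a feature subset
#'
#' merit(S) = k * mean|r_cf| / sqrt(k + k (k - 1) * mean|r_ff|), where
#' r_cf are (point-biserial) feature-class correlations of the k subset
#' members and r_ff their pairwise correlations: high class relevance is
#' rewarded, within-subset redundancy is penalized.  For a single
#' feature the merit is its |r_cf|.
#'
#' @param X Samples-by-features data frame or matrix (a `sample_id`
#'   column is ignored).
#' @param y Class labels (`"case"`/`"control"`, logical, or 0/1).
#' @param subset Feature names or column indices (non-empty).
#' @return One-row tibble: `k`, `r_cf_mean`, `r_ff_mean`, `merit`.
#' @export
cfs_merit <- function(X, y, subset) {
  X <- selection_matrix(X)
  y01 <- as_case01(y)
  if (!all(y01 %in% c(0, 1)) || length(unique(y01)) < 2L) {
    abort("both classes must be present")
  }
  if (is.character(subset)) subset <- match(subset, colnames(X))
  if (length(subset) == 0L || anyNA(subset)) abort("invalid feature subset")
  co <- cfs_correlations(X, y01)
  k <- length(subset)
  mff <- if (k > 1L) {
    s <- co$rff[subset, subset, drop = FALSE]
    mean(s[lower.tri(s)])
  } else 0
  tibble(k = k, r_cf_mean = mean(co$rcf[subset]), r_ff_mean = mff,
         merit = merit_value(co$rcf, co$rff, subset))
}

# Internal: strip a sample_id column and coerce to matrix.
selection_matrix <- function(X) {
  if (is.data.frame(X)) {
    if ("sample_id" %in% names(X)) return(feature_matrix(X, "feature table"))
    X <- as.matrix(X)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  X
}

#' Best-first CFS subset search
#'
#' Forward best-first search over feature subsets maximizing the CFS
#' merit: the highest-merit open subset is expanded by each absent
#' feature; the search stops after `stale_limit` consecutive expansions
#' that fail to improve the best merit found.  Ties are broken toward
#' the lower feature index, so the search is deterministic.
#'
#' @inheritParams cfs_merit
#' @param stale_limit Consecutive non-improving expansions tolerated
#'   (default 5, the conventional best-first backtrack allowance).
#' @param max_expansions Safety cap on node expansions (default 5000).
#' @return Character vector of selected feature names (possibly empty,
#'   with a warning, when every feature has zero variance), with the
#'   attained merit as attribute `"merit"`.
#' @export
cfs_search <- function(X, y, stale_limit = 5L, max_expansions = 5000L) {
  X <- selection_matrix(X)
  y01 <- as_case01(y)
  p <- ncol(X)
  if (p < 1L) abort("at least one feature is required")
  co <- cfs_correlations(X, y01)
  if (all(co$rcf == 0)) {
    warn("all features are uninformative (zero correlation with the class)")
    return(structure(character(0), merit = 0))
  }
  key <- function(s) paste0("s", paste(s, collapse = ","))
  visited <- new.env(parent = emptyenv())
  open_sets <- list(integer(0))
  open_merit <- 0
  assign(key(integer(0)), TRUE, envir = visited)
  best_set <- integer(0)
  best_merit <- 0
  stale <- 0L
  expansions <- 0L
  while (length(open_sets) > 0L && stale < stale_limit &&
         expansions < max_expansions) {
    i <- which.max(open_merit)  # first maximum -> lower-index tie-break
    node <- open_sets[[i]]
    open_sets[[i]] <- NULL
    open_merit <- open_merit[-i]
    expansions <- expansions + 1L
    improved <- FALSE
    for (f in setdiff(seq_len(p), node)) {
      child <- sort(c(node, f))
      k <- key(child)
      if (!is.null(visited[[k]])) next
      assign(k, TRUE, envir = visited)
      mer <- merit_value(co$rcf, co$rff, child)
      open_sets[[length(open_sets) + 1L]] <- child
      open_merit <- c(open_merit, mer)
      if (mer > best_merit + 1e-12) {
        best_merit <- mer
        best_set <- child
        improved <- TRUE
      }
    }
    stale <- if (improved) 0L else stale + 1L
  }
  structure(colnames(X)[best_set], merit = best_merit)
}

#' Cross-validation consensus CFS
#'
#' Splits the training samples into `n_folds` class-stratified folds,
#' runs [cfs_search()] on each set of `n_folds - 1` folds, and retains
#' only the features selected in every single run (the "ten out of ten"
#' rule for the default ten folds).
#'
#' @inheritParams cfs_search
#' @param n_folds Number of folds (default 10); each class must have at
#'   least `n_folds` samples.
#' @param seed Integer seed for the stratified fold assignment.
#' @return An object of class `consensus_selection`: tibble with one row
#'   per feature (`feature`, `frequency` in `0..n_folds`, `retained`),
#'   with the per-fold subsets in attribute `"per_fold"`.
#' @export
consensus_select <- function(X, y, n_folds = 10L, seed = 1L,
                             stale_limit = 5L) {
  X <- selection_matrix(X)
  y01 <- as_case01(y)
  if (length(unique(y01)) < 2L || min(table(y01)) < n_folds) {
    abort(sprintf("each class needs >= %d samples for %d-fold stratification",
                  n_folds, n_folds))
  }
  fold <- integer(length(y01))
  set.seed(seed)
  for (cl in c(0L, 1L)) {
    idx <- which(y01 == cl)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  per_fold <- lapply(seq_len(n_folds), function(i) {
    tr <- fold != i
    as.character(cfs_search(X[tr, , drop = FALSE], y01[tr],
                            stale_limit = stale_limit))
  })
  freq <- vapply(colnames(X),
                 function(f) sum(vapply(per_fold, function(s) f %in% s,
                                        logical(1))),
                 integer(1))
  out <- tibble(feature = colnames(X), frequency = unname(freq),
                retained = unname(freq) == n_folds)
  attr(out, "per_fold") <- per_fold
  attr(out, "n_folds") <- n_folds
  class(out) <- c("consensus_selection", class(out))
  out
}

#' Retained features of a consensus selection
#'
#' @param selection A `consensus_selection`.
#' @return Character vector of features selected in every fold.
#' @export
retained_features <- function(selection) {
  selection$feature[selection$retained]
}

#' Mutual information between a feature and the class
#'
#' The feature is discretized into `bins` equal-frequency bins (reduced
#' when the feature has fewer distinct values or tied quantiles), and
#' the plug-in mutual information of the bins-by-class contingency table
#' is returned in bits.  For a binary class it is bounded by 1 bit.
#'
#' @param x Numeric feature vector.
#' @param y Class labels.
#' @param bins Number of equal-frequency bins (default 4).
#' @return Mutual information in bits (non-negative scalar).
#' @export
mutual_information <- function(x, y, bins = 4L) {
  y01 <- as_case01(y)
  stopifnot(length(x) == length(y01))
  nu <- length(unique(x))
  if (nu < 2L) abort("feature needs at least 2 distinct values")
  bins <- min(bins, nu)
  br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1L),
                        names = FALSE, type = 7))
  if (length(br) < 3L) {
    b <- factor(x <= br[1], levels = c(TRUE, FALSE))
  } else {
    b <- cut(x, breaks = br, include.lowest = TRUE)
  }
  tab <- table(b, y01)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  terms <- p * log2(p / (px %o% py))
  mi <- sum(terms[p > 0])
  max(mi, 0)
}

#' Rank features by mutual information with the class
#'
#' @inheritParams cfs_search
#' @param bins Equal-frequency bin count, see [mutual_information()].
#' @return Tibble (`feature`, `mi`) sorted by decreasing mutual
#'   information.
#' @export
rank_features_mi <- function(X, y, bins = 4L) {
  X <- selection_matrix(X)
  mi <- vapply(seq_len(ncol(X)),
               function(j) mutual_information(X[, j], y, bins), numeric(1))
  dplyr::arrange(tibble(feature = colnames(X), mi = mi), dplyr::desc(mi))
}
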