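# Principal-curve machinery: Hastie-Stuetzle alternation between
# projection onto the current curve and coordinate-wise smoothing
# against the arc-length parameter.  This is the numerical core of the
# pathway dysregulation score.

# Internal: orthogonal projection of points onto the polyline through
# `v` (vertices ordered along the curve).  Returns the arc-length
# parameter, squared distance, and total polyline length.
project_polyline <- function(x, v) {
  x <- as.matrix(x); v <- as.matrix(v)
  n <- nrow(x)
  # drop zero-length segments (duplicate vertices)
  keep <- c(TRUE, rowSums((v[-1, , drop = FALSE] -
                           v[-nrow(v), , drop = FALSE])^2) > 0)
  v <- v[keep, , drop = FALSE]
  m <- nrow(v)
  if (m < 2L) {
    abort("degenerate curve: all vertices coincide",
          class = "pdsdiag_degenerate")
  }
  a <- v[-m, , drop = FALSE]
  b <- v[-1, , drop = FALSE]
  ab <- b - a
  l2 <- rowSums(ab^2)
  seglen <- sqrt(l2)
  cumlen <- c(0, cumsum(seglen))
  # squared distance of every point to every segment, fully vectorized:
  # with p = a_k + t_ik ab_k (t clamped to [0,1]),
  # d2_ik = |x_i|^2 - 2 x_i.a_k + |a_k|^2 - 2 t (x_i.ab_k - a_k.ab_k)
  #         + t^2 |ab_k|^2
  X2 <- rowSums(x^2)
  A2 <- rowSums(a^2)
  XA <- x %*% t(a)
  Xab <- x %*% t(ab)
  Aab <- rowSums(a * ab)
  tt <- sweep(Xab, 2L, Aab) / rep(l2, each = n)
  tt[tt < 0] <- 0
  tt[tt > 1] <- 1
  d2 <- (X2 - 2 * XA + tt^2 * rep(l2, each = n) -
         2 * tt * sweep(Xab, 2L, Aab))
  d2 <- sweep(d2, 2L, A2, `+`)
  k_best <- max.col(-d2, ties.method = "first")
  idx <- cbind(seq_len(n), k_best)
  list(lambda = cumlen[k_best] + tt[idx] * seglen[k_best],
       dist2 = pmax(d2[idx], 0),
       total_length = cumlen[m])
}

# Internal: smooth one coordinate against the arc-length parameter.
# Cubic smoothing spline; falls back to a straight least-squares line
# when too few distinct parameter values support a spline fit.
smooth_coordinate <- function(lambda, y, spar) {
  nu <- length(unique(lambda))
  ok <- nu >= 4L
  if (ok) {
    fit <- tryCatch(
      smooth.spline(lambda, y, spar = spar, cv = FALSE,
                    all.knots = FALSE, keep.data = FALSE,
                    nknots = min(40L, nu)),
      error = function(e) NULL)
    if (!is.null(fit)) return(predict(fit, lambda)$y)
  }
  stats::fitted(stats::lm(y ~ lambda))
}

#' Fit a smoothed principal curve
#'
#' Hastie-Stuetzle alternation: initialize the arc-length parameter with
#' the projection onto the first principal-component line, then repeat
#' (i) smooth each coordinate against the parameter with a cubic
#' smoothing spline, (ii) re-project every point onto the resulting
#' polyline and re-parameterize by arc length, until the relative change
#' in the summed squared projection residuals falls below `tol`.
#'
#' @param x Numeric matrix, one row per sample (n >= 6), columns are the
#'   (reduced) coordinates.  A single column is treated as the identity
#'   curve.
#' @param spar Smoothing parameter handed to [stats::smooth.spline()]
#'   (default 0.75; larger is smoother).
#' @param tol Relative sse convergence tolerance (default 1e-4).
#' @param max_iter Iteration cap (default 50).
#' @return An object of class `principal_curve_fit`: list with `lambda`
#'   (arc-length parameter per sample), `curve_points` (ordered polyline
#'   vertices), `total_length`, `sse`, `converged`, `n_iterations`, and
#'   `d` (ambient dimension).
#' @export
fit_principal_curve <- function(x, spar = 0.75, tol = 1e-4, max_iter = 50L) {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (n < 6L) abort("principal curve needs at least 6 samples")
  if (all(apply(x, 2L, function(z) max(z) - min(z)) == 0)) {
    abort("degenerate input: all points identical",
          class = "pdsdiag_degenerate")
  }
  if (d == 1L) {
    lam <- x[, 1] - min(x[, 1])
    ord <- order(lam)
    out <- list(lambda = lam,
                curve_points = x[ord, , drop = FALSE],
                total_length = max(lam),
                sse = 0, converged = TRUE, n_iterations = 0L, d = 1L)
    class(out) <- "principal_curve_fit"
    return(out)
  }
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  sv <- svd(xc, nu = 0L, nv = 1L)
  v1 <- sv$v[, 1]
  pivot <- which.max(abs(v1))
  if (v1[pivot] < 0) v1 <- -v1  # sample-order-independent sign
  lam <- as.numeric(xc %*% v1)
  # sse of the initial straight-line fit
  sse <- sum(xc^2) - sum(lam^2)
  best <- NULL
  converged <- FALSE
  iter <- 0L
  stale <- 0L
  while (iter < max_iter && stale < 5L) {
    iter <- iter + 1L
    ord <- order(lam)
    lam_o <- lam[ord]
    curve <- vapply(seq_len(d),
                    function(j) smooth_coordinate(lam_o, x[ord, j], spar),
                    numeric(n))
    pr <- project_polyline(x, curve)
    sse_new <- sum(pr$dist2)
    # the alternation is not monotone; keep the best iterate seen and
    # stop once it stops improving
    improved <- is.null(best) ||
      sse_new < best$sse - tol * max(best$sse, 1e-12)
    if (is.null(best) || sse_new < best$sse) {
      best <- list(lambda = pr$lambda, curve_points = curve,
                   total_length = pr$total_length, sse = sse_new)
    }
    if (abs(sse - sse_new) <= tol * max(sse, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    stale <- if (improved) 0L else stale + 1L
    sse <- sse_new
    lam <- pr$lambda
  }
  out <- c(best, list(converged = converged || stale >= 5L,
                      n_iterations = iter, d = d))
  class(out) <- "principal_curve_fit"
  out
}

#' @export
print.principal_curve_fit <- function(x, ...) {
  cat(sprintf(
    "<principal_curve_fit> n = %d, d = %d, length = %.4g, sse = %.4g (%s, %d iter)\n",
    length(x$lambda), x$d, x$total_length, x$sse,
    if (x$converged) "converged" else "not converged", x$n_iterations))
  invisible(x)
}

#' Score samples along a fitted principal curve
#'
#' Orients the curve so that the control (normal) samples sit near its
#' start, then rescales the arc-length parameter to `[0, 1]`: the
#' pathway dysregulation score.  Orientation rule: flip when the median
#' control parameter exceeds the median of the remaining samples; ties
#' are broken by the smaller mean control parameter, and a persisting
#' tie keeps the fitted orientation.
#'
#' @param fit A `principal_curve_fit`, or a bare numeric vector of
#'   arc-length parameters.
#' @param is_control Logical vector (one per sample); at least two
#'   controls are required.
#' @return Numeric PDS vector in `[0, 1]` (min 0 and max 1 attained),
#'   with attribute `"orientation"` (+1 kept, -1 flipped).
#' @export
score_pathway <- function(fit, is_control) {
  lam <- if (inherits(fit, "principal_curve_fit")) fit$lambda else as.numeric(fit)
  is_control <- as.logical(is_control)
  stopifnot(length(lam) == length(is_control))
  if (sum(is_control) < 2L) abort("at least 2 control samples are required")
  rng <- max(lam) - min(lam)
  if (rng <= 0) {
    abort("degenerate pathway: all samples project to the same point",
          class = "pdsdiag_degenerate")
  }
  pds <- (lam - min(lam)) / rng
  med_ctrl <- median(pds[is_control])
  med_rest <- if (any(!is_control)) median(pds[!is_control]) else med_ctrl
  orientation <- 1
  if (med_ctrl > med_rest) {
    orientation <- -1
  } else if (med_ctrl == med_rest) {
    if (mean(pds[is_control]) > mean(1 - pds[is_control])) orientation <- -1
  }
  if (orientation < 0) pds <- 1 - pds
  structure(pds, orientation = orientation)
}
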