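#' Quantile-normalize binned counts
#'
#' Forces every track in a normalization group onto a common distribution:
#' the mean of the group's order statistics. After normalization each
#' track's sorted values equal the cross-track mean of sorted values; ranks
#' within a track are preserved; tied values receive the mean of their tied
#' quantile targets (so an all-equal track maps to the grand mean of the
#' targets).
#'
#' @param counts a [binned_track_matrix()].
#' @param group_by_mark normalize separately within each mark (default TRUE;
#'   marks differ in genome-wide prevalence).
#' @return a [binned_track_matrix()] of normalized values.
#' @export
quantile_normalize <- function(counts, group_by_mark = TRUE) {
  stopifnot(inherits(counts, "binned_track_matrix"))
  v <- counts$values
  groups <- if (group_by_mark) split(seq_len(ncol(v)), counts$tracks$mark)
            else list(all = seq_len(ncol(v)))
  for (cols in groups) {
    if (length(cols) < 2)
      stop("quantile normalization needs >= 2 tracks per group")
    v[, cols] <- qnorm_group(v[, cols, drop = FALSE])
  }
  binned_track_matrix(v, counts$bins, counts$tracks[, c("individual", "mark")])
}

qnorm_group <- function(x) {
  n <- nrow(x)
  target <- rowMeans(apply(x, 2, sort.int, method = "quick"))
  cs <- c(0, cumsum(target))
  out <- x
  for (j in seq_len(ncol(x))) {
    rmin <- rank(x[, j], ties.method = "min")
    rmax <- rank(x[, j], ties.method = "max")
    out[, j] <- (cs[rmax + 1] - cs[rmin]) / (rmax - rmin + 1)
  }
  out
}

#' Regress covariates out of binned counts
#'
#' Per bin (and separately per mark), fits a log-link count regression of
#' the track values on standardized covariates across tracks, then removes
#' the covariate effect multiplicatively: `corrected = observed *
#' exp(b0) / fitted`. Point estimates come from Poisson-likelihood
#' estimating equations, which coincide with the quasi-Poisson fit; the
#' quasi dispersion only affects standard errors, which are not used here.
#'
#' @param norm a [binned_track_matrix()] (typically quantile-normalized).
#' @param covariates data.frame, one row per track; standardized internally
#'   to mean 0, sd 1 (categorical covariates must be pre-encoded).
#' @param group_by_mark fit per mark (default TRUE).
#' @param max_iter,tol IRLS settings for the per-bin fits.
#' @return a [binned_track_matrix()] of corrected values (>= 0, continuous).
#' @export
regress_covariates <- function(norm, covariates, group_by_mark = TRUE,
                               max_iter = 50L, tol = 1e-8) {
  stopifnot(inherits(norm, "binned_track_matrix"))
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != ncol(norm$values))
    stop("covariates must have one row per track")
  if (anyNA(covariates)) stop("covariates must not contain missing values")
  if (ncol(covariates) == 0) return(norm)
  x <- scale(as.matrix(covariates))
  if (any(!is.finite(x))) stop("singular design: constant covariate column")
  p <- ncol(x)
  v <- norm$values
  out <- v
  groups <- if (group_by_mark) split(seq_len(ncol(v)), norm$tracks$mark)
            else list(all = seq_len(ncol(v)))
  n_fail <- 0L
  for (cols in groups) {
    if (length(cols) < p + 2)
      stop("need at least p+2 tracks per group to fit p covariates")
    design <- cbind(`(Intercept)` = 1, x[cols, , drop = FALSE])
    if (qr(design)$rank < ncol(design))
      stop("singular design: covariates collinear within a group")
    sub <- v[, cols, drop = FALSE]
    nonzero <- rowSums(sub) > 0
    out[!nonzero, cols] <- 0
    if (any(nonzero)) {
      fit <- .irls_poisson_batch(design, sub[nonzero, , drop = FALSE],
                                 max_iter, tol)
      beta <- fit$beta
      ok <- fit$converged & apply(is.finite(beta), 1, all)
      # retry stragglers with the reference fitter before giving up
      for (b in which(!ok)) {
        g <- tryCatch(
          stats::glm.fit(design, sub[nonzero, , drop = FALSE][b, ],
                         family = stats::poisson(),
                         control = list(maxit = max_iter, epsilon = tol)),
          error = function(e) NULL)
        if (!is.null(g) && g$converged) {
          beta[b, ] <- g$coefficients
          ok[b] <- TRUE
        }
      }
      n_fail <- n_fail + sum(!ok)
      fitted <- exp(pmin(pmax(beta %*% t(design), -30), 30))
      corr <- sub[nonzero, , drop = FALSE] * exp(beta[, 1]) / fitted
      corr[!ok, ] <- sub[nonzero, , drop = FALSE][!ok, ]
      out[nonzero, cols] <- corr
    }
  }
  if (n_fail > 0)
    warning(sprintf("%d bin fits did not converge; left uncorrected", n_fail))
  binned_track_matrix(out, norm$bins, norm$tracks[, c("individual", "mark")])
}

#' Poisson-tail threshold for one track
#'
#' Smallest non-negative integer `c` with `P(X >= c) <= pthresh` for
#' `X ~ Poisson(lambda)`, forced to at least 1 so that zero signal is never
#' called present.
#'
#' @param lambda Poisson mean (the track's genome-wide mean signal).
#' @param pthresh tail probability threshold.
#' @return integer threshold.
#' @export
poisson_threshold <- function(lambda, pthresh = 1e-4) {
  stopifnot(lambda >= 0, pthresh > 0)
  if (lambda == 0) return(1L)
  # P(X >= c) = 1 - P(X <= c-1); qpois gives the smallest q with
  # P(X <= q) >= 1 - pthresh, i.e. the smallest c-1 with tail(c) <= pthresh.
  cstar <- as.integer(stats::qpois(1 - pthresh, lambda)) + 1L
  while (cstar > 1L &&
         stats::ppois(cstar - 2L, lambda, lower.tail = FALSE) <= pthresh)
    cstar <- cstar - 1L
  max(cstar, 1L)
}

#' Binarize corrected signal with a Poisson background model
#'
#' Per track, the background rate `lambda` is the genome-wide mean of the
#' corrected values; a bin is called present iff its value is at least the
#' track's Poisson tail threshold (see [poisson_threshold()]).
#'
#' @param corrected a [binned_track_matrix()].
#' @param pthresh Poisson tail probability (default 1e-4).
#' @return a [binary_call_matrix()]; the per-track integer thresholds are in
#'   `$thresholds`.
#' @export
binarize <- function(corrected, pthresh = 1e-4) {
  stopifnot(inherits(corrected, "binned_track_matrix"))
  v <- corrected$values
  lambda <- colMeans(v)
  if (any(lambda == 0))
    warning("track(s) with zero mean signal: all calls 0 there")
  thr <- vapply(lambda, poisson_threshold, integer(1), pthresh = pthresh)
  calls <- sweep(v, 2, thr, `>=`) * 1L
  binary_call_matrix(calls, corrected$bins,
                     corrected$tracks[, c("individual", "mark")],
                     thresholds = thr)
}
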