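# Random-matrix-theory threshold selection via the generalized Brody
# distribution: scan correlation cutoffs until the nearest-neighbour
# spacing distribution (NNSD) of the thresholded matrix becomes
# Poisson-like (fitted Brody beta near 0).

#' Brody spacing density
#'
#' One-parameter family interpolating between Poisson (`beta = 0`,
#' `P(s) = exp(-s)`) and Wigner/GOE (`beta = 1`,
#' `P(s) = (pi/2) s exp(-pi s^2 / 4)`) nearest-neighbour spacing
#' statistics: `P(s) = c (beta + 1) s^beta exp(-c s^(beta + 1))` with
#' `c = Gamma((beta + 2) / (beta + 1))^(beta + 1)` (unit mean spacing).
#'
#' @param s Spacings (non-negative).
#' @param beta Brody parameter in `[0, 1.2]`.
#' @return Density values.
#' @export
brody_pdf <- function(s, beta) {
  cc <- gamma((beta + 2) / (beta + 1))^(beta + 1)
  cc * (beta + 1) * s^beta * exp(-cc * s^(beta + 1))
}

#' Fit the Brody parameter to observed spacings
#'
#' Normalises the spacings to unit mean, histograms their density on
#' `[0, smax]` and fits `beta` by least squares against [brody_pdf()].
#'
#' @param spacings Positive spacings (e.g. unfolded eigenvalue spacings).
#' @param bins Histogram bin count (default 30).
#' @param smax Histogram upper limit in units of the mean spacing
#'   (default 3).
#' @return A list with `beta` and `fit_error` (residual sum of squares).
#' @export
fit_brody <- function(spacings, bins = 30, smax = 3) {
  spacings <- spacings[is.finite(spacings) & spacings >= 0]
  if (length(spacings) < 10) abort("need >= 10 spacings to fit")
  s <- spacings / mean(spacings)
  breaks <- seq(0, smax, length.out = bins + 1)
  h <- graphics::hist(pmin(s, smax - 1e-12), breaks = breaks, plot = FALSE)
  mids <- h$mids
  dens <- h$density
  obj <- function(beta) sum((dens - brody_pdf(mids, beta))^2)
  opt <- optimize(obj, interval = c(0, 1.2))
  list(beta = opt$minimum, fit_error = opt$objective)
}

# Unfold a sorted eigenvalue spectrum to unit mean density via a smooth
# fit to the empirical cumulative distribution; exact degeneracies are
# collapsed first (their zero spacings carry no level-repulsion signal).
unfold_spacings <- function(ev, df = 10) {
  ev <- sort(ev)
  ev <- ev[c(TRUE, diff(ev) > 1e-10)]
  n <- length(ev)
  if (n < 12) return(numeric())
  cdf <- (seq_len(n) - 0.5) / n
  fit <- smooth.spline(ev, cdf, df = min(df, max(4, n / 4)))
  unfolded <- n * pmin(pmax(predict(fit, ev)$y, 0), 1)
  sp <- diff(sort(unfolded))
  sp[sp > 0]
}

#' Choose a correlation-network cutoff by the RMT/Brody criterion
#'
#' For each candidate cutoff, off-diagonal correlations below it (in
#' absolute value) are zeroed, the eigenvalue spectrum of the thresholded
#' matrix is unfolded, and the Brody parameter is fitted to its
#' nearest-neighbour spacing distribution. The chosen threshold is the
#' smallest cutoff whose fitted `beta` drops to `beta_poisson_tol` or
#' below (Poisson-like spacings, i.e. the residual modules are
#' statistically independent). If no cutoff qualifies the scan returns the
#' cutoff with the smallest `beta`, flagged.
#'
#' @param corr Symmetric correlation matrix with unit diagonal.
#' @param cut_grid Increasing cutoff grid (default `seq(0.1, 0.9, 0.05)`).
#' @param beta_poisson_tol Poisson acceptance level for `beta`
#'   (default 0.1).
#' @param bins,smax Histogram specification passed to [fit_brody()].
#' @return An object of class `qs_rmt`: `threshold`, `converged`, and a
#'   `scan` tibble (`cutoff`, `beta`, `fit_error`, `n_spacings`).
#' @export
rmt_threshold <- function(corr, cut_grid = seq(0.1, 0.9, by = 0.05),
                          beta_poisson_tol = 0.1, bins = 30, smax = 3) {
  corr <- as.matrix(corr)
  if (!isTRUE(all.equal(corr, t(corr), tolerance = 1e-8))) {
    abort("`corr` must be symmetric")
  }
  if (any(abs(diag(corr) - 1) > 1e-8)) abort("`corr` must have unit diagonal")
  cut_grid <- sort(cut_grid)
  scan <- purrr::map(cut_grid, function(ct) {
    a <- corr
    a[abs(a) < ct] <- 0
    diag(a) <- 1
    ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
    sp <- unfold_spacings(ev)
    if (length(sp) < 10) {
      return(tibble(cutoff = ct, beta = NA_real_, fit_error = NA_real_,
                    n_spacings = length(sp)))
    }
    fit <- fit_brody(sp, bins = bins, smax = smax)
    tibble(cutoff = ct, beta = fit$beta, fit_error = fit$fit_error,
           n_spacings = length(sp))
  })
  scan <- dplyr::bind_rows(scan)
  ok <- which(!is.na(scan$beta) & scan$beta <= beta_poisson_tol)
  if (length(ok)) {
    threshold <- scan$cutoff[ok[1]]
    converged <- TRUE
  } else {
    threshold <- scan$cutoff[which.min(scan$beta)]
    converged <- FALSE
  }
  structure(list(threshold = threshold, converged = converged, scan = scan,
                 beta_poisson_tol = beta_poisson_tol),
            class = "qs_rmt")
}

#' @export
print.qs_rmt <- function(x, ...) {
  cat(sprintf("RMT/Brody threshold: %.3g (%s)\n", x$threshold,
              if (x$converged) sprintf("beta <= %.3g reached", x$beta_poisson_tol)
              else "grid exhausted; smallest beta"))
  print(x$scan, n = Inf)
  invisible(x)
}
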