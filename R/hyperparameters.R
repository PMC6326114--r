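# Hyper-parameter estimation: empirical code prevalences, the skew-t fit to
# the similarity distribution, its rightmost inflexion point c0, the prior
# match probability pi0, and (opt-in) data-driven discrepancy rates.

#' Empirical code prevalences
#'
#' Per-code sample fractions, clipped away from 0 and 1 so that codes never
#' (or always) recorded do not produce infinite log-likelihood-ratio
#' weights. The clip bound is `1/(2n)` — half an observation.
#'
#' @param D a [binary_records] object.
#' @param clip clip to `[1/(2n), 1 - 1/(2n)]` (default `TRUE`).
#' @return named numeric vector of prevalences.
#' @export
estimate_prevalence <- function(D, clip = TRUE) {
  n <- nrow(D)
  if (is.null(n) || n < 1L) stop("dataset has no patients")
  p <- colMeans(unclass(D))
  if (clip) p <- clip_unit(p, 1 / (2 * n))
  p
}

#' Skew-t density, distribution sampler and maximum-likelihood fit
#'
#' The four-parameter (location `xi`, scale `omega`, skewness `alpha`,
#' degrees of freedom `nu`) skew-t density in the Azzalini parameterization:
#' \deqn{f(x) = \frac{2}{\omega}\, t_\nu(z)\,
#'   T_{\nu+1}\!\Big(\alpha z \sqrt{\tfrac{\nu+1}{z^2+\nu}}\Big),\qquad
#'   z = (x-\xi)/\omega,}
#' where \eqn{t_\nu} and \eqn{T_{\nu+1}} are the Student-t density and
#' distribution functions. `alpha = 0` recovers the scaled Student-t and
#' large `nu` the skew-normal/normal limits.
#'
#' @param x quantiles.
#' @param xi location.
#' @param omega scale, positive.
#' @param alpha skewness.
#' @param nu degrees of freedom, positive.
#' @param log return log-density.
#' @return `dskewt`: density values.
#' @export
dskewt <- function(x, xi = 0, omega = 1, alpha = 0, nu = 10, log = FALSE) {
  if (omega <= 0 || nu <= 0) stop("omega and nu must be positive")
  z <- (x - xi) / omega
  ld <- log(2) - log(omega) + stats::dt(z, df = nu, log = TRUE) +
    stats::pt(alpha * z * sqrt((nu + 1) / (z^2 + nu)), df = nu + 1,
              log.p = TRUE)
  if (log) ld else exp(ld)
}

#' @rdname dskewt
#' @param n number of draws.
#' @return `rskewt`: random draws, via the scale-mixture representation
#'   (skew-normal draw divided by an independent `sqrt(chi^2_nu / nu)`).
#' @export
rskewt <- function(n, xi = 0, omega = 1, alpha = 0, nu = 10) {
  delta <- alpha / sqrt(1 + alpha^2)
  z0 <- abs(stats::rnorm(n))
  z1 <- stats::rnorm(n)
  sn <- delta * z0 + sqrt(1 - delta^2) * z1
  w <- sqrt(stats::rchisq(n, df = nu) / nu)
  xi + omega * sn / w
}

#' @rdname dskewt
#' @param sample numeric vector of observations (at least 100).
#' @param max_sample if the sample is larger, fit on a seeded uniform
#'   subsample of this size (default 5e6).
#' @param subsample_seed seed used for that subsample.
#' @return `fit_skew_t`: an object of class `skew_t_fit` with elements
#'   `xi`, `omega`, `alpha`, `nu`, `log_likelihood`, `se` (delta-method
#'   standard errors on the natural scale), `convergence`, `n` and the
#'   sample `range`.
#' @details
#' The likelihood is maximized by bounded quasi-Newton (`L-BFGS-B`) on
#' `(xi, log omega, alpha, log nu)` with `nu` bounded in `[1, 200]`,
#' multi-started from moment-based values (and a symmetric-t start), since
#' skew-t likelihoods can be multimodal in small samples.
#' @export
fit_skew_t <- function(sample, max_sample = 5e6, subsample_seed = 1L) {
  x <- as.numeric(sample[is.finite(sample)])
  if (length(x) < 100L) stop("need at least 100 finite values to fit a skew-t")
  if (length(x) > max_sample) {
    x <- withr_seed(subsample_seed, sample(x, max_sample))
  }
  m <- mean(x); s <- stats::sd(x)
  skw <- mean(((x - m) / s)^3)
  nll <- function(par) {
    ld <- dskewt(x, par[1L], exp(par[2L]), par[3L], exp(par[4L]), log = TRUE)
    if (any(!is.finite(ld))) return(1e10)
    -sum(ld)
  }
  starts <- list(c(m, log(s), sign(skw) * min(abs(skw) * 3, 5), log(10)),
                 c(stats::median(x), log(s), 0, log(5)),
                 c(m - s * sign(skw) / 2, log(s), sign(skw) * 1, log(30)))
  lower <- c(-Inf, -Inf, -50, log(1))
  upper <- c(Inf, Inf, 50, log(200))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, nll, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    stop("skew-t likelihood optimization failed from every start; ",
         "sample summary: ", paste(round(summary(x), 3), collapse = " "))
  h <- tryCatch(stats::optimHess(best$par, nll), error = function(e) NULL)
  se <- rep(NA_real_, 4L)
  if (!is.null(h)) {
    v <- tryCatch(diag(solve(h)), error = function(e) rep(NA_real_, 4L))
    v[v < 0] <- NA_real_
    # delta method back to the natural scale for omega and nu
    se <- sqrt(v) * c(1, exp(best$par[2L]), 1, exp(best$par[4L]))
  }
  structure(list(xi = best$par[1L], omega = exp(best$par[2L]),
                 alpha = best$par[3L], nu = exp(best$par[4L]),
                 log_likelihood = -best$value,
                 se = stats::setNames(se, c("xi", "omega", "alpha", "nu")),
                 convergence = best$convergence,
                 n = length(x), range = range(x)),
            class = "skew_t_fit")
}

#' @export
print.skew_t_fit <- function(x, ...) {
  cat(sprintf(paste0("<skew_t_fit> xi = %.4g, omega = %.4g, alpha = %.4g, ",
                     "nu = %.4g (logLik %.1f, n = %d)\n"),
              x$xi, x$omega, x$alpha, x$nu, x$log_likelihood, x$n))
  invisible(x)
}

# run expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Rightmost inflexion point of a fitted skew-t density
#'
#' Scans the analytic density's second derivative (central differences on a
#' regular grid, 10,001 points by default) and returns the largest abscissa
#' at which it changes sign. Used as the similarity threshold `c0` above
#' which pairs are counted as likely matches.
#'
#' @param fit a `skew_t_fit` (or list with `xi`, `omega`, `alpha`, `nu`).
#' @param grid_lo,grid_hi grid limits; default to the fitted sample range
#'   widened by two fitted scales.
#' @param n_grid number of grid points.
#' @return the abscissa of the rightmost sign change (linearly interpolated
#'   between the bracketing grid points).
#' @export
rightmost_inflexion <- function(fit, grid_lo = NULL, grid_hi = NULL,
                                n_grid = 10001L) {
  if (is.null(grid_lo)) grid_lo <- fit$range[1L] - 2 * fit$omega
  if (is.null(grid_hi)) grid_hi <- fit$range[2L] + 2 * fit$omega
  if (!is.finite(grid_lo) || !is.finite(grid_hi) || grid_hi <= grid_lo)
    stop("invalid inflexion search grid")
  g <- seq(grid_lo, grid_hi, length.out = n_grid)
  d <- dskewt(g, fit$xi, fit$omega, fit$alpha, fit$nu)
  d2 <- diff(d, differences = 2L)           # second central difference
  sgn <- sign(d2)
  flip <- which(sgn[-1L] * sgn[-length(sgn)] < 0)
  if (length(flip) == 0L)
    stop("no inflexion point found on the grid; the fitted density is degenerate")
  i <- flip[length(flip)]                   # d2 indices offset by 1 vs grid
  x1 <- g[i + 1L]; x2 <- g[i + 2L]
  y1 <- d2[i]; y2 <- d2[i + 1L]
  x1 + (x2 - x1) * y1 / (y1 - y2)
}

#' Prior match probability from the similarity distribution
#'
#' The observed similarities follow a mixture `pi0 * g + (1 - pi0) * f`
#' where `f` is the non-match component; since true matches are rare and lie
#' far to the right, `pi0` is estimated as the fraction of pairs whose
#' similarity exceeds the threshold `c0` (the rightmost inflexion of the
#' fitted `f`), clamped inside `(0, 1)` by one pair's worth of mass.
#'
#' @param scores a [similarity_scores] matrix (or numeric vector of
#'   similarities).
#' @param c0 similarity threshold.
#' @return estimated prior match probability.
#' @export
estimate_pi0 <- function(scores, c0) {
  if (!is.finite(c0)) stop("c0 must be finite")
  s <- as.numeric(scores)
  clip_unit(mean(s > c0), 1 / length(s))
}

#' Estimate the prior match probability end-to-end
#'
#' Convenience wrapper: fit the skew-t to the similarity sample, locate the
#' rightmost inflexion `c0`, and count exceedances.
#'
#' @inheritParams estimate_pi0
#' @inheritParams fit_skew_t
#' @return list with `pi_0`, `c0` and the `skew_t_fit`.
#' @export
auto_pi0 <- function(scores, max_sample = 5e6, subsample_seed = 1L) {
  fit <- fit_skew_t(as.numeric(scores), max_sample = max_sample,
                    subsample_seed = subsample_seed)
  c0 <- rightmost_inflexion(fit)
  list(pi_0 = estimate_pi0(scores, c0), c0 = c0, fit = fit)
}

#' Data-driven discrepancy rates from high-similarity pairs
#'
#' Without gold-standard labels the discrepancy rates are only roughly
#' estimable: among pairs whose similarity exceeds `c0` (mostly true
#' matches), `eps_minus[k]` is the fraction with the code present in A but
#' absent in B among pairs with the code present in A, and `eps_plus[k]`
#' the fraction present in B among pairs with the code absent in A. Codes
#' with an empty denominator fall back to `default`. This is an explicit
#' opt-in; the primary path is a user-supplied scalar (0.01 in the package's
#' reference analyses).
#'
#' @param A,B [binary_records] objects.
#' @param scores their [similarity_scores] matrix.
#' @param c0 similarity threshold selecting the high-similarity pairs.
#' @param align code alignment used for the scores.
#' @param default fallback rate for codes with no eligible pairs.
#' @param clip clip estimates to `[1e-6, 1 - 1e-6]`.
#' @return list with length-K vectors `eps_minus`, `eps_plus` and the
#'   number of pairs used `n_pairs`.
#' @export
estimate_discrepancy_rates <- function(A, B, scores, c0,
                                       align = align_codes(A, B),
                                       default = 0.01, clip = TRUE) {
  idx <- which(unclass(scores) > c0, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("no pair exceeds c0 = ", format(c0),
         "; supply eps_minus/eps_plus manually")
  Xa <- aligned_matrix(A, align, "a")[idx[, 1L], , drop = FALSE]
  Xb <- aligned_matrix(B, align, "b")[idx[, 2L], , drop = FALSE]
  n1 <- colSums(Xa)                 # pairs with code present in A
  n0 <- nrow(Xa) - n1
  em <- colSums(Xa * (1 - Xb)) / n1 # present in A, absent in B
  ep <- colSums((1 - Xa) * Xb) / n0
  em[!is.finite(em)] <- default
  ep[!is.finite(ep)] <- default
  if (clip) {
    em <- clip_unit(em, 1e-6)
    ep <- clip_unit(ep, 1e-6)
  }
  list(eps_minus = stats::setNames(em, align$codes),
       eps_plus = stats::setNames(ep, align$codes),
       n_pairs = nrow(idx))
}
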