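# Synthetic linked-dataset generator: sparse correlated binary code
# matrices (Gaussian-copula threshold model with heavy-tailed per-code
# prevalence), the correlated-Gaussian perturbation mechanism producing the
# second dataset, and partial-overlap subsetting with known ground truth.

#' Generate a sparse correlated binary code matrix
#'
#' Gaussian-copula threshold model: each patient draws a latent vector with
#' a one-factor correlation structure (pairwise latent correlation
#' `correlation`), and code k is recorded when the latent value exceeds the
#' normal quantile matching its target prevalence. Per-code prevalences are
#' drawn from a heavy-tailed sampler (default `Beta(0.3, 6)`: many rare
#' codes, a few common ones). When `mean_codes` is given, the sampled
#' prevalences are rescaled so the expected number of codes per patient
#' matches it (claims data typically show ~5 codes per patient). All-zero
#' patients are redrawn: a patient enters a claims or EHR extract only by
#' having at least one recorded code.
#'
#' @param n_patients,K dimensions.
#' @param prevalence_sampler function of K returning per-code prevalences,
#'   or a numeric vector/scalar of fixed prevalences.
#' @param correlation latent pairwise correlation in `[0, 1)` (one-factor
#'   structure; 0 = independent codes).
#' @param mean_codes optional target mean codes per patient; rescales the
#'   sampled prevalences.
#' @param seed integer seed (mandatory for reproducibility).
#' @return a [binary_records] object with patient ids `P000001, ...` and
#'   code ids `C0001, ...`; the prevalence vector used is attached as
#'   attribute `prevalence`.
#' @export
generate_base_matrix <- function(n_patients, K,
                                 prevalence_sampler = function(K) stats::rbeta(K, 0.3, 6),
                                 correlation = 0.2,
                                 mean_codes = NULL,
                                 seed) {
  if (K < 1L) stop("K must be at least 1")
  if (n_patients < 1L) stop("n_patients must be at least 1")
  if (correlation < 0 || correlation >= 1)
    stop("correlation must be in [0, 1)")
  set.seed(seed)
  p <- if (is.function(prevalence_sampler)) prevalence_sampler(K)
  else rep_len(prevalence_sampler, K)
  p <- clip_unit(p, 1e-4, 0.9)
  if (!is.null(mean_codes)) {
    p <- p * mean_codes / sum(p)
    p <- clip_unit(p, 1e-4, 0.9)
  }
  thr <- stats::qnorm(1 - p)
  draw <- function(n) {
    f <- stats::rnorm(n)                       # shared factor per patient
    e <- matrix(stats::rnorm(n * K), n, K)
    z <- sqrt(correlation) * f + sqrt(1 - correlation) * e
    (sweep(z, 2L, thr, ">")) * 1
  }
  X <- draw(n_patients)
  # redraw all-zero patients (patients are in the extract because they
  # have at least one recorded code)
  for (guard in 1:50) {
    zero <- which(rowSums(X) == 0)
    if (length(zero) == 0L) break
    X[zero, ] <- draw(length(zero))
  }
  zero <- which(rowSums(X) == 0)
  if (length(zero) > 0L)  # pathological prevalences; give them one rare code
    X[cbind(zero, sample(K, length(zero), replace = TRUE, prob = p))] <- 1
  dimnames(X) <- list(sprintf("P%06d", seq_len(n_patients)),
                      sprintf("C%04d", seq_len(K)))
  out <- binary_records(X)
  attr(out, "prevalence") <- stats::setNames(p, colnames(X))
  out
}

#' Empirical correlation matrix of the binary code columns
#'
#' Pearson correlation of the presence/absence columns. Zero-variance
#' columns (codes never or always recorded) get self-correlation 1 and
#' cross-correlations 0 rather than `NA`.
#'
#' @param D a [binary_records] object with at least 2 patients.
#' @return a `K x K` correlation matrix.
#' @export
empirical_correlation <- function(D) {
  if (nrow(D) < 2L) stop("need at least 2 patients")
  X <- unclass(D)
  v <- apply(X, 2L, stats::var)
  S <- suppressWarnings(stats::cor(X))
  S[v == 0, ] <- 0
  S[, v == 0] <- 0
  diag(S) <- 1
  S
}

# eigen-factorization of a covariance matrix with negative eigenvalues
# floored at 0 (nearest-PSD projection); returns L with L %*% t(L) = Sigma.
psd_factor <- function(Sigma, warn = TRUE) {
  eg <- eigen(Sigma, symmetric = TRUE)
  neg <- eg$values < -1e-8 * max(abs(eg$values))
  if (any(neg) && warn)
    warning("correlation matrix is not PSD; ", sum(neg),
            " negative eigenvalues floored at 0")
  eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
}

#' Perturb a binary code matrix with correlated Gaussian noise
#'
#' Implements the indicator perturbation
#' \deqn{X^* = 1_{X \cdot N(1, \rho\Sigma) + (1-X)\cdot N(-3, \rho\Sigma) > 0}}
#' applied patient by patient: two independent latent Gaussian vectors are
#' drawn per patient, `Z1` centred at 1 (governing whether present codes
#' survive) and `Z2` centred at -3 (whether absent codes appear), both with
#' covariance `rho * Sigma`, and the perturbed indicator is 1 exactly when
#' the selected latent value is strictly positive. With `Sigma` the
#' identity, a present code flips with probability `pnorm(-1/sqrt(rho))`
#' and an absent one with `pnorm(-3/sqrt(rho))` - discrepancies are
#' asymmetric by construction. `rho = 0` returns the input exactly.
#'
#' @param X a [binary_records] object.
#' @param rho perturbation level, `>= 0`.
#' @param Sigma `K x K` covariance/correlation of the noise; defaults to
#'   [empirical_correlation] of `X`. Projected to the nearest PSD matrix if
#'   needed (negative eigenvalues floored).
#' @param seed integer seed.
#' @return a [binary_records] object of the same shape (same ids).
#' @export
perturb_records <- function(X, rho, Sigma = NULL, seed) {
  if (rho < 0) stop("rho must be non-negative")
  Xm <- unclass(X)
  if (rho == 0) return(X)
  n <- nrow(Xm); K <- ncol(Xm)
  set.seed(seed)
  if (is.null(Sigma)) Sigma <- empirical_correlation(X)
  if (!identical(dim(Sigma), c(K, K)))
    stop("Sigma must be K x K")
  identity_sigma <- isTRUE(all.equal(unname(Sigma), diag(K), tolerance = 1e-12))
  if (identity_sigma) {
    Z1 <- 1 + sqrt(rho) * matrix(stats::rnorm(n * K), n, K)
    Z2 <- -3 + sqrt(rho) * matrix(stats::rnorm(n * K), n, K)
  } else {
    L <- psd_factor(Sigma)
    Z1 <- 1 + sqrt(rho) * (matrix(stats::rnorm(n * K), n, K) %*% t(L))
    Z2 <- -3 + sqrt(rho) * (matrix(stats::rnorm(n * K), n, K) %*% t(L))
  }
  Xs <- (Xm * Z1 + (1 - Xm) * Z2 > 0) * 1
  dimnames(Xs) <- dimnames(Xm)
  binary_records(Xs)
}

#' Split an original/perturbed pair into two partially overlapping datasets
#'
#' Takes `n_a` patients of the original matrix and `n_b` patients of the
#' perturbed matrix such that exactly `n_overlap` patients appear in both
#' (the true matches). Patient identifiers are re-randomized independently
#' on each side so row order and id values carry no signal; the ground
#' truth is returned as an id-pair table.
#'
#' @param X original [binary_records]; `X_star` its perturbed counterpart
#'   (same patients, same order).
#' @param n_a,n_b subset sizes; `n_overlap <= min(n_a, n_b)` and
#'   `n_a + n_b - n_overlap <= n_patients`.
#' @param n_overlap number of true matched pairs.
#' @param seed integer seed.
#' @return list with `A`, `B` ([binary_records]) and `truth` (data.frame
#'   `id_a`, `id_b`).
#' @export
split_overlap <- function(X, X_star, n_a, n_b, n_overlap, seed) {
  n <- nrow(X)
  if (!identical(dim(X), dim(X_star)))
    stop("X and X_star must have the same shape")
  if (n_overlap > min(n_a, n_b) || n_a > n || n_b > n ||
      n_a + n_b - n_overlap > n)
    stop("infeasible subset sizes: n_a = ", n_a, ", n_b = ", n_b,
         ", n_overlap = ", n_overlap, ", n_patients = ", n)
  set.seed(seed)
  perm <- sample(n)
  shared <- perm[seq_len(n_overlap)]
  only_a <- perm[seq_len(n_a - n_overlap) + n_overlap]
  only_b <- perm[seq_len(n_b - n_overlap) + n_a]
  rows_a <- sample(c(shared, only_a))
  rows_b <- sample(c(shared, only_b))
  ids_a <- sprintf("A%06d", sample(9 * n, n_a))
  ids_b <- sprintf("B%06d", sample(9 * n, n_b))
  A <- unclass(X)[rows_a, , drop = FALSE]
  B <- unclass(X_star)[rows_b, , drop = FALSE]
  rownames(A) <- ids_a
  rownames(B) <- ids_b
  truth <- data.frame(id_a = ids_a[match(shared, rows_a)],
                      id_b = ids_b[match(shared, rows_b)],
                      stringsAsFactors = FALSE)
  list(A = binary_records(A), B = binary_records(B), truth = truth)
}

#' Simulate a linked dataset pair with known ground truth
#'
#' One-call wrapper around [generate_base_matrix], [empirical_correlation],
#' [perturb_records] and [split_overlap], reproducing the simulation design
#' used throughout the package: generate a base matrix, perturb it at level
#' `rho` with the base matrix's own empirical code correlation, and take
#' partially overlapping subsets.
#'
#' @inheritParams generate_base_matrix
#' @inheritParams perturb_records
#' @inheritParams split_overlap
#' @param Sigma noise covariance; `"empirical"` (default) uses the base
#'   matrix's empirical correlation, `"identity"` the identity.
#' @return list with `A`, `B`, `truth`, and the `config` actually used.
#' @export
simulate_linked_pair <- function(n_patients, K, n_a, n_b, n_overlap,
                                 rho = 0.5,
                                 prevalence_sampler = function(K) stats::rbeta(K, 0.3, 6),
                                 correlation = 0.2,
                                 mean_codes = NULL,
                                 Sigma = c("empirical", "identity"),
                                 seed) {
  if (is.character(Sigma)) Sigma <- match.arg(Sigma)
  X <- generate_base_matrix(n_patients, K, prevalence_sampler, correlation,
                            mean_codes, seed = seed)
  S <- if (identical(Sigma, "identity")) diag(K)
  else if (identical(Sigma, "empirical")) empirical_correlation(X)
  else Sigma
  Xs <- perturb_records(X, rho, S, seed = seed + 1L)
  out <- split_overlap(X, Xs, n_a, n_b, n_overlap, seed = seed + 2L)
  out$config <- list(n_patients = n_patients, K = K, n_a = n_a, n_b = n_b,
                     n_overlap = n_overlap, rho = rho,
                     correlation = correlation, mean_codes = mean_codes,
                     seed = seed)
  out
}
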