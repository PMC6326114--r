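# Fellegi-Sunter comparator: latent-class EM over per-pair agreement
# vectors (Winkler/Grannis style), agreement-weight scoring, the plain
# threshold classifier, the one-to-one largest-score variant with ties
# kept, and blocking.
#
# Agreement on code k means A_k(i) == B_k(j): a (0,0) concordance counts
# exactly like a (1,1) concordance, which is the classical method's known
# weakness on sparse binary codes. All EM and scoring sums over pairs are
# evaluated either through exact bilinear identities (no mask; the
# agreement indicator gamma = 1 - a - b + 2ab makes every needed sum a
# matrix product) or by streaming over an admissible pair list (with a
# blocking mask), optionally compressed by grouping identical agreement
# patterns.

FS_CLIP <- 1e-6

#' Blocking mask from per-patient labels
#'
#' A candidate pair is admissible iff the two patients carry the same
#' blocking label (e.g. an age band).
#'
#' @param block_a,block_b label vectors, one per patient of A resp. B
#'   (no missing values).
#' @return an `nA x nB` logical matrix.
#' @export
blocking_mask <- function(block_a, block_b) {
  if (anyNA(block_a) || anyNA(block_b))
    stop("blocking labels must be provided for every patient")
  m <- outer(as.character(block_a), as.character(block_b), "==")
  if (!any(m)) warning("blocking mask admits no pair (disjoint label sets)")
  m
}

# gamma-sum helper: for weight vector v over codes, returns the nA x nB
# matrix of sum_k gamma_ijk * v_k, using gamma = 1 - a - b + 2ab.
gamma_bilinear <- function(Xa, Xb, v) {
  sweep(2 * (Xa %*% (v * t(Xb))), 2L, as.vector(Xb %*% v)) -
    as.vector(Xa %*% v) + sum(v)
}

#' Fit the Fellegi-Sunter latent-class model by EM
#'
#' Conditional-independence latent-class EM over all admissible pairs: the
#' E-step computes each pair's match responsibility from the current
#' `(m, u, p)`, the M-step re-estimates `m` and `u` as responsibility-
#' weighted per-code agreement rates and `p` as the mean responsibility.
#' Parameters are clipped away from 0 and 1.
#'
#' @param A,B [binary_records] objects.
#' @param align code alignment (defaults to union).
#' @param blocking optional logical mask of admissible pairs from
#'   [blocking_mask].
#' @param m0,u0,p0 initial values; defaults are `m0 = 0.9`, `u0` the
#'   empirical per-code agreement rate over admissible pairs, and
#'   `p0 = 1/max(nA, nB)`.
#' @param tol convergence tolerance on the maximum absolute parameter
#'   change (default 1e-6).
#' @param max_iter maximum EM iterations (default 500); non-convergence
#'   returns with a warning flag rather than an error.
#' @param compress in the pair-list path, group identical agreement
#'   patterns before iterating (default `TRUE` when K <= 64).
#' @return An object of class `fs_model`: list with `m`, `u`, `p`,
#'   `n_iter`, `converged`, `log_likelihood` (trace over iterations) and
#'   `codes`.
#' @export
fs_em <- function(A, B, align = align_codes(A, B), blocking = NULL,
                  m0 = 0.9, u0 = NULL, p0 = NULL,
                  tol = 1e-6, max_iter = 500L,
                  compress = length(align$codes) <= 64L) {
  Xa <- aligned_matrix(A, align, "a")
  Xb <- aligned_matrix(B, align, "b")
  K <- ncol(Xa); nA <- nrow(Xa); nB <- nrow(Xb)
  if (K < 1L) stop("need at least one aligned code")
  if (!is.null(blocking) && !identical(dim(blocking), c(nA, nB)))
    stop("blocking mask dimensions do not match the datasets")

  if (is.null(p0)) p0 <- 1 / max(nA, nB)
  if (is.null(u0)) {
    if (is.null(blocking)) {
      pa <- colMeans(Xa); pb <- colMeans(Xb)
      u0 <- pa * pb + (1 - pa) * (1 - pb)
    } else {
      idx <- which(blocking, arr.ind = TRUE)
      u0 <- colMeans(1 - abs(Xa[idx[, 1L], , drop = FALSE] -
                               Xb[idx[, 2L], , drop = FALSE]))
    }
  }
  m <- clip_unit(rep_len(m0, K), FS_CLIP)
  u <- clip_unit(rep_len(u0, K), FS_CLIP)
  p <- clip_unit(p0, FS_CLIP)
  stopifnot(all(m > 0 & m < 1), all(u > 0 & u < 1), p > 0, p < 1)

  if (is.null(blocking)) {
    em_fit_bilinear(Xa, Xb, m, u, p, tol, max_iter, align$codes)
  } else {
    em_fit_pairs(Xa, Xb, which(blocking, arr.ind = TRUE), m, u, p,
                 tol, max_iter, compress, align$codes)
  }
}

# EM over all nA x nB pairs via bilinear identities; never materializes the
# per-pair-per-code agreement array.
em_fit_bilinear <- function(Xa, Xb, m, u, p, tol, max_iter, codes) {
  K <- ncol(Xa); nA <- nrow(Xa); nB <- nrow(Xb); N <- nA * nB
  llt <- numeric(0L)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    lm <- gamma_bilinear(Xa, Xb, stats::qlogis(m)) + sum(log(1 - m))
    lu <- gamma_bilinear(Xa, Xb, stats::qlogis(u)) + sum(log(1 - u))
    R <- stats::plogis(stats::qlogis(p) + lm - lu)
    # observed-data log-likelihood: log(p e^lm + (1-p) e^lu), stably
    hi <- pmax(lm, lu)
    llt <- c(llt, sum(hi + log(p * exp(lm - hi) + (1 - p) * exp(lu - hi))))
    S <- sum(R)
    rB <- colSums(R)
    agree_m <- S - as.vector(t(Xa) %*% rowSums(R)) - as.vector(t(Xb) %*% rB) +
      2 * colSums(Xa * (R %*% Xb))
    # agreement totals over all pairs (responsibility 1 everywhere)
    tot <- N - nB * colSums(Xa) - nA * colSums(Xb) + 2 * colSums(Xa) * colSums(Xb)
    m_new <- clip_unit(agree_m / S, FS_CLIP)
    u_new <- clip_unit((tot - agree_m) / (N - S), FS_CLIP)
    p_new <- clip_unit(S / N, FS_CLIP)
    delta <- max(abs(c(m_new - m, u_new - u, p_new - p)))
    m <- m_new; u <- u_new; p <- p_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("Fellegi-Sunter EM did not converge in ", max_iter, " iterations")
  fs_model(m, u, p, iter, converged, llt, codes)
}

# EM over an explicit admissible pair list (blocked problems and the
# reference path used to cross-check the bilinear implementation).
em_fit_pairs <- function(Xa, Xb, idx, m, u, p, tol, max_iter, compress, codes) {
  G <- 1 - abs(Xa[idx[, 1L], , drop = FALSE] - Xb[idx[, 2L], , drop = FALSE])
  wts <- rep(1, nrow(G))
  if (compress) {
    key <- apply(G, 1L, paste, collapse = "")
    first <- !duplicated(key)
    wts <- as.vector(table(factor(key, levels = key[first])))
    G <- G[first, , drop = FALSE]
  }
  N <- sum(wts)
  llt <- numeric(0L)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    lm <- as.vector(G %*% stats::qlogis(m)) + sum(log(1 - m))
    lu <- as.vector(G %*% stats::qlogis(u)) + sum(log(1 - u))
    R <- stats::plogis(stats::qlogis(p) + lm - lu)
    hi <- pmax(lm, lu)
    llt <- c(llt, sum(wts * (hi + log(p * exp(lm - hi) + (1 - p) * exp(lu - hi)))))
    S <- sum(wts * R)
    m_new <- clip_unit(as.vector(t(G) %*% (wts * R)) / S, FS_CLIP)
    u_new <- clip_unit(as.vector(t(G) %*% (wts * (1 - R))) / (N - S), FS_CLIP)
    p_new <- clip_unit(S / N, FS_CLIP)
    delta <- max(abs(c(m_new - m, u_new - u, p_new - p)))
    m <- m_new; u <- u_new; p <- p_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("Fellegi-Sunter EM did not converge in ", max_iter, " iterations")
  fs_model(m, u, p, iter, converged, llt, codes)
}

fs_model <- function(m, u, p, n_iter, converged, ll_trace, codes) {
  if (max(abs(m - u)) < 1e-3)
    warning("m and u are numerically indistinguishable; the match class is ",
            "unidentifiable (degenerate agreement data)")
  structure(list(m = stats::setNames(m, codes), u = stats::setNames(u, codes),
                 p = p, n_iter = n_iter, converged = converged,
                 log_likelihood = ll_trace, codes = codes),
            class = "fs_model")
}

#' @export
print.fs_model <- function(x, ...) {
  cat(sprintf(paste0("<fs_model> K = %d, p = %.4g, mean m = %.3f, mean u = ",
                     "%.3f (%d iterations%s)\n"),
              length(x$m), x$p, mean(x$m), mean(x$u), x$n_iter,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Fellegi-Sunter agreement scores
#'
#' Per-pair score \eqn{\sum_k [\gamma_k \log(m_k/u_k) +
#' (1-\gamma_k)\log\{(1-m_k)/(1-u_k)\}]} where \eqn{\gamma_k} indicates
#' agreement on code k. Pairs outside the blocking mask carry no score
#' (`NA`).
#'
#' @param model a fitted [fs_em] model.
#' @param A,B [binary_records] objects.
#' @param align code alignment (must match the one used for fitting).
#' @param blocking optional admissibility mask.
#' @return an `nA x nB` matrix of class `fs_scores`.
#' @export
fs_scores <- function(model, A, B, align = align_codes(A, B), blocking = NULL) {
  Xa <- aligned_matrix(A, align, "a")
  Xb <- aligned_matrix(B, align, "b")
  if (length(model$m) != ncol(Xa))
    stop("model covers ", length(model$m), " codes but alignment has ", ncol(Xa))
  wa <- log(model$m / model$u) - log((1 - model$m) / (1 - model$u))
  s <- gamma_bilinear(Xa, Xb, wa) + sum(log((1 - model$m) / (1 - model$u)))
  if (!is.null(blocking)) s[!blocking] <- NA_real_
  structure(s, dimnames = list(rownames(A), rownames(B)),
            class = c("fs_scores", class(unclass(s))))
}

#' Classify pairs by Fellegi-Sunter score
#'
#' `fs_match_all` is the unmodified baseline: every admissible pair whose
#' score reaches the threshold is declared. `fs_match_best` is the
#' one-to-one variant: only the largest score per patient is eligible (ties
#' at the maximum are all kept); by default maximality is required in both
#' the row and the column, with a row-only mode for sensitivity analyses.
#'
#' @param scores an [fs_scores] matrix (blocked pairs `NA`).
#' @param threshold minimum score (default 0: more likely a match than
#'   not under the fitted model).
#' @param mode for `fs_match_best`: `"row_and_col"` (default) or
#'   `"row_only"`.
#' @return a `match_set` data.frame with columns `id_a`, `id_b`, `score`.
#' @export
fs_match_all <- function(scores, threshold = 0) {
  idx <- which(!is.na(unclass(scores)) & unclass(scores) >= threshold,
               arr.ind = TRUE)
  fs_match_set(scores, idx, threshold)
}

#' @rdname fs_match_all
#' @export
fs_match_best <- function(scores, threshold = 0,
                          mode = c("row_and_col", "row_only")) {
  mode <- match.arg(mode)
  s <- unclass(scores)
  rmax <- suppressWarnings(apply(s, 1L, max, na.rm = TRUE))  # -Inf if all NA
  keep <- !is.na(s) & s >= threshold & s == rmax
  if (mode == "row_and_col") {
    cmax <- suppressWarnings(apply(s, 2L, max, na.rm = TRUE))
    keep <- keep & sweep(s, 2L, cmax, "==")
  }
  keep[is.na(keep)] <- FALSE
  fs_match_set(scores, which(keep, arr.ind = TRUE), threshold)
}

fs_match_set <- function(scores, idx, threshold) {
  out <- data.frame(id_a = rownames(scores)[idx[, 1L]],
                    id_b = colnames(scores)[idx[, 2L]],
                    score = unclass(scores)[idx],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$id_a, out$id_b), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, threshold = threshold, class = c("match_set", "data.frame"))
}
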