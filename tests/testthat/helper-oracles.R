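# Independent oracles and small fixture builders, kept deliberately naive:
# per-pair per-code summation for the similarity, direct evaluation of the
# posterior formula, and a plain-loop latent-class EM.

random_records <- function(n, K, p = 0.1, prefix = "p", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rbinom(n * K, 1, p), n, K,
              dimnames = list(paste0(prefix, seq_len(n)),
                              sprintf("c%03d", seq_len(K))))
  binary_records(m)
}

# naive per-pair per-code similarity (the decomposition's ground truth)
oracle_similarity <- function(A, B, w, align) {
  Xa <- dxlink:::aligned_matrix(A, align, "a")
  Xb <- dxlink:::aligned_matrix(B, align, "b")
  out <- matrix(0, nrow(Xa), nrow(Xb))
  for (i in seq_len(nrow(Xa))) for (j in seq_len(nrow(Xb))) {
    a <- Xa[i, ]; b <- Xb[j, ]
    out[i, j] <- sum(ifelse(a == 1 & b == 1, w$w11,
                     ifelse(a == 0 & b == 0, w$w00,
                     ifelse(a == 1 & b == 0, w$w10, w$w01))))
  }
  out
}

# direct (non-log-space) evaluation of the directed posterior; only safe
# for moderate scores
oracle_posterior_row <- function(scores_row, pi_0) {
  e <- exp(scores_row + qlogis(pi_0))
  e / (1 + sum(e))
}

# plain latent-class EM over an explicit pair-by-code agreement matrix
oracle_fs_em <- function(A, B, align, m, u, p, tol = 1e-6, max_iter = 500L) {
  Xa <- dxlink:::aligned_matrix(A, align, "a")
  Xb <- dxlink:::aligned_matrix(B, align, "b")
  idx <- expand.grid(i = seq_len(nrow(Xa)), j = seq_len(nrow(Xb)))
  G <- 1 - abs(Xa[idx$i, , drop = FALSE] - Xb[idx$j, , drop = FALSE])
  for (iter in seq_len(max_iter)) {
    fm <- exp(G %*% log(m) + (1 - G) %*% log(1 - m))
    fu <- exp(G %*% log(u) + (1 - G) %*% log(1 - u))
    r <- as.vector(p * fm / (p * fm + (1 - p) * fu))
    m_new <- pmin(pmax(as.vector(t(G) %*% r) / sum(r), 1e-6), 1 - 1e-6)
    u_new <- pmin(pmax(as.vector(t(G) %*% (1 - r)) / sum(1 - r), 1e-6), 1 - 1e-6)
    p_new <- pmin(pmax(mean(r), 1e-6), 1 - 1e-6)
    delta <- max(abs(c(m_new - m, u_new - u, p_new - p)))
    m <- m_new; u <- u_new; p <- p_new
    if (delta < tol) break
  }
  list(m = m, u = u, p = p)
}

as_similarity <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- paste0("a", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("b", seq_len(ncol(m)))
  structure(m, class = c("similarity_matrix", class(unclass(m))))
}

as_averaged_posterior <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- paste0("a", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("b", seq_len(ncol(m)))
  structure(m, direction = "averaged",
            class = c("posterior_matrix", class(unclass(m))))
}

# shared heavy simulation grid (the scaled-down replication of the
# simulation study), computed once per test run
acceptance_grid <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- run_experiment_grid(rho = 0.5, K = 1000L, overlap_frac = 0.5,
                                    n_patients = 800L, n_a = 500L, n_b = 300L,
                                    mean_codes = 5, eps = 0.01, pi0 = "auto",
                                    n_replicates = 5L, seed = 123L)
    cache
  }
})
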