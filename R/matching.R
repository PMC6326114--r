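# Core Bayesian matching: per-code log-likelihood-ratio weights, pairwise
# similarity, directed posterior match probabilities with a no-match
# category, and the averaged-posterior decision rule.

clip_unit <- function(p, lo, hi = 1 - lo) pmin(pmax(p, lo), hi)

#' Per-code log-likelihood-ratio weights
#'
#' For code `k` with prevalence `pi_B[k]` in dataset B and discrepancy rates
#' `eps_minus[k]` (code present in A but absent in B for a true match) and
#' `eps_plus[k]` (absent in A, present in B), the four observation patterns
#' contribute the log-likelihood ratios
#' \deqn{w_{11} = \log\frac{1-\varepsilon^-}{\pi_B},\quad
#'       w_{00} = \log\frac{1-\varepsilon^+}{1-\pi_B},\quad
#'       w_{10} = \log\frac{\varepsilon^-}{1-\pi_B},\quad
#'       w_{01} = \log\frac{\varepsilon^+}{\pi_B}.}
#'
#' @param pi_B length-K vector of code prevalences in B, each in (0,1).
#' @param eps_minus,eps_plus discrepancy rates, scalar (broadcast to all
#'   codes) or length-K, each in (0,1).
#' @param codes optional code labels.
#' @param clip if `TRUE` (default) prevalences are clipped to
#'   `[eps_clip, 1-eps_clip]` with `eps_clip = 1e-6` for epsilons, and the
#'   caller is expected to have clipped `pi_B` already via
#'   [estimate_prevalence]; with `clip = FALSE` boundary values are an error.
#' @return An object of class `code_weights`: list of the four length-K
#'   weight vectors `w11`, `w00`, `w10`, `w01` plus `codes`.
#' @export
#' @examples
#' w <- code_weights(pi_B = 0.1, eps_minus = 0.01, eps_plus = 0.01)
#' w$w11  # log(0.99 / 0.1)
code_weights <- function(pi_B, eps_minus = 0.01, eps_plus = 0.01,
                         codes = NULL, clip = TRUE) {
  K <- length(pi_B)
  if (length(eps_minus) == 1L) eps_minus <- rep(eps_minus, K)
  if (length(eps_plus) == 1L) eps_plus <- rep(eps_plus, K)
  if (length(eps_minus) != K || length(eps_plus) != K)
    stop("eps_minus/eps_plus must be scalars or have the same length as pi_B")
  if (is.null(codes)) codes <- names(pi_B) %||% paste0("code", seq_len(K))
  if (clip) {
    eps_minus <- clip_unit(eps_minus, 1e-6)
    eps_plus <- clip_unit(eps_plus, 1e-6)
  }
  bad <- which(pi_B <= 0 | pi_B >= 1 | eps_minus <= 0 | eps_minus >= 1 |
                 eps_plus <= 0 | eps_plus >= 1)
  if (length(bad) > 0L)
    stop("hyper-parameters at or outside (0,1) for code(s): ",
         paste(utils::head(codes[bad], 5L), collapse = ", "))
  structure(list(w11 = log((1 - eps_minus) / pi_B),
                 w00 = log((1 - eps_plus) / (1 - pi_B)),
                 w10 = log(eps_minus / (1 - pi_B)),
                 w01 = log(eps_plus / pi_B),
                 codes = codes),
            class = "code_weights")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.code_weights <- function(x, ...) {
  cat(sprintf("<code_weights> K = %d; mean w11 = %.3f, mean w00 = %.3f\n",
              length(x$w11), mean(x$w11), mean(x$w00)))
  invisible(x)
}

#' Pairwise similarity scores
#'
#' The similarity between record i of A and record j of B is the naive-Bayes
#' log-likelihood ratio \eqn{\mathcal{L}(ij)=\sum_k \mathcal{L}_k(A_k(i),
#' B_k(j))}. It is evaluated through the exact rank-1 + bilinear
#' decomposition
#' \deqn{\mathcal{L}(ij) = \textstyle\sum_k w_{00,k} + r_i + c_j +
#'   [A\,\mathrm{diag}(d)\,B^\top]_{ij}}
#' with \eqn{r_i=\sum_k A_{ik}(w_{10,k}-w_{00,k})},
#' \eqn{c_j=\sum_k B_{jk}(w_{01,k}-w_{00,k})} and
#' \eqn{d_k=w_{11,k}-w_{10,k}-w_{01,k}+w_{00,k}}, which scales to thousands
#' of codes.
#'
#' @param A,B [binary_records] objects.
#' @param weights a [code_weights] object over the aligned codes.
#' @param align a [align_codes] result (defaults to the union alignment).
#' @return A numeric `nA x nB` matrix of class `similarity_matrix` with
#'   patient ids as dimnames.
#' @export
similarity_scores <- function(A, B, weights, align = align_codes(A, B)) {
  K <- length(align$codes)
  if (length(weights$w11) != K)
    stop("weights cover ", length(weights$w11), " codes but alignment has ", K)
  Xa <- aligned_matrix(A, align, "a")
  Xb <- aligned_matrix(B, align, "b")
  d <- weights$w11 - weights$w10 - weights$w01 + weights$w00
  base <- sum(weights$w00)
  r <- as.vector(Xa %*% (weights$w10 - weights$w00))
  cc <- as.vector(Xb %*% (weights$w01 - weights$w00))
  s <- Xa %*% (d * t(Xb))
  s <- s + outer(r, cc, "+") + base
  if (any(!is.finite(s))) stop("non-finite similarity scores; check hyper-parameters")
  structure(s, dimnames = list(rownames(A), rownames(B)),
            class = c("similarity_matrix", class(unclass(s))))
}

#' Directed posterior match probabilities
#'
#' For each record i of A, the candidate matches are the nB records of B
#' plus an explicit no-match category; the posterior that i matches j is
#' \deqn{\pi_{ij}(A\to B) =
#'   \frac{\exp\{\mathcal{L}(ij)+\mathrm{logit}(\pi_0)\}}
#'        {1+\sum_{\ell}\exp\{\mathcal{L}(i\ell)+\mathrm{logit}(\pi_0)\}}}
#' and symmetrically per column of B for the B-to-A direction. Evaluation is
#' done in log space with a max-shift so similarity scores in the hundreds
#' do not overflow.
#'
#' @param scores a [similarity_scores] matrix.
#' @param pi_0 prior match probability for a random cross-dataset pair,
#'   in (0,1).
#' @param direction `"A_to_B"` (normalize over rows) or `"B_to_A"`
#'   (over columns).
#' @return An `nA x nB` matrix of class `posterior_matrix` with attributes
#'   `direction` and `no_match` (the vector of leftover no-match masses, one
#'   per row or column).
#' @export
directed_posterior <- function(scores, pi_0, direction = c("A_to_B", "B_to_A")) {
  direction <- match.arg(direction)
  if (any(!is.finite(scores))) stop("similarity scores must be finite")
  if (length(pi_0) != 1L || pi_0 <= 0 || pi_0 >= 1)
    stop("pi_0 must be a single probability strictly inside (0,1)")
  s <- unclass(scores) + stats::qlogis(pi_0)
  margin <- if (direction == "A_to_B") 1L else 2L
  m <- pmax(apply(s, margin, max), 0)
  if (margin == 1L) {
    e <- exp(s - m)                       # recycles m down columns
    denom <- exp(-m) + rowSums(e)
    p <- e / denom
    nm <- exp(-m) / denom
  } else {
    e <- exp(sweep(s, 2L, m))
    denom <- exp(-m) + colSums(e)
    p <- sweep(e, 2L, denom, "/")
    nm <- exp(-m) / denom
  }
  structure(p, dimnames = dimnames(scores), direction = direction,
            no_match = nm, class = c("posterior_matrix", class(unclass(p))))
}

#' Average the two directed posterior matrices
#'
#' The final posterior match probability is the elementwise mean
#' \eqn{\hat\pi_{ij} = \{\hat\pi_{ij}(B\to A)+\hat\pi_{ij}(A\to B)\}/2}.
#'
#' @param p_ab posterior with direction `A_to_B`.
#' @param p_ba posterior with direction `B_to_A`.
#' @return a `posterior_matrix` with direction `"averaged"`.
#' @export
average_posterior <- function(p_ab, p_ba) {
  if (!identical(dim(p_ab), dim(p_ba)))
    stop("directed posterior matrices have different shapes")
  if (!identical(attr(p_ab, "direction"), "A_to_B") ||
      !identical(attr(p_ba, "direction"), "B_to_A"))
    stop("average_posterior expects one A_to_B and one B_to_A matrix, in that order")
  p <- (unclass(p_ab) + unclass(p_ba)) / 2
  attributes(p) <- list(dim = dim(p_ab), dimnames = dimnames(p_ab))
  structure(p, direction = "averaged",
            class = c("posterior_matrix", class(unclass(p))))
}

#' @export
print.posterior_matrix <- function(x, ...) {
  cat(sprintf("<posterior_matrix> %d x %d, direction %s, %d entries >= 0.5\n",
              nrow(x), ncol(x), attr(x, "direction"), sum(unclass(x) >= 0.5)))
  invisible(x)
}

#' Declare matches from the averaged posterior
#'
#' A pair is declared a match when its averaged posterior reaches the
#' threshold (`>= alpha`; ties at the threshold count as matches). 0.5 is
#' the natural cutoff (the pair is more likely a match than not); 0.9 suits
#' studies with low tolerance for false matches.
#'
#' @param posterior an averaged `posterior_matrix`.
#' @param alpha threshold in (0,1).
#' @return An object of class `match_set`: a data.frame with columns `id_a`,
#'   `id_b`, `posterior`, plus attribute `threshold`.
#' @export
match_pairs <- function(posterior, alpha = 0.5) {
  if (!identical(attr(posterior, "direction"), "averaged"))
    stop("match_pairs expects the averaged posterior matrix")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  idx <- which(unclass(posterior) >= alpha, arr.ind = TRUE)
  out <- data.frame(id_a = rownames(posterior)[idx[, 1L]],
                    id_b = colnames(posterior)[idx[, 2L]],
                    posterior = unclass(posterior)[idx],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$posterior, out$id_a, out$id_b), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, threshold = alpha, class = c("match_set", "data.frame"))
}

#' Write declared matches as TSV
#'
#' @param matches a `match_set` (or any data.frame of pairs).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_match_pairs <- function(matches, path) {
  utils::write.table(as.data.frame(matches), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pair list (matches or truth) from TSV
#'
#' @param path TSV with at least two columns: id in A, id in B.
#' @return data.frame with columns `id_a`, `id_b` (extra columns kept).
#' @export
read_pairs <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  names(df)[1:2] <- c("id_a", "id_b")
  df
}
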