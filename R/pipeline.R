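# End-to-end matching pipeline with a reproducible run report, plus the
# bridge for the anonymized RA benchmark distributed inside the CRAN
# 'ludic' package.

log_stage <- function(verbose, stage, fmt, ...) {
  if (verbose)
    message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ",
            sprintf(fmt, ...))
}

#' Run the full Bayesian matching pipeline
#'
#' Executes read -> align -> rare-code filter -> prevalence estimation ->
#' (optional automatic prior estimation via the skew-t fit and its
#' rightmost inflexion) -> per-code weights -> similarity -> directed
#' posteriors -> averaging -> thresholding, and returns the declared
#' matches together with the posterior matrix and a run report recording
#' every hyper-parameter actually used.
#'
#' @param A,B [binary_records] objects, or file paths accepted by
#'   [read_binary_records].
#' @param eps_minus,eps_plus discrepancy rates (scalar or per-code).
#' @param pi0 `"auto"` (default: skew-t fit + rightmost inflexion +
#'   exceedance fraction) or a fixed probability.
#' @param alpha posterior threshold for declaring matches.
#' @param policy code alignment policy (`"union"` or `"intersection"`).
#' @param min_count rare-code pre-filter: keep codes recorded at least this
#'   many times in the pooled data (default 1).
#' @param pi0_max_sample subsample cap for the skew-t fit.
#' @param seed seed used for any subsampling.
#' @param verbose log per-stage progress.
#' @return list of class `dxlink_run`: `matches` (a `match_set`),
#'   `posterior` (averaged `posterior_matrix`), and `report` (list with the
#'   hyper-parameters used, dataset sizes, package version, seed and
#'   elapsed wall time).
#' @export
match_pipeline <- function(A, B, eps_minus = 0.01, eps_plus = 0.01,
                           pi0 = "auto", alpha = 0.5,
                           policy = c("union", "intersection"),
                           min_count = 1L, pi0_max_sample = 5e6,
                           seed = 1L, verbose = FALSE) {
  policy <- match.arg(policy)
  t0 <- proc.time()[["elapsed"]]
  if (is.character(A)) A <- read_binary_records(A)
  if (is.character(B)) B <- read_binary_records(B)
  log_stage(verbose, "read", "A: %d x %d, B: %d x %d",
            nrow(A), ncol(A), nrow(B), ncol(B))
  align <- align_codes(A, B, policy)
  if (min_count > 1L) align <- filter_rare_codes(align, A, B, min_count)
  log_stage(verbose, "align", "%d codes (%s)", length(align$codes), policy)
  pi_B <- estimate_prevalence(B)[match(align$codes, colnames(B))]
  pi_B[is.na(pi_B)] <- 1 / (2 * nrow(B))
  w <- code_weights(pi_B, eps_minus, eps_plus, codes = align$codes)
  sc <- similarity_scores(A, B, w, align)
  log_stage(verbose, "similarity", "range [%.2f, %.2f]", min(sc), max(sc))
  pi0_detail <- NULL
  if (identical(pi0, "auto")) {
    est <- auto_pi0(sc, max_sample = pi0_max_sample, subsample_seed = seed)
    pi0_used <- est$pi_0
    pi0_detail <- list(c0 = est$c0,
                       skew_t = est$fit[c("xi", "omega", "alpha", "nu")])
    log_stage(verbose, "pi0", "c0 = %.3f, pi0 = %.3g", est$c0, pi0_used)
  } else {
    pi0_used <- pi0
  }
  post <- average_posterior(directed_posterior(sc, pi0_used, "A_to_B"),
                            directed_posterior(sc, pi0_used, "B_to_A"))
  matches <- match_pairs(post, alpha)
  log_stage(verbose, "match", "%d pairs at alpha = %.2f", nrow(matches), alpha)
  report <- list(n_a = nrow(A), n_b = nrow(B), K = length(align$codes),
                 policy = policy, min_count = min_count,
                 eps_minus = eps_minus, eps_plus = eps_plus,
                 pi0_mode = if (identical(pi0, "auto")) "auto" else "fixed",
                 pi0_used = pi0_used, pi0_detail = pi0_detail,
                 alpha = alpha, seed = seed,
                 package_version = as.character(utils::packageVersion("dxlink")),
                 elapsed_s = proc.time()[["elapsed"]] - t0)
  structure(list(matches = matches, posterior = post, report = report),
            class = "dxlink_run")
}

#' @export
print.dxlink_run <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0("<dxlink_run> %d x %d patients over %d codes; pi0 = ",
                     "%.3g (%s); %d matches at alpha = %.2f (%.1f s)\n"),
              r$n_a, r$n_b, r$K, r$pi0_used, r$pi0_mode,
              nrow(x$matches), r$alpha, r$elapsed_s))
  invisible(x)
}

#' Export / load the anonymized RA benchmark from the CRAN 'ludic' package
#'
#' The anonymized RA1/RA2 binarized diagnosis-code matrices and the
#' silver-standard match pairs are distributed inside the CRAN package
#' \pkg{ludic}. `export_ludic_benchmark()` writes them to the package's CSV
#' dialect (requires \pkg{ludic} to be installed); `read_ludic_benchmark()`
#' loads such an export for use as ordinary inputs.
#'
#' @param dir directory to write to / read from.
#' @param span `"6y"` or `"11y"` time span variant.
#' @return `export_ludic_benchmark`: the directory, invisibly.
#'   `read_ludic_benchmark`: list with `RA1`, `RA2` ([binary_records]) and
#'   `silver` (data.frame `id_a`, `id_b`).
#' @export
export_ludic_benchmark <- function(dir) {
  if (!requireNamespace("ludic", quietly = TRUE))
    stop("the 'ludic' package is not installed; the benchmark cannot be exported")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  env <- new.env()
  utils::data("RA1", "RA2", "silverstandard_truematches", package = "ludic",
              envir = env)
  objs <- as.list(env)
  write_side <- function(m, name) {
    m <- as.matrix(m)
    write_binary_records(binary_records((m > 0) * 1,
                                        patient_ids = rownames(m),
                                        code_ids = colnames(m)),
                         file.path(dir, paste0(name, ".csv")))
  }
  write_side(objs$RA1, "RA1")
  write_side(objs$RA2, "RA2")
  ss <- as.data.frame(objs$silverstandard_truematches,
                      stringsAsFactors = FALSE)
  names(ss)[1:2] <- c("id_a", "id_b")
  utils::write.table(ss, file.path(dir, "silver_standard.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname export_ludic_benchmark
#' @export
read_ludic_benchmark <- function(dir) {
  paths <- file.path(dir, c("RA1.csv", "RA2.csv", "silver_standard.tsv"))
  if (!all(file.exists(paths)))
    stop("benchmark export not found under '", dir,
         "'; run export_ludic_benchmark() on a machine with the 'ludic' ",
         "package installed")
  list(RA1 = read_binary_records(paths[1L]),
       RA2 = read_binary_records(paths[2L]),
       silver = read_pairs(paths[3L]))
}
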