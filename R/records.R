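#' Binary patient-by-code record matrix
#'
#' The basic data container: one dataset's patients-by-codes matrix of
#' presence/absence indicators (1 = code ever recorded for the patient,
#' 0 = never), with unique patient identifiers as row names and unique code
#' labels as column names.
#'
#' @param x matrix (or object coercible to one) of 0/1 indicators.
#' @param patient_ids optional character vector of unique patient
#'   identifiers; defaults to `rownames(x)`.
#' @param code_ids optional character vector of unique code labels; defaults
#'   to `colnames(x)`.
#'
#' @return A numeric matrix of class `binary_records` with `patient_ids` as
#'   row names and `code_ids` as column names.
#' @export
#' @examples
#' binary_records(rbind(p1 = c(a = 1, b = 0), p2 = c(a = 0, b = 1)))
binary_records <- function(x, patient_ids = NULL, code_ids = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!is.null(patient_ids)) rownames(x) <- as.character(patient_ids)
  if (!is.null(code_ids)) colnames(x) <- as.character(code_ids)
  validate_binary_records(x)
  class(x) <- c("binary_records", class(unclass(x)))
  x
}

validate_binary_records <- function(x) {
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("binary_records requires patient ids (row names) and code ids (column names)")
  if (anyDuplicated(rownames(x)))
    stop("duplicate patient ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate code ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  bad <- which(!(x == 0 | x == 1), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-binary cell at patient '%s', code '%s' (value %s)",
                 rownames(x)[bad[1L, 1L]], colnames(x)[bad[1L, 2L]],
                 format(x[bad[1L, , drop = FALSE]])))
  invisible(x)
}

#' @export
print.binary_records <- function(x, ...) {
  cat(sprintf("<binary_records> %d patients x %d codes, %.2f codes/patient\n",
              nrow(x), ncol(x), mean(rowSums(unclass(x)))))
  invisible(x)
}

#' Read a binary record dataset from CSV/TSV or MatrixMarket files
#'
#' The dense dialect is a delimited table whose first column holds the
#' patient identifier and whose header row holds the code labels, cells
#' being 0 or 1. The sparse dialect is a MatrixMarket `.mtx` file plus two
#' sidecar line-lists (one id per line) for patient and code ids.
#'
#' @param path file path (`.csv`, `.tsv`/`.txt`, or `.mtx`).
#' @param format `"auto"` (from extension), `"csv"`, `"tsv"` or `"mtx"`.
#' @param patient_ids_path,code_ids_path sidecar paths for the `mtx` format;
#'   default to `<path>.patients` / `<path>.codes`.
#' @return a [binary_records] object.
#' @export
read_binary_records <- function(path,
                                format = c("auto", "csv", "tsv", "mtx"),
                                patient_ids_path = NULL,
                                code_ids_path = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  if (format == "mtx") {
    if (is.null(patient_ids_path)) patient_ids_path <- paste0(path, ".patients")
    if (is.null(code_ids_path)) code_ids_path <- paste0(path, ".codes")
    m <- as.matrix(Matrix::readMM(path))
    pid <- readLines(patient_ids_path)
    cid <- readLines(code_ids_path)
    if (nrow(m) != length(pid) || ncol(m) != length(cid))
      stop("mtx dimensions do not match the id sidecars")
    return(binary_records(m, patient_ids = pid, code_ids = cid))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("expected a patient-id column plus at least one code column")
  pid <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at row %d (patient '%s'), column '%s'",
                 bad[1L], pid[bad[1L]], colnames(m)[bad[2L]]))
  }
  binary_records(m, patient_ids = pid, code_ids = colnames(m))
}

#' Write a binary record dataset
#'
#' @param x a [binary_records] object.
#' @inheritParams read_binary_records
#' @return `path`, invisibly.
#' @export
write_binary_records <- function(x, path,
                                 format = c("auto", "csv", "tsv", "mtx"),
                                 patient_ids_path = NULL,
                                 code_ids_path = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  if (format == "mtx") {
    if (is.null(patient_ids_path)) patient_ids_path <- paste0(path, ".patients")
    if (is.null(code_ids_path)) code_ids_path <- paste0(path, ".codes")
    Matrix::writeMM(Matrix::Matrix(unclass(x), sparse = TRUE), path)
    writeLines(rownames(x), patient_ids_path)
    writeLines(colnames(x), code_ids_path)
    return(invisible(path))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- data.frame(patient_id = rownames(x), unclass(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align the code sets of two datasets
#'
#' Builds the ordered list of codes used for linkage: by default the union
#' of codes recorded at least once in either dataset (codes missing from one
#' side behave as all-absent columns there), or their intersection. Code
#' order is lexicographic so runs are reproducible regardless of input
#' column order.
#'
#' @param A,B [binary_records] objects.
#' @param policy `"union"` (default) or `"intersection"`.
#' @return An object of class `code_alignment`: list with `codes`,
#'   `index_a`, `index_b` (`NA` where absent, only possible under union) and
#'   `policy`.
#' @export
align_codes <- function(A, B, policy = c("union", "intersection")) {
  policy <- match.arg(policy)
  ca <- colnames(A); cb <- colnames(B)
  codes <- if (policy == "union") sort(union(ca, cb)) else sort(intersect(ca, cb))
  if (length(codes) == 0L)
    stop("no shared codes between the two datasets under policy '", policy, "'")
  structure(list(codes = codes,
                 index_a = match(codes, ca),
                 index_b = match(codes, cb),
                 policy = policy),
            class = "code_alignment")
}

#' @export
print.code_alignment <- function(x, ...) {
  cat(sprintf("<code_alignment> %d codes (%s policy), absent in A: %d, in B: %d\n",
              length(x$codes), x$policy, sum(is.na(x$index_a)), sum(is.na(x$index_b))))
  invisible(x)
}

# Reindex a dataset to the aligned code order; codes absent on this side
# (union policy) become all-zero columns.
aligned_matrix <- function(D, align, side = c("a", "b")) {
  side <- match.arg(side)
  idx <- if (side == "a") align$index_a else align$index_b
  out <- matrix(0, nrow(D), length(align$codes),
                dimnames = list(rownames(D), align$codes))
  pres <- !is.na(idx)
  out[, pres] <- unclass(D)[, idx[pres], drop = FALSE]
  out
}

#' Drop extremely rare codes from an alignment
#'
#' Extremely rare codes can dominate the likelihood-ratio weights, so an
#' optional pre-filter keeps only codes recorded at least `min_count` times
#' in the pooled data.
#'
#' @param align a [align_codes] result.
#' @param A,B the two datasets the alignment was built from.
#' @param min_count minimum pooled recording count (default 1, i.e. keep
#'   codes seen at least once).
#' @return a filtered `code_alignment`.
#' @export
filter_rare_codes <- function(align, A, B, min_count = 1L) {
  pooled <- colSums(aligned_matrix(A, align, "a")) +
    colSums(aligned_matrix(B, align, "b"))
  keep <- pooled >= min_count
  if (!any(keep)) stop("rare-code filter removed every code (min_count = ",
                       min_count, ")")
  structure(list(codes = align$codes[keep],
                 index_a = align$index_a[keep],
                 index_b = align$index_b[keep],
                 policy = align$policy),
            class = "code_alignment")
}
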