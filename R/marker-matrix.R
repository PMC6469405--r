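#' Marker matrix with a recorded coding shift
#'
#' A `marker_matrix` is an n x p numeric matrix of allele dosages (rows =
#' lines/individuals, columns = markers) together with a p-vector `shift`
#' recording the translation already subtracted from the raw coding.  A raw
#' 0/1 or 0/1/2 matrix has `shift = 0`; column-mean centering stores the
#' column means in `shift`, and so on.  Keeping the shift with the data means
#' downstream fits can record the coding they were trained in and re-apply it
#' at prediction time.
#'
#' @param values numeric matrix of dosages, no missing values.
#' @param line_ids character vector of row labels (defaults to rownames).
#' @param marker_ids character vector of column labels (defaults to colnames).
#' @param shift numeric p-vector already subtracted from the raw coding.
#'
#' @return An object of class `marker_matrix`: a list with elements `values`
#'   (labelled numeric matrix) and `shift`.
#' @examples
#' M <- marker_matrix(matrix(c(2, 2, 1, 2, 2, 0, 2, 1, 1, 0),
#'   ncol = 2, byrow = TRUE))
#' column_means(M)
#' translate_markers(M, "column_mean")
#' @export
marker_matrix <- function(values, line_ids = rownames(values),
                          marker_ids = colnames(values),
                          shift = numeric(ncol(values))) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("marker matrix must have at least one line and one marker")
  if (anyNA(values))
    stop("marker matrix contains missing values; impute before construction")
  if (is.null(line_ids)) line_ids <- paste0("line", seq_len(nrow(values)))
  if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(ncol(values)))
  if (length(line_ids) != nrow(values) || length(marker_ids) != ncol(values))
    stop("label lengths do not match matrix dimensions")
  if (length(shift) == 1L) shift <- rep(shift, ncol(values))
  if (length(shift) != ncol(values))
    stop("shift must have one entry per marker")
  dimnames(values) <- list(as.character(line_ids), as.character(marker_ids))
  structure(list(values = values, shift = as.numeric(shift)),
            class = "marker_matrix")
}

#' Coerce to a marker matrix
#'
#' @param x a `marker_matrix`, or a numeric matrix / data frame of dosages
#'   (treated as raw coding, `shift = 0`).
#' @return A `marker_matrix`.
#' @export
as_marker_matrix <- function(x) {
  if (inherits(x, "marker_matrix")) return(x)
  marker_matrix(as.matrix(x))
}

#' @export
as.matrix.marker_matrix <- function(x, ...) x$values

#' @export
dim.marker_matrix <- function(x) dim(x$values)

#' @export
dimnames.marker_matrix <- function(x) dimnames(x$values)

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d lines x %d markers\n",
              nrow(x$values), ncol(x$values)))
  if (any(x$shift != 0)) {
    cat("coding shift (first entries):",
        paste(signif(utils::head(x$shift, 5), 4), collapse = ", "),
        if (length(x$shift) > 5) "..." else "", "\n")
  } else {
    cat("coding shift: none (raw coding)\n")
  }
  print(utils::head(x$values, 6))
  if (nrow(x$values) > 6) cat("...\n")
  invisible(x)
}

#' Per-marker column means
#'
#' @param M a `marker_matrix` or numeric matrix.
#' @return Named numeric p-vector of column means.
#' @export
column_means <- function(M) {
  colMeans(as.matrix(as_marker_matrix(M)))
}

#' Translate the marker coding
#'
#' Subtracts a constant row vector P from every row of the marker matrix,
#' i.e. forms `M - 1_n P^t`.  The applied shift accumulates in the `shift`
#' field so the total translation relative to the raw coding is always known.
#'
#' Modes:
#' \describe{
#'   \item{`none`}{identity, P = 0.}
#'   \item{`column_mean`}{P = column means; translated columns sum to zero
#'     (the allele-frequency-centred coding of common practice).}
#'   \item{`symmetric`}{P = `max_dosage / 2` for every marker, turning a
#'     0..max coding into a symmetric one (0/1 becomes -0.5/+0.5).}
#'   \item{`constant`}{P supplied by the caller, either a scalar or a
#'     p-vector.}
#' }
#'
#' @param M a `marker_matrix` or numeric matrix.
#' @param mode one of `"none"`, `"column_mean"`, `"symmetric"`, `"constant"`.
#' @param P translation vector (or scalar) for `mode = "constant"`.
#' @param max_dosage maximum dosage of the raw coding, required for
#'   `mode = "symmetric"` (1 for presence/absence, 2 for diploid counts).
#' @return A translated `marker_matrix` with updated `shift`.
#' @export
translate_markers <- function(M,
                              mode = c("none", "column_mean", "symmetric",
                                       "constant"),
                              P = NULL, max_dosage = NULL) {
  M <- as_marker_matrix(M)
  mode <- match.arg(mode)
  p <- ncol(M$values)
  P <- switch(mode,
    none = numeric(p),
    column_mean = colMeans(M$values),
    symmetric = {
      if (is.null(max_dosage) || max_dosage <= 0)
        stop("mode = 'symmetric' requires a positive max_dosage")
      rep(max_dosage / 2, p)
    },
    constant = {
      if (is.null(P)) stop("mode = 'constant' requires P")
      if (length(P) == 1L) P <- rep(P, p)
      as.numeric(P)
    })
  if (length(P) != p)
    stop(sprintf("P has length %d but the matrix has %d markers",
                 length(P), p))
  values <- sweep(M$values, 2L, P, `-`)
  marker_matrix(values, shift = M$shift + P)
}

# Detect the field separator of a delimited text file (tab or comma).
.detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("file '", path, "' is empty")
  if (grepl("\t", first)) "\t" else ","
}

#' Read a marker matrix from delimited text or VCF
#'
#' Delimited files (TSV or CSV, auto-detected) must carry a header row of
#' marker IDs and a first column of line IDs; entries are numeric allele
#' dosages.  VCF files are read through the \pkg{vcfR} package: the GT field
#' of each biallelic site is converted to the per-sample count of the
#' alternate allele (the usual dosage convention: 0/0, 0/1, 1/1 become
#' 0, 1, 2); phased and unphased genotypes are treated identically;
#' multi-allelic sites are rejected.
#'
#' @param path path to the file.
#' @param format `"delimited"` or `"vcf"`; `"auto"` picks `"vcf"` for
#'   `.vcf`/`.vcf.gz` extensions.
#' @param impute `"none"` (missing entries are an error, naming the offending
#'   row and column) or `"column_mean"` (missing entries replaced by the mean
#'   of the observed entries in their column).
#' @return A `marker_matrix` with `shift = 0`.
#' @export
read_marker_matrix <- function(path, format = c("auto", "delimited", "vcf"),
                               impute = c("none", "column_mean")) {
  format <- match.arg(format)
  impute <- match.arg(impute)
  if (!file.exists(path)) stop("file '", path, "' does not exist")
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "delimited"
  raw <- switch(format,
                delimited = .read_delimited_markers(path),
                vcf = .read_vcf_dosages(path))
  .impute_markers(raw, impute, path)
}

.read_delimited_markers <- function(path) {
  sep <- .detect_sep(path)
  nf <- utils::count.fields(path, sep = sep, quote = "\"")
  if (length(unique(nf)) != 1L)
    stop("ragged rows in '", path, "': rows have between ",
         min(nf), " and ", max(nf), " fields")
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          row.names = 1L, check.names = FALSE,
                          colClasses = "character", comment.char = "")
  values <- suppressWarnings(
    matrix(as.numeric(as.matrix(df)), nrow = nrow(df),
           dimnames = dimnames(df)))
  bad <- which(is.na(values) & as.matrix(df) != "NA" &
                 as.matrix(df) != "", arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric entry at line '%s', marker '%s' in '%s'",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
                 path))
  values
}

.read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  if (any(multi))
    stop("multi-allelic sites are not supported (first at record ",
         which(multi)[1], ")")
  gt <- vcfR::extract.gt(v, element = "GT")
  # dosage = count of the alternate allele (0/0 -> 0, 0/1 -> 1, 1/1 -> 2);
  # phased and unphased genotypes are treated identically
  count_alt <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles == "1")
  }
  dos <- apply(gt, c(1, 2), count_alt)
  ids <- rownames(dos)
  if (is.null(ids) || anyDuplicated(ids))
    ids <- paste0("site", seq_len(nrow(dos)))
  # samples become rows
  t(matrix(dos, nrow = nrow(dos),
           dimnames = list(ids, colnames(dos))))
}

.impute_markers <- function(values, impute, path) {
  if (anyNA(values)) {
    if (impute == "none") {
      bad <- which(is.na(values), arr.ind = TRUE)
      stop(sprintf(
        "missing value at line '%s', marker '%s' in '%s' (impute = 'none')",
        rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]], path))
    }
    for (j in seq_len(ncol(values))) {
      nas <- is.na(values[, j])
      if (any(nas)) {
        if (all(nas))
          stop("marker '", colnames(values)[j], "' has no observed values")
        values[nas, j] <- mean(values[!nas, j])
      }
    }
  }
  marker_matrix(values)
}

#' Write a marker matrix as tab-delimited text
#'
#' The written file round-trips through [read_marker_matrix()] exactly.
#' Note only the current values are written; the coding shift is not stored
#' in the file.
#'
#' @param M a `marker_matrix` or numeric matrix.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_marker_matrix <- function(M, path) {
  M <- as_marker_matrix(M)
  df <- data.frame(line_id = rownames(M$values), M$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype vector from delimited text
#'
#' Expects two columns, line ID and value, with a header (TSV or CSV,
#' auto-detected).
#'
#' @param path path to the file.
#' @return Named numeric vector (names are line IDs).
#' @export
read_phenotype <- function(path) {
  if (!file.exists(path)) stop("file '", path, "' does not exist")
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("phenotype file needs columns: line_id, value")
  y <- as.numeric(df[[2]])
  if (anyNA(y)) stop("non-numeric or missing phenotype value in '", path, "'")
  names(y) <- as.character(df[[1]])
  y
}

#' Write a phenotype vector as tab-delimited text
#'
#' @param y named numeric vector.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_phenotype <- function(y, path) {
  ids <- names(y)
  if (is.null(ids)) ids <- paste0("line", seq_along(y))
  utils::write.table(data.frame(line_id = ids, value = as.numeric(y)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Align a phenotype to a marker matrix by line id; errors on mismatch.
align_phenotype <- function(M, y) {
  M <- as_marker_matrix(M)
  if (is.null(names(y))) {
    if (length(y) != nrow(M$values))
      stop("phenotype length does not match the number of lines")
    return(as.numeric(y))
  }
  idx <- match(rownames(M$values), names(y))
  if (anyNA(idx))
    stop("phenotype is missing lines: ",
         paste(utils::head(rownames(M$values)[is.na(idx)], 5),
               collapse = ", "))
  as.numeric(y[idx])
}
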