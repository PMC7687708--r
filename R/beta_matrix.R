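#' Construct a beta-value matrix
#'
#' A `BetaMatrix` is a numeric matrix of DNA-methylation beta values
#' (methylation fraction, 0 = unmethylated, 1 = fully methylated) with CpG
#' identifiers as row names and sample identifiers as column names. Missing
#' measurements are `NA`. The object records whether the input was rescaled
#' from pyrosequencing-style percentages in the `"scale_note"` attribute.
#'
#' @param values numeric matrix, CpGs in rows, samples in columns; row and
#'   column names must be unique and non-empty.
#' @param scale_note `"unit"` if values were already fractions, `"percent"`
#'   if they were divided by 100 on import.
#' @return a `BetaMatrix` (numeric matrix subclass).
#' @export
beta_matrix <- function(values, scale_note = "unit") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      (ncol(values) > 0L && is.null(colnames(values))))
    stop("beta matrix requires CpG row names and sample column names")
  if (is.null(dimnames(values)))
    dimnames(values) <- list(character(0), character(0))
  m <- values
  attr(m, "scale_note") <- scale_note
  class(m) <- c("BetaMatrix", "matrix", "array")
  validate_beta_matrix(m)
  m
}

#' Validate beta-matrix invariants
#'
#' Checks that all non-missing values lie in \[0, 1\] (tolerance 1e-9) and
#' that CpG and sample identifiers are unique.
#'
#' @param m matrix with row/column names.
#' @param tol numeric tolerance for range violations.
#' @return `m`, invisibly; errors describe the first violation found.
#' @export
validate_beta_matrix <- function(m, tol = 1e-9) {
  cpgs <- rownames(m)
  samples <- colnames(m)
  dup <- cpgs[duplicated(cpgs)]
  if (length(dup)) stop("duplicate CpG id(s): ", paste(unique(dup), collapse = ", "))
  dup <- samples[duplicated(samples)]
  if (length(dup)) stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  v <- m[!is.na(m)]
  if (length(v) && (min(v) < -tol || max(v) > 1 + tol)) {
    bad <- which(!is.na(m) & (m < -tol | m > 1 + tol), arr.ind = TRUE)[1L, ]
    stop(sprintf("beta value out of [0,1]: %.6g at CpG '%s', sample '%s'",
                 m[bad[1L], bad[2L]], cpgs[bad[1L]], samples[bad[2L]]))
  }
  invisible(m)
}

#' @export
print.BetaMatrix <- function(x, ...) {
  cat(sprintf("BetaMatrix: %d CpGs x %d samples (scale: %s, %d missing)\n",
              nrow(x), ncol(x), attr(x, "scale_note") %||% "unit",
              sum(is.na(x))))
  n <- min(5L, nrow(x)); p <- min(5L, ncol(x))
  if (n && p) print(unclass(x)[seq_len(n), seq_len(p), drop = FALSE], ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a beta-value matrix from delimited text
#'
#' Reads a TSV/CSV with one header row and one key column. BeadChip-style
#' fractional beta values and pyrosequencing-style percentages are both
#' accepted: under `scale = "auto"` the matrix is divided by 100 whenever any
#' finite value exceeds 1.5 (a genuine beta matrix never reaches that, while
#' minor >1 artifacts are tolerated and clipped).
#'
#' @param path file path; `.csv` is comma-separated, anything else tab.
#' @param orientation `"cpg_rows"` (default, CpGs in rows) or
#'   `"sample_rows"` (transposed on input).
#' @param scale `"auto"`, `"unit"` (values already fractions) or
#'   `"percent"` (always divide by 100).
#' @param missing_tokens character cell values treated as missing
#'   (case-insensitive; the empty string is always missing).
#' @return a [beta_matrix()] in CpG-rows orientation.
#' @export
load_beta_matrix <- function(path, orientation = c("cpg_rows", "sample_rows"),
                             scale = c("auto", "unit", "percent"),
                             missing_tokens = c("", "NA", "NaN")) {
  orientation <- match.arg(orientation)
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = .guess_sep(path),
                          check.names = FALSE, colClasses = "character",
                          na.strings = NULL, comment.char = "",
                          quote = "\"", stringsAsFactors = FALSE)
  if (ncol(df) < 1L) stop("no key column found in ", path)
  keys <- df[[1L]]
  cols <- names(df)[-1L]
  vals <- matrix(NA_real_, nrow = nrow(df), ncol = length(cols),
                 dimnames = list(keys, cols))
  missing_tokens <- tolower(missing_tokens)
  for (j in seq_along(cols)) {
    raw <- df[[j + 1L]]
    miss <- tolower(trimws(raw)) %in% missing_tokens
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !miss)
    if (length(bad))
      stop(sprintf("unparseable cell '%s' at row %d, column '%s' of %s",
                   raw[bad[1L]], bad[1L], cols[j], path))
    num[miss] <- NA_real_
    vals[, j] <- num
  }
  if (orientation == "sample_rows") vals <- t(vals)
  dup <- rownames(vals)[duplicated(rownames(vals))]
  if (length(dup)) stop("duplicate CpG id(s): ", paste(unique(dup), collapse = ", "))
  dup <- colnames(vals)[duplicated(colnames(vals))]
  if (length(dup)) stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))

  note <- "unit"
  finite_max <- suppressWarnings(max(vals, na.rm = TRUE))
  if (scale == "percent" ||
      (scale == "auto" && is.finite(finite_max) && finite_max > 1.5)) {
    vals <- vals / 100
    note <- "percent"
  }
  tol <- 1e-9
  if (any(!is.na(vals) & (vals < -tol | vals > 1 + tol))) {
    bad <- which(!is.na(vals) & (vals < -tol | vals > 1 + tol), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "value out of [0,1] after scaling: %.6g at CpG '%s', sample '%s'",
      vals[bad[1L], bad[2L]], rownames(vals)[bad[1L]], colnames(vals)[bad[2L]]))
  }
  vals[!is.na(vals) & vals < 0] <- 0
  vals[!is.na(vals) & vals > 1] <- 1
  beta_matrix(vals, scale_note = note)
}

#' Write a beta-value matrix to tab-separated text
#'
#' CpGs as rows, samples as columns, 15 significant digits so that a
#' write/load round trip reproduces values to better than 1e-12. Row and
#' column order follow the matrix.
#'
#' @param m beta matrix (or any numeric matrix with dimnames).
#' @param path output file path.
#' @param key_name header of the CpG id column.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(m, path, key_name = "cpg_id") {
  header <- paste(c(key_name, colnames(m)), collapse = "\t")
  if (nrow(m) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], .fmt_num(m[i, ])), collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a sample annotation table
#'
#' Expects delimited text with columns `sample_id` and `cell_type`, plus
#' optional `study_id` and `split` (values `train`/`validation`). This is how
#' a fixed training/validation partition of reference profiles is encoded.
#'
#' @param path file path (TSV, or CSV by extension).
#' @return data.frame with one row per sample.
#' @export
load_sample_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ann <- utils::read.table(path, header = TRUE, sep = .guess_sep(path),
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "\"", comment.char = "")
  required <- c("sample_id", "cell_type")
  miss <- setdiff(required, names(ann))
  if (length(miss))
    stop("annotation is missing required column(s): ", paste(miss, collapse = ", "))
  ann$sample_id <- as.character(ann$sample_id)
  ann$cell_type <- as.character(ann$cell_type)
  dup <- ann$sample_id[duplicated(ann$sample_id)]
  if (length(dup))
    stop("duplicate sample_id(s): ", paste(unique(dup), collapse = ", "))
  if ("split" %in% names(ann)) {
    ok <- is.na(ann$split) | ann$split %in% c("train", "validation")
    if (!all(ok))
      stop("invalid split value(s): ",
           paste(unique(ann$split[!ok]), collapse = ", "),
           " (expected 'train' or 'validation')")
  }
  ann
}

#' Read a probe list
#'
#' Plain text, one CpG id per line; blank lines and `#` comments ignored.
#'
#' @param path file path.
#' @return character vector of CpG ids.
#' @export
read_probe_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Specify probe filters
#'
#' Platform-derived constraints (e.g. restricting to CpGs shared between the
#' 450K and EPIC BeadChips, dropping sex-chromosome probes) are expressed as
#' user-supplied keep/drop lists rather than parsed from array manifests.
#' `drop_missing` removes any CpG with at least one missing value, the usual
#' "probes shared across all samples" filter.
#'
#' @param keep_list optional character vector of CpG ids to retain.
#' @param drop_list optional character vector of CpG ids to remove
#'   (applied after `keep_list`).
#' @param drop_missing drop CpGs with any missing value?
#' @return a `ProbeFilterSpec` list.
#' @export
probe_filter_spec <- function(keep_list = NULL, drop_list = NULL,
                              drop_missing = FALSE) {
  structure(list(keep_list = keep_list, drop_list = drop_list,
                 drop_missing = isTRUE(drop_missing)),
            class = "ProbeFilterSpec")
}

#' Filter probes of a beta matrix
#'
#' Rows are restricted to `keep_list` (if given), minus `drop_list`, minus —
#' when `drop_missing` — any CpG carrying a missing value. Surviving CpGs
#' keep their original order. Filtering is idempotent.
#'
#' @param m beta matrix.
#' @param spec a [probe_filter_spec()].
#' @return filtered beta matrix.
#' @export
filter_probes <- function(m, spec) {
  stopifnot(inherits(spec, "ProbeFilterSpec"))
  keep <- rownames(m)
  if (!is.null(spec$keep_list)) keep <- keep[keep %in% spec$keep_list]
  if (!is.null(spec$drop_list)) keep <- keep[!keep %in% spec$drop_list]
  if (spec$drop_missing) {
    has_na <- rownames(m)[rowSums(is.na(m)) > 0L]
    keep <- keep[!keep %in% has_na]
  }
  if (!length(keep))
    stop("no CpGs survive filtering; inspect keep/drop lists and missingness")
  out <- m[keep, , drop = FALSE]
  beta_matrix(out, scale_note = attr(m, "scale_note") %||% "unit")
}

#' Align a beta matrix with a sample annotation
#'
#' Restricts both to the intersection of sample ids, in the matrix's column
#' order. Dropped ids on either side are reported in a warning.
#'
#' @param m beta matrix.
#' @param ann annotation data.frame with a `sample_id` column.
#' @return list with elements `matrix` and `annotation`.
#' @export
align_samples <- function(m, ann) {
  common <- intersect(colnames(m), ann$sample_id)
  if (!length(common)) stop("no samples shared between matrix and annotation")
  common <- colnames(m)[colnames(m) %in% common]  # matrix order
  dropped <- c(setdiff(colnames(m), common), setdiff(ann$sample_id, common))
  if (length(dropped))
    warning("dropping unmatched sample(s): ", paste(dropped, collapse = ", "))
  m2 <- beta_matrix(m[, common, drop = FALSE],
                    scale_note = attr(m, "scale_note") %||% "unit")
  ann2 <- ann[match(common, ann$sample_id), , drop = FALSE]
  rownames(ann2) <- NULL
  list(matrix = m2, annotation = ann2)
}
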