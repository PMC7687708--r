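#' Build the marker-CpG reference matrix
#'
#' Entry (i, j) is the arithmetic mean beta value of marker CpG i over the
#' (training) samples annotated with cell type j. The resulting matrix is
#' the basis of reference-based deconvolution. Its condition number is
#' checked: near-collinear cell-type profiles (e.g. fibroblast-like
#' classes) destabilize the least-squares fit, so conditions above 1e6
#' trigger a warning, as does rank deficiency.
#'
#' @param m beta matrix of labelled (training) samples.
#' @param ann annotation data.frame (`sample_id`, `cell_type`).
#' @param marker_cpgs character vector of marker CpG ids (rows).
#' @param cell_types character vector of cell-type labels (columns);
#'   defaults to the sorted labels present in `ann`.
#' @return a `ReferenceMatrix`: numeric matrix markers x cell types with
#'   attributes `n_samples` (per-type training sample counts) and
#'   `condition` (2-norm condition number).
#' @export
build_reference <- function(m, ann, marker_cpgs, cell_types = NULL) {
  missing_cpg <- setdiff(marker_cpgs, rownames(m))
  if (length(missing_cpg))
    stop("marker CpG(s) absent from matrix: ", paste(missing_cpg, collapse = ", "))
  if (is.null(cell_types)) cell_types <- sort(unique(ann$cell_type))
  ref <- matrix(NA_real_, length(marker_cpgs), length(cell_types),
                dimnames = list(marker_cpgs, cell_types))
  n_samples <- stats::setNames(integer(length(cell_types)), cell_types)
  for (ct in cell_types) {
    ids <- ann$sample_id[ann$cell_type == ct]
    ids <- ids[ids %in% colnames(m)]
    if (!length(ids)) stop("cell type without samples: ", ct)
    n_samples[ct] <- length(ids)
    ref[, ct] <- rowMeans(m[marker_cpgs, ids, drop = FALSE])
  }
  if (anyNA(ref))
    stop("reference contains missing entries; filter probes with missing data first")
  cond <- kappa(ref, exact = TRUE)
  if (!is.finite(cond) || cond > 1e6)
    warning(sprintf(
      "reference matrix is ill-conditioned (condition number %.3g); cell-type profiles may be near-collinear", cond))
  structure(ref, n_samples = n_samples, condition = cond,
            class = c("ReferenceMatrix", "matrix", "array"))
}

#' @export
print.ReferenceMatrix <- function(x, ...) {
  cat(sprintf("ReferenceMatrix: %d marker CpGs x %d cell types (condition %.3g)\n",
              nrow(x), ncol(x), attr(x, "condition")))
  print(unclass(x)[, , drop = FALSE], ...)
  invisible(x)
}

#' Non-negative least squares fit of one sample
#'
#' Solves `min ||R w - b||_2` subject to `w >= 0` with the Lawson-Hanson
#' active-set algorithm.
#'
#' @param R numeric matrix, marker CpGs x cell types.
#' @param b numeric vector of the sample's beta values at the marker CpGs.
#' @return list with `weights` (raw non-negative coefficients, named by
#'   cell type) and `residual` (Euclidean norm of `R w - b`).
#' @export
nnls_solve <- function(R, b) {
  if (!is.matrix(R) || length(b) != nrow(R))
    stop(sprintf("dimension mismatch: R is %dx%d but b has length %d",
                 NROW(R), NCOL(R), length(b)))
  if (anyNA(R) || anyNA(b)) stop("R and b must not contain missing values")
  fit <- pracma::lsqnonneg(unclass(R), as.numeric(b))
  w <- stats::setNames(fit$x, colnames(R))
  list(weights = w, residual = sqrt(max(fit$resid.norm, 0)))
}

#' Reference-based deconvolution of cell-type proportions
#'
#' For every sample, its beta values at the reference marker CpGs are fit
#' against the reference columns by non-negative least squares and the
#' weights are normalized to proportions (`w / sum(w)`). Samples lacking a
#' marker CpG are, under `missing_policy = "exclude"`, flagged excluded
#' rather than estimated from a partial signature; `"drop_rows"` instead
#' removes the missing markers from both sides (with a warning), refusing
#' samples that would retain fewer markers than there are cell types.
#' All-zero weight vectors are flagged degenerate, with `NA` proportions,
#' rather than coerced to a fabricated composition.
#'
#' @param m beta matrix of the samples to decompose.
#' @param R a [build_reference()] matrix (markers x cell types).
#' @param missing_policy `"exclude"` (default) or `"drop_rows"`.
#' @return a `DeconvolutionResult` data.frame: `sample_id`, one proportion
#'   column per cell type, `residual`, `excluded`, `reason`. Raw NNLS
#'   weights are kept in the `"raw_weights"` attribute (samples x types).
#' @export
deconvolve <- function(m, R, missing_policy = c("exclude", "drop_rows")) {
  missing_policy <- match.arg(missing_policy)
  markers <- rownames(R)
  types <- colnames(R)
  samples <- colnames(m)
  props <- matrix(NA_real_, length(samples), length(types),
                  dimnames = list(samples, types))
  raw <- props
  residual <- rep(NA_real_, length(samples))
  excluded <- logical(length(samples))
  reason <- rep(NA_character_, length(samples))

  present_rows <- markers[markers %in% rownames(m)]
  for (i in seq_along(samples)) {
    b <- stats::setNames(rep(NA_real_, length(markers)), markers)
    b[present_rows] <- m[present_rows, samples[i]]
    miss <- markers[is.na(b)]
    use <- markers
    if (length(miss)) {
      if (missing_policy == "exclude") {
        excluded[i] <- TRUE
        reason[i] <- paste0("missing marker CpG(s): ", paste(miss, collapse = ", "))
        next
      }
      use <- setdiff(markers, miss)
      if (length(use) < length(types)) {
        excluded[i] <- TRUE
        reason[i] <- sprintf(
          "only %d of %d markers available (< %d cell types)",
          length(use), length(markers), length(types))
        next
      }
      warning(sprintf("sample '%s': dropping missing marker row(s) %s",
                      samples[i], paste(miss, collapse = ", ")))
    }
    fit <- nnls_solve(R[use, , drop = FALSE], b[use])
    raw[i, ] <- fit$weights
    residual[i] <- fit$residual
    s <- sum(fit$weights)
    if (s == 0) {
      reason[i] <- "degenerate all-zero NNLS solution"
    } else {
      props[i, ] <- fit$weights / s
    }
  }
  if (all(excluded)) stop("all samples excluded: ",
                          paste(unique(reason[excluded]), collapse = "; "))
  out <- data.frame(sample_id = samples, props, residual = residual,
                    excluded = excluded, reason = reason,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "raw_weights") <- raw
  class(out) <- c("DeconvolutionResult", "data.frame")
  out
}

#' Compare estimated against true mixture proportions
#'
#' @param truth numeric matrix or data.frame of true proportions,
#'   samples x cell types (row names or a `sample_id` column identify
#'   samples).
#' @param est a [deconvolve()] result.
#' @return list with `mae_per_type` (named), `mae` (overall mean absolute
#'   error), `rmse`, and `pearson_r` of mixed versus estimated fractions
#'   over all sample/type pairs (`NA` when either side is constant), plus
#'   `n_samples` actually compared (excluded samples are skipped).
#' @export
evaluate_mixtures <- function(truth, est) {
  if (is.data.frame(truth)) {
    if ("sample_id" %in% names(truth)) {
      rn <- truth$sample_id
      truth <- as.matrix(truth[setdiff(names(truth), "sample_id")])
      rownames(truth) <- rn
    } else truth <- as.matrix(truth)
  }
  types <- colnames(truth)
  est_types <- setdiff(names(est), c("sample_id", "residual", "excluded", "reason"))
  if (!setequal(types, est_types))
    stop("cell-type sets differ between truth and estimate: ",
         paste(symdiff <- union(setdiff(types, est_types),
                                setdiff(est_types, types)), collapse = ", "))
  keep <- !est$excluded & est$sample_id %in% rownames(truth)
  if (!any(keep)) stop("no non-excluded samples shared with truth")
  E <- as.matrix(est[keep, types, drop = FALSE])
  Tm <- truth[est$sample_id[keep], types, drop = FALSE]
  err <- E - Tm
  mae_per_type <- colMeans(abs(err))
  r <- if (stats::sd(as.numeric(Tm)) == 0 || stats::sd(as.numeric(E)) == 0)
    NA_real_ else stats::cor(as.numeric(Tm), as.numeric(E))
  list(mae_per_type = mae_per_type,
       mae = mean(abs(err)),
       rmse = sqrt(mean(err^2)),
       pearson_r = r,
       n_samples = sum(keep))
}

#' Read / write a reference matrix as TSV
#'
#' Same layout as a beta matrix: first column the marker CpG id, header the
#' cell-type names, full precision values.
#'
#' @param path file path.
#' @return for `read_reference_matrix`, a `ReferenceMatrix`.
#' @export
read_reference_matrix <- function(path) {
  m <- load_beta_matrix(path, scale = "unit")
  if (anyNA(m)) stop("reference matrix must not contain missing entries")
  structure(unclass(m), scale_note = NULL,
            n_samples = NULL, condition = kappa(unclass(m), exact = TRUE),
            class = c("ReferenceMatrix", "matrix", "array"))
}

#' @rdname read_reference_matrix
#' @param R reference matrix.
#' @export
write_reference_matrix <- function(R, path) {
  write_beta_matrix(R, path, key_name = "cpg_id")
}
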