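# internal helpers shared across modules

# delimiter from file extension: .csv -> comma, everything else tab
.guess_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

# row-wise unbiased sample variance of a numeric matrix (n - 1 denominator)
.row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) stop("variance requires at least 2 samples per group")
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}

# full-precision numeric formatting for TSV output (15 significant digits
# keeps read/write round trips below 1e-12 per value)
.fmt_num <- function(x) {
  out <- sprintf("%.15g", x)
  out[is.na(x)] <- "NA"
  out
}

.assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name,
                 format(min), format(max)), call. = FALSE)
  invisible(x)
}
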