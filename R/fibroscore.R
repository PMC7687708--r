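#' Two-CpG FibroScore
#'
#' The FibroScore is the difference in methylation between a CpG
#' hypermethylated in fibroblasts/MSCs and one hypomethylated there:
#' `beta(hyper_cpg) - beta(hypo_cpg)`, in \[-1, 1\]. Higher values indicate
#' a larger fibroblast/MSC fraction. Defaults are cg18096962
#' (hypermethylated, lncRNA RP11-60A8.1) and cg18005280 (hypomethylated,
#' LRIG1), chosen by cross-validated F1 ranking on reference cell-type
#' profiles.
#'
#' @param m beta matrix.
#' @param hyper_cpg id of the fibroblast-hypermethylated CpG.
#' @param hypo_cpg id of the fibroblast-hypomethylated CpG.
#' @return data.frame `sample_id`, `score`, `missing`. Samples lacking
#'   either CpG (row absent or value `NA`) are flagged missing, never
#'   silently dropped. An error is raised only when neither CpG exists in
#'   the matrix.
#' @export
fibro_score <- function(m, hyper_cpg = "cg18096962", hypo_cpg = "cg18005280") {
  if (hyper_cpg == hypo_cpg) stop("hyper_cpg and hypo_cpg must differ")
  have_hyper <- hyper_cpg %in% rownames(m)
  have_hypo <- hypo_cpg %in% rownames(m)
  if (!have_hyper && !have_hypo)
    stop(sprintf("neither '%s' nor '%s' present in the matrix",
                 hyper_cpg, hypo_cpg))
  b_hyper <- if (have_hyper) m[hyper_cpg, ] else rep(NA_real_, ncol(m))
  b_hypo <- if (have_hypo) m[hypo_cpg, ] else rep(NA_real_, ncol(m))
  score <- unname(b_hyper - b_hypo)
  data.frame(sample_id = colnames(m), score = score,
             missing = is.na(score), stringsAsFactors = FALSE)
}

#' Classify samples by FibroScore threshold
#'
#' `score >= threshold` is called `"fibroblast"`, below `"other"`; the
#' boundary tie goes to fibroblast. Missing scores stay `NA`. The default
#' cutoff 0 is the natural symmetric choice for a difference score (the
#' hypermethylated marker exceeds the hypomethylated one); see
#' [best_threshold()] for a training-set-derived alternative.
#'
#' @param result data.frame from [fibro_score()] (or a numeric score
#'   vector).
#' @param threshold classification cutoff (default 0).
#' @return character vector of labels `"fibroblast"`/`"other"`/`NA`.
#' @export
classify_fibro <- function(result, threshold = 0) {
  score <- if (is.data.frame(result)) result$score else result
  ifelse(is.na(score), NA_character_,
         ifelse(score >= threshold, "fibroblast", "other"))
}

#' Accuracy-maximizing threshold on a labelled set
#'
#' Sweeps every midpoint between consecutive distinct scores (plus the
#' extremes) and returns the cutoff maximizing classification accuracy.
#'
#' @param scores numeric FibroScore values.
#' @param truth character labels, `"fibroblast"` or `"other"`.
#' @return list with `threshold` and `accuracy`.
#' @export
best_threshold <- function(scores, truth) {
  ok <- !is.na(scores)
  s <- scores[ok]; y <- truth[ok] == "fibroblast"
  u <- sort(unique(s))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  acc <- vapply(cand, function(t) mean((s >= t) == y), numeric(1))
  best <- which.max(acc)
  list(threshold = cand[best], accuracy = acc[best])
}

#' Classification accuracy
#'
#' Proportion of exact label matches. Missing predictions count as errors;
#' missing truth is not allowed.
#'
#' @param predicted character vector of predicted labels.
#' @param truth character vector of true labels, same length.
#' @return fraction in \[0, 1\].
#' @export
accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  if (anyNA(truth)) stop("truth labels must not be missing")
  mean(!is.na(predicted) & predicted == truth)
}

#' Compare score distributions between two groups
#'
#' Welch two-sample t-test (unequal variances), two-sided, as used to
#' contrast FibroScore distributions between e.g. fibrotic and healthy
#' tissue. When both groups are essentially constant the test degenerates:
#' p is 0 if the means differ, 1 if they coincide.
#'
#' @param scores_a,scores_b numeric vectors, each of length >= 2.
#' @param var_equal use the pooled-variance Student test instead of Welch?
#' @return list with `statistic` (t), `df` and `p.value`.
#' @export
compare_groups <- function(scores_a, scores_b, var_equal = FALSE) {
  if (length(scores_a) < 2L || length(scores_b) < 2L)
    stop("each group needs at least 2 observations")
  eps <- .Machine$double.eps
  va <- stats::var(scores_a); vb <- stats::var(scores_b)
  if (va <= eps && vb <= eps) {
    dm <- mean(scores_a) - mean(scores_b)
    if (abs(dm) <= eps)
      return(list(statistic = 0, df = NA_real_, p.value = 1))
    return(list(statistic = sign(dm) * Inf, df = NA_real_, p.value = 0))
  }
  tt <- stats::t.test(scores_a, scores_b, var.equal = var_equal,
                      alternative = "two.sided")
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value)
}
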