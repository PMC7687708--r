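#' Stratified k-fold assignment
#'
#' Partitions samples into `k` folds preserving cell-type composition:
#' within each label class, fold sizes differ by at most one, and classes
#' with fewer than `k` members are spread over distinct folds. The
#' assignment is deterministic given `seed`.
#'
#' @param labels named character vector, `sample_id -> cell_type`.
#' @param k number of folds (default 10).
#' @param seed integer RNG seed.
#' @return a `FoldPlan`: list with `k`, `seed` and `assignment`
#'   (named integer vector of fold indices in `1..k`).
#' @export
stratified_folds <- function(labels, k = 10L, seed = 1L) {
  if (is.null(names(labels)) || anyNA(labels))
    stop("'labels' must be a named vector without NA")
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  assignment <- integer(length(labels))
  names(assignment) <- names(labels)
  set.seed(seed)
  for (cls in sort(unique(labels))) {
    ids <- names(labels)[labels == cls]
    ids <- sample(ids)
    offset <- sample.int(k, 1L) - 1L
    folds <- ((seq_along(ids) - 1L + offset) %% k) + 1L
    assignment[ids] <- folds
  }
  structure(list(k = k, seed = as.integer(seed), assignment = assignment),
            class = "FoldPlan")
}

#' Per-CpG group statistics
#'
#' For each CpG computes `dMean`, the difference of group mean beta values
#' between the target cell type and all other samples (target minus rest),
#' and `sVar`, the sum of the unbiased within-group variances. CpGs with
#' `dMean > 0` are hypermethylated in the target, `dMean < 0`
#' hypomethylated.
#'
#' @param m beta matrix.
#' @param ann annotation data.frame (`sample_id`, `cell_type`).
#' @param target target cell-type label.
#' @param sample_subset optional character vector restricting the samples
#'   used (e.g. one cross-validation fold).
#' @return data.frame with columns `cpg_id`, `dMean`, `sVar`, `direction`.
#' @export
cpg_stats <- function(m, ann, target, sample_subset = NULL) {
  ids <- if (is.null(sample_subset)) ann$sample_id else sample_subset
  ids <- ids[ids %in% colnames(m)]
  lab <- ann$cell_type[match(ids, ann$sample_id)]
  in_target <- lab == target
  if (sum(in_target) < 2L || sum(!in_target) < 2L)
    stop(sprintf(
      "need >= 2 samples per group, got %d target and %d other",
      sum(in_target), sum(!in_target)))
  mt <- m[, ids[in_target], drop = FALSE]
  mo <- m[, ids[!in_target], drop = FALSE]
  dmean <- rowMeans(mt) - rowMeans(mo)
  svar <- .row_vars(mt) + .row_vars(mo)
  data.frame(cpg_id = rownames(m), dMean = unname(dmean), sVar = unname(svar),
             direction = ifelse(dmean > 0, "hyper",
                                ifelse(dmean < 0, "hypo", "none")),
             stringsAsFactors = FALSE)
}

#' Parabola gate parameters
#'
#' The gate selects CpGs lying under the parabola `sVar < (a * dMean)^2` in
#' the dMean/sVar plane: large group separation, small within-group
#' variance. `a` starts at `a_init` and is widened by `a_step` until at
#' least `min_hyper` hypermethylated and `min_hypo` hypomethylated CpGs
#' pass, capped at `a_max`.
#'
#' @param a_init initial coefficient (default 0.1).
#' @param a_step increment (default 0.1).
#' @param min_hyper minimum selected CpGs with `dMean > 0` (default 10).
#' @param min_hypo minimum selected CpGs with `dMean < 0` (default 10).
#' @param a_max cap on the coefficient (default 10).
#' @return a `ParabolaGate` list.
#' @export
parabola_gate <- function(a_init = 0.1, a_step = 0.1,
                          min_hyper = 10L, min_hypo = 10L, a_max = 10) {
  .assert_scalar_number(a_init, "a_init", min = 0)
  .assert_scalar_number(a_step, "a_step", min = 1e-12)
  .assert_scalar_number(a_max, "a_max", min = a_init)
  structure(list(a_init = a_init, a_step = a_step,
                 min_hyper = as.integer(min_hyper),
                 min_hypo = as.integer(min_hypo), a_max = a_max),
            class = "ParabolaGate")
}

#' Adaptive parabola selection of candidate CpGs
#'
#' Applies the gate `sVar < (a * dMean)^2`, escalating `a` from
#' `gate$a_init` in steps of `gate$a_step` until both the hyper- and
#' hypomethylated minima are met. If the cap `a_max` is reached first, the
#' CpGs passing at the cap are returned with a warning.
#'
#' @param stats data.frame from [cpg_stats()].
#' @param gate a [parabola_gate()].
#' @return list with `hyper` and `hypo` (selected CpG ids) and `a_final`.
#' @export
parabola_select <- function(stats, gate = parabola_gate()) {
  if (!nrow(stats)) stop("'stats' is empty")
  stopifnot(inherits(gate, "ParabolaGate"))
  n_steps <- max(0L, ceiling((gate$a_max - gate$a_init) / gate$a_step))
  for (i in 0:n_steps) {
    a <- gate$a_init + i * gate$a_step
    if (a > gate$a_max) a <- gate$a_max
    pass <- stats$sVar < (a * stats$dMean)^2
    hyper <- stats$cpg_id[pass & stats$dMean > 0]
    hypo <- stats$cpg_id[pass & stats$dMean < 0]
    if (length(hyper) >= gate$min_hyper && length(hypo) >= gate$min_hypo)
      return(list(hyper = hyper, hypo = hypo, a_final = a))
  }
  warning(sprintf(
    "parabola cap a_max = %g reached with %d hyper / %d hypo selected (wanted %d / %d)",
    gate$a_max, length(hyper), length(hypo), gate$min_hyper, gate$min_hypo))
  list(hyper = hyper, hypo = hypo, a_final = gate$a_max)
}

#' Area under the precision-recall curve (average precision)
#'
#' Average-precision formulation: samples are ranked by decreasing score,
#' tied scores share a threshold, and the area is the sum over thresholds of
#' precision times the recall increment. Invariant under strictly monotone
#' transforms of the scores.
#'
#' @param scores numeric vector; higher means more target-like.
#' @param labels logical (or 0/1) vector of target membership.
#' @return AUPR in \[0, 1\].
#' @export
aupr <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  npos <- sum(labels)
  if (npos == 0L || npos == length(labels))
    stop("both classes must be present to compute AUPR")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # threshold groups: runs of tied scores
  ends <- cumsum(rle(s)$lengths)
  tp <- cumsum(as.integer(y))[ends]
  precision <- tp / ends
  d_recall <- diff(c(0L, tp)) / npos
  sum(precision * d_recall)
}

#' Best F1 score over all thresholds
#'
#' The single-CpG classifier "score >= threshold implies target" is swept
#' over all distinct score values; the maximum F1 is returned. The variant
#' used when ranking candidates for the two-CpG fibroblast score.
#'
#' @inheritParams aupr
#' @return maximum F1 in \[0, 1\].
#' @export
f1_best <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  npos <- sum(labels)
  if (npos == 0L || npos == length(labels))
    stop("both classes must be present to compute F1")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  keep <- !duplicated(s, fromLast = TRUE)  # last index of each tie group
  tp <- cumsum(as.integer(y))[keep]
  npred <- seq_along(y)[keep]
  f1 <- 2 * tp / (npred + npos)  # 2TP / (2TP + FP + FN)
  max(f1)
}

#' Cross-validated marker ranking
#'
#' For each fold of `plan`: group statistics and the parabola gate are
#' computed on that fold's samples, and every gated CpG is scored on all
#' remaining samples with the chosen metric (AUPR or best F1), orienting
#' scores by direction (hypomethylated markers use `1 - beta`, so that
#' higher always means more target-like). The per-fold metric is optionally
#' scaled by `|dMean|`; the final score is the mean scaled metric over the
#' folds where the CpG passed the gate, multiplied by the fraction of folds
#' where it was selected. Hyper- and hypomethylated candidates are ranked
#' separately; ties break by larger `|mean dMean|`, then CpG id.
#'
#' @param m beta matrix.
#' @param ann annotation data.frame.
#' @param target target cell-type label.
#' @param plan a [stratified_folds()] plan covering the samples to use.
#' @param gate a [parabola_gate()].
#' @param metric `"aupr"` or `"f1"`.
#' @param scale_by_dmean multiply the per-fold metric by `|dMean|`?
#' @return a `MarkerRanking` data.frame: `cpg_id`, `direction`,
#'   `selection_frequency`, `mean_metric`, `mean_dMean`, `final_score`,
#'   `rank` (per direction; unselected CpGs rank after all selected ones).
#' @export
rank_markers <- function(m, ann, target, plan, gate = parabola_gate(),
                         metric = c("aupr", "f1"), scale_by_dmean = TRUE) {
  metric <- match.arg(metric)
  stopifnot(inherits(plan, "FoldPlan"))
  metric_fun <- if (metric == "aupr") aupr else f1_best
  all_ids <- names(plan$assignment)
  all_ids <- all_ids[all_ids %in% colnames(m)]
  if (!length(all_ids)) stop("fold plan covers no samples of the matrix")
  lab_all <- ann$cell_type[match(all_ids, ann$sample_id)]

  cpgs <- rownames(m)
  n_sel <- integer(length(cpgs)); names(n_sel) <- cpgs
  sum_metric <- numeric(length(cpgs)); names(sum_metric) <- cpgs
  sum_dmean <- numeric(length(cpgs)); names(sum_dmean) <- cpgs

  for (f in seq_len(plan$k)) {
    fold_ids <- all_ids[plan$assignment[all_ids] == f]
    if (!length(fold_ids)) next
    st <- tryCatch(cpg_stats(m, ann, target, fold_ids), error = function(e)
      stop("fold ", f, ": ", conditionMessage(e),
           "; use fewer folds or more samples per cell type", call. = FALSE))
    sum_dmean <- sum_dmean + st$dMean
    sel <- parabola_select(st, gate)
    eval_ids <- setdiff(all_ids, fold_ids)
    eval_lab <- lab_all[match(eval_ids, all_ids)] == target
    if (!any(eval_lab) || all(eval_lab))
      stop("fold ", f, ": evaluation samples contain a single class")
    dmean_f <- stats::setNames(st$dMean, st$cpg_id)
    for (side in c("hyper", "hypo")) {
      for (cg in sel[[side]]) {
        b <- m[cg, eval_ids]
        sc <- if (side == "hypo") 1 - b else b
        val <- metric_fun(sc, eval_lab)
        if (scale_by_dmean) val <- val * abs(dmean_f[[cg]])
        n_sel[cg] <- n_sel[cg] + 1L
        sum_metric[cg] <- sum_metric[cg] + val
      }
    }
  }

  mean_dmean <- sum_dmean / plan$k
  freq <- n_sel / plan$k
  mean_metric <- ifelse(n_sel > 0L, sum_metric / pmax(n_sel, 1L), 0)
  final <- mean_metric * freq
  out <- data.frame(
    cpg_id = cpgs,
    direction = ifelse(mean_dmean > 0, "hyper",
                       ifelse(mean_dmean < 0, "hypo", "none")),
    selection_frequency = unname(freq),
    mean_metric = unname(mean_metric),
    mean_dMean = unname(mean_dmean),
    final_score = unname(final),
    stringsAsFactors = FALSE)
  # rank within direction: score desc, then |mean dMean| desc, then cpg_id
  out <- out[order(out$direction, -out$final_score, -abs(out$mean_dMean),
                   out$cpg_id), , drop = FALSE]
  out$rank <- stats::ave(seq_len(nrow(out)), out$direction,
                         FUN = seq_along)
  rownames(out) <- NULL
  class(out) <- c("MarkerRanking", "data.frame")
  out
}

#' Top-ranked marker for a direction
#'
#' @param ranking a `MarkerRanking`.
#' @param direction `"hypo"` or `"hyper"`.
#' @param n number of top CpGs to return.
#' @return character vector of CpG ids, best first.
#' @export
top_markers <- function(ranking, direction = c("hypo", "hyper"), n = 1L) {
  direction <- match.arg(direction)
  sub <- ranking[ranking$direction == direction, , drop = FALSE]
  sub <- sub[order(sub$rank), , drop = FALSE]
  utils::head(sub$cpg_id, n)
}
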