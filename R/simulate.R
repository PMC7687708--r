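#' Simulation configuration
#'
#' Parameters of the synthetic beta-value generator. Pure cell-type
#' profiles follow the hypomethylated-marker geometry of targeted
#' methylation signatures: each cell type is hypomethylated at its own
#' marker CpGs (mean `marker_low_mean`) and hypermethylated at the other
#' types' markers (mean `marker_high_mean`); background CpGs share one
#' per-CpG mean across all cell types, drawn uniformly from \[0.2, 0.8\].
#' Biological variation is modelled by a Beta distribution reparameterized
#' by (mean, SD), which keeps values in \[0, 1\]; mixture measurement error
#' is additive Gaussian, truncated to \[0, 1\].
#'
#' @param n_cell_types number of cell types (default 5).
#' @param samples_per_type pure samples per type (default 10).
#' @param n_marker_cpgs_per_type planted markers per type (default 10).
#' @param n_background_cpgs non-informative CpGs (default 400).
#' @param marker_low_mean beta mean at a type's own marker (default 0.10).
#' @param marker_high_mean beta mean at other types' markers (default 0.85).
#' @param within_type_sd biological SD of beta within a type (default 0.05).
#' @param measurement_sd additive noise SD on mixtures (default 0.02).
#' @param dirichlet_alpha Dirichlet concentration for mixture proportions
#'   (default 1, i.e. uniform on the simplex).
#' @param seed integer RNG seed.
#' @return a validated `SimulationConfig` list.
#' @export
sim_config <- function(n_cell_types = 5L, samples_per_type = 10L,
                       n_marker_cpgs_per_type = 10L, n_background_cpgs = 400L,
                       marker_low_mean = 0.10, marker_high_mean = 0.85,
                       within_type_sd = 0.05, measurement_sd = 0.02,
                       dirichlet_alpha = 1, seed = 1L) {
  cfg <- list(n_cell_types = as.integer(n_cell_types),
              samples_per_type = as.integer(samples_per_type),
              n_marker_cpgs_per_type = as.integer(n_marker_cpgs_per_type),
              n_background_cpgs = as.integer(n_background_cpgs),
              marker_low_mean = marker_low_mean,
              marker_high_mean = marker_high_mean,
              within_type_sd = within_type_sd,
              measurement_sd = measurement_sd,
              dirichlet_alpha = dirichlet_alpha,
              seed = as.integer(seed))
  for (nm in c("n_cell_types", "samples_per_type", "n_marker_cpgs_per_type"))
    if (cfg[[nm]] < 1L) stop("'", nm, "' must be >= 1")
  if (cfg$n_background_cpgs < 0L) stop("'n_background_cpgs' must be >= 0")
  .assert_scalar_number(cfg$marker_low_mean, "marker_low_mean", 0, 1)
  .assert_scalar_number(cfg$marker_high_mean, "marker_high_mean", 0, 1)
  .assert_scalar_number(cfg$within_type_sd, "within_type_sd", 0)
  .assert_scalar_number(cfg$measurement_sd, "measurement_sd", 0)
  .assert_scalar_number(cfg$dirichlet_alpha, "dirichlet_alpha", 1e-12)
  structure(cfg, class = "SimulationConfig")
}

# canonical cell-type names used by the simulator (targeted deconvolution
# panels typically cover these lineages)
.sim_type_names <- function(n) {
  base <- c("fibroblast", "leukocyte", "epithelial", "hepatocyte",
            "endothelial", "glia", "neuron", "iPSC")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("celltype%02d", seq_len(n - length(base))))
}

# Beta draws parameterized by (mean, sd); sd = 0 degenerates to a constant.
# Feasibility requires sd^2 < mean * (1 - mean).
.rbeta_meansd <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  if (mean <= 0 || mean >= 1)
    stop("Beta mean must lie strictly in (0, 1) when sd > 0")
  if (sd^2 >= mean * (1 - mean))
    stop(sprintf(
      "infeasible Beta parameterization: need sd^2 < mean*(1-mean), got sd^2 = %.4g >= %.4g",
      sd^2, mean * (1 - mean)))
  nu <- mean * (1 - mean) / sd^2 - 1
  stats::rbeta(n, mean * nu, (1 - mean) * nu)
}

#' Simulate pure cell-type beta profiles
#'
#' Generates `n_cell_types * samples_per_type` pure samples over planted
#' marker CpGs and background CpGs (see [sim_config()]). Deterministic
#' given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `matrix` (beta matrix), `annotation` (sample_id,
#'   cell_type), and `truth` (data.frame `cpg_id`, `role` in
#'   \{`marker`, `background`\}, `marker_of` cell type or `NA`).
#' @export
simulate_pure_profiles <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  types <- .sim_type_names(cfg$n_cell_types)
  n_marker <- cfg$n_cell_types * cfg$n_marker_cpgs_per_type
  marker_ids <- sprintf("cgM%06d", seq_len(n_marker))
  marker_of <- rep(types, each = cfg$n_marker_cpgs_per_type)
  bg_ids <- if (cfg$n_background_cpgs)
    sprintf("cgB%06d", seq_len(cfg$n_background_cpgs)) else character(0)
  sample_ids <- as.vector(vapply(types, function(t)
    sprintf("%s_s%02d", t, seq_len(cfg$samples_per_type)),
    character(cfg$samples_per_type)))
  sample_type <- rep(types, each = cfg$samples_per_type)

  n_s <- length(sample_ids)
  vals <- matrix(NA_real_, n_marker + length(bg_ids), n_s,
                 dimnames = list(c(marker_ids, bg_ids), sample_ids))
  for (i in seq_len(n_marker)) {
    own <- sample_type == marker_of[i]
    vals[i, own] <- .rbeta_meansd(sum(own), cfg$marker_low_mean,
                                  cfg$within_type_sd)
    vals[i, !own] <- .rbeta_meansd(sum(!own), cfg$marker_high_mean,
                                   cfg$within_type_sd)
  }
  if (length(bg_ids)) {
    bg_means <- stats::runif(length(bg_ids), 0.2, 0.8)
    for (j in seq_along(bg_ids)) {
      vals[n_marker + j, ] <- .rbeta_meansd(n_s, bg_means[j],
                                            cfg$within_type_sd)
    }
  }
  truth <- data.frame(
    cpg_id = c(marker_ids, bg_ids),
    role = c(rep("marker", n_marker), rep("background", length(bg_ids))),
    marker_of = c(marker_of, rep(NA_character_, length(bg_ids))),
    stringsAsFactors = FALSE)
  list(matrix = beta_matrix(vals),
       annotation = data.frame(sample_id = sample_ids,
                               cell_type = sample_type,
                               stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate in-silico DNA mixtures
#'
#' Each mixture's beta value at marker CpG i is the convex combination of
#' the pure per-type means, `sum_t w_t * mean_t(i)`, plus additive Gaussian
#' measurement noise truncated (clipped) to \[0, 1\]. Proportions `w` are
#' either drawn from a symmetric Dirichlet or supplied explicitly — e.g. an
#' incremental two-type gradient such as neuron fractions 0, 0.1, ..., 1.
#'
#' @param pure_means numeric matrix, marker CpGs x cell types, of pure
#'   profile means (e.g. a [build_reference()] matrix).
#' @param n_mixtures number of mixture samples (ignored when `weights`
#'   is supplied).
#' @param cfg a [sim_config()]; uses `measurement_sd`, `dirichlet_alpha`
#'   and `seed`.
#' @param weights optional matrix of explicit proportions, mixtures x cell
#'   types; every row must sum to 1 within 1e-9.
#' @return list with `matrix` (beta matrix, markers x mixtures) and
#'   `truth` (data.frame `sample_id` + one proportion column per type).
#'   The number of noise values clipped at the \[0,1\] boundary is recorded
#'   in the matrix attribute `"n_clipped"`.
#' @export
simulate_mixtures <- function(pure_means, n_mixtures = 10L,
                              cfg = sim_config(), weights = NULL) {
  stopifnot(inherits(cfg, "SimulationConfig"), is.matrix(pure_means))
  types <- colnames(pure_means)
  if (is.null(types)) stop("'pure_means' needs cell-type column names")
  set.seed(cfg$seed + 1L)  # distinct stream from the pure-profile draw
  if (is.null(weights)) {
    g <- matrix(stats::rgamma(n_mixtures * length(types),
                              shape = cfg$dirichlet_alpha),
                n_mixtures, length(types))
    weights <- g / rowSums(g)
    colnames(weights) <- types
  } else {
    weights <- as.matrix(weights)
    if (ncol(weights) != length(types))
      stop("'weights' must have one column per cell type")
    if (is.null(colnames(weights))) colnames(weights) <- types
    bad <- abs(rowSums(weights) - 1) > 1e-9
    if (any(bad))
      stop("weights row(s) not summing to 1: ",
           paste(which(bad), collapse = ", "))
    n_mixtures <- nrow(weights)
  }
  sample_ids <- sprintf("mix%03d", seq_len(n_mixtures))
  rownames(weights) <- sample_ids
  clean <- unclass(pure_means) %*% t(weights[, types, drop = FALSE])
  noise <- if (cfg$measurement_sd > 0)
    matrix(stats::rnorm(length(clean), 0, cfg$measurement_sd),
           nrow(clean), ncol(clean)) else 0
  vals <- clean + noise
  n_clipped <- sum(vals < 0 | vals > 1)
  vals <- pmin(pmax(vals, 0), 1)
  dimnames(vals) <- list(rownames(pure_means), sample_ids)
  m <- beta_matrix(vals)
  attr(m, "n_clipped") <- n_clipped
  truth <- data.frame(sample_id = sample_ids, weights,
                      check.names = FALSE, stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(matrix = m, truth = truth)
}

#' Simulate a marker-selection benchmark
#'
#' Pure profiles in which the planted markers are the only true signal:
#' background CpGs are identically distributed across cell types (their
#' expected dMean is 0 for every target), so a selection procedure should
#' recover exactly the planted set.
#'
#' @inheritParams simulate_pure_profiles
#' @return as [simulate_pure_profiles()].
#' @export
simulate_selection_benchmark <- function(cfg = sim_config()) {
  # the pure-profile generator already draws background CpGs from one
  # shared per-CpG distribution for all cell types
  simulate_pure_profiles(cfg)
}
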