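test_that("stratified folds balance every class and are deterministic", {
  labels <- setNames(rep(c("a", "b"), each = 10), paste0("s", 1:20))
  plan <- stratified_folds(labels, k = 10, seed = 4)
  # perfect stratification: one sample of each class per fold
  tab <- table(labels, plan$assignment)
  expect_true(all(tab == 1))
  expect_identical(plan$assignment,
                   stratified_folds(labels, k = 10, seed = 4)$assignment)
  expect_false(identical(plan$assignment,
                         stratified_folds(labels, k = 10, seed = 5)$assignment))
  expect_error(stratified_folds(labels, k = 1), "at least 2")
})

test_that("per-class fold counts differ by at most one for random labels", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(6:40, 1)
    k <- sample(2:8, 1)
    labels <- setNames(sample(letters[1:3], n, replace = TRUE),
                       paste0("s", seq_len(n)))
    plan <- stratified_folds(labels, k = k, seed = rep)
    for (cls in unique(labels)) {
      counts <- tabulate(plan$assignment[labels == cls], nbins = k)
      expect_lte(diff(range(counts)), 1)
      # classes smaller than k land in distinct folds
      if (sum(labels == cls) <= k)
        expect_true(all(counts <= 1))
    }
  }
})

test_that("cpg_stats reproduces group mean/variance formulas", {
  fx <- make_two_marker_fixture()
  st <- cpg_stats(fx$matrix, fx$annotation, "fibroblast")
  expect_equal(st$dMean[st$cpg_id == "mk_hypo"], -0.9)
  expect_equal(st$sVar[st$cpg_id == "mk_hypo"], 0)
  expect_equal(st$dMean[st$cpg_id == "flat1"], 0)
  expect_equal(st$direction[st$cpg_id == "mk_hyper"], "hyper")

  # random 6-sample input against direct formulas
  set.seed(8)
  m <- make_beta_fixture(n_cpg = 12, n_sample = 6, seed = 8)
  ann <- data.frame(sample_id = colnames(m),
                    cell_type = c("t", "t", "t", "o", "o", "o"),
                    stringsAsFactors = FALSE)
  st <- cpg_stats(m, ann, "t")
  for (i in c(1, 5, 12)) {
    a <- m[i, 1:3]; b <- m[i, 4:6]
    expect_equal(st$dMean[i], mean(a) - mean(b))
    expect_equal(st$sVar[i], var(a) + var(b))
  }

  expect_error(cpg_stats(m, ann, "t", sample_subset = colnames(m)[c(1, 4, 5)]),
               ">= 2 samples per group")
})

test_that("parabola gate selects below y = (ax)^2 and escalates as needed", {
  # zero-variance CpG passes at the initial coefficient
  st <- data.frame(cpg_id = c("z", "v"), dMean = c(-0.5, -0.5),
                   sVar = c(0, 0.1), direction = "hypo",
                   stringsAsFactors = FALSE)
  sel <- parabola_select(st, parabola_gate(min_hyper = 0, min_hypo = 1))
  expect_identical(sel$hypo, "z")
  expect_equal(sel$a_final, 0.1)

  # table meeting both minima immediately does not escalate
  st2 <- data.frame(cpg_id = sprintf("c%02d", 1:20),
                    dMean = rep(c(0.8, -0.8), 10),
                    sVar = 0.001, stringsAsFactors = FALSE)
  sel2 <- parabola_select(st2, parabola_gate())
  expect_equal(sel2$a_final, 0.1)
  expect_equal(length(sel2$hyper), 10)

  # unreachable minimum stops at the cap with a warning
  st3 <- data.frame(cpg_id = "only", dMean = 0.5, sVar = 0.0,
                    stringsAsFactors = FALSE)
  expect_warning(sel3 <- parabola_select(st3, parabola_gate()), "a_max")
  expect_equal(sel3$a_final, 10)
})

test_that("aupr matches an exhaustive threshold oracle and its limits", {
  # perfect separation
  expect_equal(aupr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  # all-tied scores collapse to a single threshold: AUPR = prevalence
  expect_equal(aupr(rep(0.5, 10), c(rep(1, 3), rep(0, 7))), 0.3)
  expect_error(aupr(1:4, c(1, 1, 1, 1)), "both classes")

  set.seed(13)
  for (rep in 1:200) {
    n <- sample(4:12, 1)
    labels <- integer(n)
    while (sum(labels) %in% c(0, n)) labels <- rbinom(n, 1, 0.4)
    scores <- if (rep %% 2) runif(n) else sample(seq(0, 1, 0.25), n, TRUE)
    expect_equal(aupr(scores, labels),
                 oracle_average_precision(scores, labels), tolerance = 1e-12)
  }
})

test_that("f1_best matches an exhaustive threshold oracle and its limits", {
  expect_equal(f1_best(c(5, 4, 1, 0), c(1, 1, 0, 0)), 1.0)
  # the all-positive classifier bounds best F1 below by 2p/(p+1)
  set.seed(14)
  for (rep in 1:100) {
    n <- sample(4:12, 1)
    labels <- integer(n)
    while (sum(labels) %in% c(0, n)) labels <- rbinom(n, 1, 0.5)
    scores <- if (rep %% 2) runif(n) else sample(seq(0, 1, 1 / 3), n, TRUE)
    got <- f1_best(scores, labels)
    expect_equal(got, oracle_best_f1(scores, labels), tolerance = 1e-12)
    p <- mean(labels)
    expect_gte(got, 2 * p / (p + 1) - 1e-12)
  }
  expect_error(f1_best(1:3, c(0, 0, 0)), "both classes")
})

test_that("ranking metrics are invariant under monotone score transforms", {
  set.seed(15)
  for (rep in 1:20) {
    n <- 10
    labels <- integer(n)
    while (sum(labels) %in% c(0, n)) labels <- rbinom(n, 1, 0.5)
    scores <- runif(n)
    trans <- exp(3 * scores) - 1
    expect_equal(aupr(scores, labels), aupr(trans, labels))
    expect_equal(f1_best(scores, labels), f1_best(trans, labels))
  }
})

test_that("rank_markers reproduces the hand-computed two-fold fixture", {
  fx <- make_two_marker_fixture()
  labels <- setNames(fx$annotation$cell_type, fx$annotation$sample_id)
  plan <- stratified_folds(labels, k = 2, seed = 1)
  gate <- parabola_gate(min_hyper = 1, min_hypo = 1)
  rk <- rank_markers(fx$matrix, fx$annotation, "fibroblast", plan,
                     gate = gate, metric = "aupr")
  # both perfect markers: selected in every fold, AUPR 1, |dMean| = 0.9
  # => final score = 1 * 0.9 * (2/2) = 0.9
  expect_equal(rk$final_score[rk$cpg_id == "mk_hypo"], 0.9)
  expect_equal(rk$final_score[rk$cpg_id == "mk_hyper"], 0.9)
  expect_equal(rk$selection_frequency[rk$cpg_id == "mk_hypo"], 1)
  # never-selected CpGs score 0 and rank after the selected ones of
  # their direction
  expect_equal(rk$final_score[rk$cpg_id == "flat1"], 0)
  expect_equal(rk$final_score[rk$cpg_id == "weak_hypo"], 0)
  expect_identical(rk$direction[rk$cpg_id == "flat1"], "none")
  expect_identical(top_markers(rk, "hypo"), "mk_hypo")
  expect_identical(top_markers(rk, "hyper"), "mk_hyper")
  expect_gt(rk$rank[rk$cpg_id == "weak_hypo"],
            rk$rank[rk$cpg_id == "mk_hypo"])

  # unscaled F1 variant: perfect markers score 1
  rk2 <- rank_markers(fx$matrix, fx$annotation, "fibroblast", plan,
                      gate = gate, metric = "f1", scale_by_dmean = FALSE)
  expect_equal(rk2$final_score[rk2$cpg_id == "mk_hypo"], 1)
})

test_that("rank_markers is invariant to sample column order", {
  sim <- simulate_selection_benchmark(
    sim_config(n_cell_types = 3, samples_per_type = 6,
               n_marker_cpgs_per_type = 4, n_background_cpgs = 40, seed = 2))
  labels <- setNames(sim$annotation$cell_type, sim$annotation$sample_id)
  plan <- stratified_folds(labels, k = 3, seed = 9)
  gate <- parabola_gate(min_hyper = 2, min_hypo = 2)
  rk <- rank_markers(sim$matrix, sim$annotation, "fibroblast", plan, gate)

  perm <- sample(ncol(sim$matrix))
  m2 <- beta_matrix(unclass(sim$matrix)[, perm, drop = FALSE])
  rk2 <- rank_markers(m2, sim$annotation, "fibroblast", plan, gate)
  expect_equal(as.data.frame(rk), as.data.frame(rk2))

  # scores stay within [0, 1] when scaled by |dMean|
  expect_true(all(rk$final_score >= 0 & rk$final_score <= 1))
})

test_that("too-small folds give an instructive error", {
  fx <- make_two_marker_fixture()
  labels <- setNames(fx$annotation$cell_type, fx$annotation$sample_id)
  plan <- stratified_folds(labels, k = 4, seed = 1)  # 1 target sample/fold
  expect_error(
    rank_markers(fx$matrix, fx$annotation, "fibroblast", plan,
                 parabola_gate(min_hyper = 1, min_hypo = 1)),
    "fewer folds|more samples")
})
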