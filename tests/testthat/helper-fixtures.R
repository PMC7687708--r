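# in-code fixtures shared across test files

# small random beta matrix with optional missing values
make_beta_fixture <- function(n_cpg = 10, n_sample = 6, seed = 1,
                              na_frac = 0) {
  set.seed(seed)
  v <- matrix(runif(n_cpg * n_sample), n_cpg, n_sample,
              dimnames = list(sprintf("cg%07d", seq_len(n_cpg)),
                              sprintf("s%02d", seq_len(n_sample))))
  if (na_frac > 0)
    v[sample(length(v), ceiling(na_frac * length(v)))] <- NA_real_
  beta_matrix(v)
}

# two-class fixture with one perfect hypo and one perfect hyper marker:
# 4 target + 4 other samples, constant within group, plus flat background
make_two_marker_fixture <- function() {
  samples <- c(paste0("fib", 1:4), paste0("oth", 1:4))
  v <- rbind(
    mk_hypo   = c(rep(0.05, 4), rep(0.95, 4)),
    mk_hyper  = c(rep(0.95, 4), rep(0.05, 4)),
    flat1     = rep(0.5, 8),
    weak_hypo = c(0.30, 0.31, 0.32, 0.33, 0.34, 0.35, 0.36, 0.37))
  colnames(v) <- samples
  list(matrix = beta_matrix(v),
       annotation = data.frame(
         sample_id = samples,
         cell_type = rep(c("fibroblast", "other"), each = 4),
         stringsAsFactors = FALSE))
}
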