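# shared fixtures and generators for the test suite

# the two worked-example repertoires (frequencies over 100 reads)
example_f1 <- c(0.33, 0.29, 0.28, 0.05, 0.04, 0.01)
example_f2 <- c(0.42, 0.30, 0.10, 0.08, 0.05, 0.05)

extdata <- function(name) {
  system.file("extdata", name, package = "divprof", mustWork = TRUE)
}

# random clonal frequency distribution with n clones (Dirichlet-like via
# normalized exponentials of varying scale, so both flat and skewed shapes
# appear)
random_frequencies <- function(n, skew = stats::runif(1, 0.2, 3)) {
  w <- stats::rexp(n)^skew
  w / sum(w)
}

# small two-class cohort of simulated repertoires with disjoint clonal
# expansion regimes; returns the classifier feature matrix and labels
two_regime_features <- function(seed, n_per_class = 12, n_reads = 1e4) {
  low <- simulate_cohort(n_per_class, zipf_b_range = c(0.001, 0.01),
                         n_reads = n_reads, seed = seed)
  high <- simulate_cohort(n_per_class, zipf_b_range = c(0.05, 0.1),
                          n_reads = n_reads, seed = seed + 500)
  high$sample_id <- sub("rep_", "exp_", high$sample_id)
  x <- profile_matrix(repertoire_profiles(dplyr::bind_rows(low, high)),
                      "diversity")
  y <- factor(rep(c("low", "high"), each = n_per_class),
              levels = c("high", "low"))
  list(x = x, y = y)
}
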