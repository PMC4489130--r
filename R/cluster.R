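#' Distance matrix between profile or distribution vectors
#'
#' Computes the pairwise distance matrix used for hierarchical clustering.
#' Euclidean distance compares both shape and magnitude (appropriate for
#' Diversity profiles, where species-richness differences matter); the
#' Pearson correlation distance 1 - r is scale invariant and compares shapes
#' only (appropriate for Evenness profiles and for frequency distributions on
#' a common clone index).
#'
#' @param x A numeric matrix with one row per sample (e.g. from
#'   [profile_matrix()] or [cohort_matrix()]).
#' @param metric `"euclidean"` or `"correlation"` (1 - Pearson r, ranging from 0 to 2).
#' @return A [stats::dist] object with attribute `metric`.
#' @export
profile_distance <- function(x, metric = c("euclidean", "correlation")) {
  metric <- match.arg(metric)
  if (!is.matrix(x) || nrow(x) < 2) {
    abort("`x` must be a matrix with at least 2 rows.")
  }
  if (metric == "euclidean") {
    d <- dist(x)
  } else {
    if (ncol(x) < 2) abort("Correlation distance needs vectors of length >= 2.")
    sds <- apply(x, 1, sd)
    if (any(sds == 0)) {
      bad <- rownames(x)[sds == 0]
      if (is.null(bad)) bad <- which(sds == 0)
      abort(paste0("Zero-variance vector(s) under the correlation metric: ",
                   paste(bad, collapse = ", ")))
    }
    d <- as.dist(1 - cor(t(x)))
  }
  attr(d, "metric") <- metric
  d
}

#' Complete-linkage hierarchical clustering
#'
#' @param d A [stats::dist] object, e.g. from [profile_distance()].
#' @return An [stats::hclust] tree (complete linkage).
#' @export
hierarchical_cluster <- function(d) {
  if (attr(d, "Size") < 2) abort("Need at least 2 observations to cluster.")
  hclust(d, method = "complete")
}

#' Cophenetic correlation between two dendrograms
#'
#' The cophenetic distance between two observations is the merge height at
#' which they are first combined into a single cluster. The cophenetic
#' correlation between two dendrograms over the same observations is the
#' Pearson correlation of their cophenetic distance vectors: 1 for identical
#' tree structure, near 0 for statistically unrelated trees.
#'
#' @param t1,t2 [stats::hclust] trees over the same labels.
#' @return The correlation coefficient r, between -1 and 1.
#' @export
cophenetic_correlation <- function(t1, t2) {
  if (!setequal(t1$labels, t2$labels) ||
      length(t1$labels) != length(t2$labels)) {
    abort("The two dendrograms must have identical leaf sets.")
  }
  c1 <- cophenetic(t1)
  c2 <- cophenetic(t2)
  # align label order before correlating the upper triangles
  m2 <- as.matrix(c2)[labels(c1), labels(c1)]
  cor(as.vector(c1), as.vector(as.dist(m2)))
}

#' Dendrogram fidelity as a function of the number of alpha values
#'
#' Measures how faithfully Diversity profiles represent the underlying clonal
#' frequency distributions: the cohort's distributions (on the union clone
#' index) and their Diversity profiles are each hierarchically clustered
#' (complete linkage, Pearson correlation distance by default), and the
#' cophenetic correlation between the two dendrograms is computed as the
#' number of alpha values entering the profile grows. With the
#' `"accumulate"` scheme the first `n` grid values (from alpha = 0 upward)
#' are used; the `"spread"` scheme instead takes `n` values evenly spread
#' over the grid.
#'
#' @param cohort Long tibble of repertoires (`sample_id`, `clone_id`,
#'   `frequency`), e.g. from [simulate_cohort()].
#' @param alphas Alpha grid on which profiles are computed.
#' @param n_alpha_values Integer vector of profile sizes to evaluate
#'   (each between 2 and `length(alphas)`).
#' @param metric Distance metric for both dendrograms (default
#'   `"correlation"`).
#' @param scheme `"accumulate"` (default) or `"spread"`.
#' @return A tibble of class `divprof_sweep` with columns `n_alphas` and
#'   `cophenetic_r`.
#' @export
alpha_sweep <- function(cohort, alphas = alpha_grid(),
                        n_alpha_values = seq(2, length(alphas)),
                        metric = c("correlation", "euclidean"),
                        scheme = c("accumulate", "spread")) {
  metric <- match.arg(metric)
  scheme <- match.arg(scheme)
  alphas <- check_alpha_grid(alphas)
  if (any(n_alpha_values < 2 | n_alpha_values > length(alphas))) {
    abort("`n_alpha_values` must lie between 2 and the grid length.")
  }
  m <- cohort_matrix(cohort)
  ref_tree <- hierarchical_cluster(profile_distance(m, metric))
  ref_coph <- as.vector(cophenetic(ref_tree))

  profiles <- repertoire_profiles(cohort, alphas)
  pm <- profile_matrix(profiles, "diversity")
  pm <- pm[rownames(m), , drop = FALSE]

  rs <- vapply(n_alpha_values, function(n) {
    cols <- switch(scheme,
      accumulate = seq_len(n),
      spread = unique(round(seq(1, length(alphas), length.out = n)))
    )
    tree <- hierarchical_cluster(profile_distance(pm[, cols, drop = FALSE],
                                                  metric))
    cor(ref_coph, as.vector(cophenetic(tree)))
  }, numeric(1))
  out <- tibble::tibble(n_alphas = as.integer(n_alpha_values),
                        cophenetic_r = rs)
  class(out) <- unique(c("divprof_sweep", class(out)))
  out
}
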