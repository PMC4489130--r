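#' Detect the intersection of two diversity profiles
#'
#' Two repertoires whose Diversity profiles cross exchange their diversity
#' ranking as alpha grows: single indices such as Shannon (alpha = 1) or
#' Simpson (alpha = 2) may then disagree qualitatively about which repertoire
#' is "more diverse". A crossing is reported wherever the profile difference
#' changes sign between adjacent grid points with magnitude above a relative
#' tolerance on both flanks (suppressing floating-point pseudo-crossings
#' between near-identical profiles); the crossing alpha is located by linear
#' interpolation.
#'
#' @param p1,p2 Diversity profiles on the same alpha grid: tibbles from
#'   [diversity_profile()] (column `diversity`) or [evenness_profile()]
#'   (column `evenness`).
#' @param tolerance Relative tolerance: differences with
#'   |d| <= tolerance * max(profile values) count as ties.
#' @return A list of class `intersection_report` with elements `intersects`
#'   (logical), `crossing_alphas` (interpolated crossing positions),
#'   `sign_pattern` (one of "+", "-", "0" per grid point, sign of p1 - p2).
#' @examples
#' f1 <- c(0.33, 0.29, 0.28, 0.05, 0.04, 0.01)
#' f2 <- c(0.42, 0.30, 0.10, 0.08, 0.05, 0.05)
#' detect_intersection(diversity_profile(f1), diversity_profile(f2))
#' @export
detect_intersection <- function(p1, p2, tolerance = 1e-6) {
  g1 <- profile_values(p1)
  g2 <- profile_values(p2)
  if (length(g1$alpha) != length(g2$alpha) ||
      any(abs(g1$alpha - g2$alpha) > 1e-12)) {
    abort("The two profiles must share the same alpha grid.")
  }
  d <- g1$value - g2$value
  scale <- max(abs(c(g1$value, g2$value)))
  s <- ifelse(abs(d) <= tolerance * scale, 0L, sign(d))
  crossings <- numeric(0)
  for (k in seq_len(length(d) - 1)) {
    if (s[k] * s[k + 1] == -1) {
      a0 <- g1$alpha[k]; a1 <- g1$alpha[k + 1]
      crossings <- c(crossings, a0 + (a1 - a0) * d[k] / (d[k] - d[k + 1]))
    }
  }
  structure(
    list(intersects = length(crossings) > 0,
         crossing_alphas = crossings,
         sign_pattern = c("-", "0", "+")[s + 2L]),
    class = "intersection_report"
  )
}

#' @export
print.intersection_report <- function(x, ...) {
  if (x$intersects) {
    cat("Profiles intersect at alpha =",
        paste(signif(x$crossing_alphas, 4), collapse = ", "), "\n")
  } else {
    cat("Profiles do not intersect.\n")
  }
  invisible(x)
}

# extract (alpha, value) from a profile tibble
profile_values <- function(p) {
  if (!is.data.frame(p) || !"alpha" %in% names(p)) {
    abort("Profiles must be tibbles with an `alpha` column.")
  }
  col <- intersect(c("diversity", "evenness"), names(p))[1]
  if (is.na(col)) abort("Profile needs a `diversity` or `evenness` column.")
  list(alpha = p$alpha, value = p[[col]])
}

#' Delineate differentially expanded sub-repertoires
#'
#' Compares the rank-ordered cumulative clonal frequency curves of two
#' repertoires. Because the Hill diversity is Schur-concave, intersecting
#' Diversity profiles imply intersecting cumulative frequency curves, and the
#' crossover ranks delineate the sub-repertoires over which each repertoire
#' is the more clonally expanded one. The per-rank difference of cumulative
#' frequencies (in percentage points) quantifies the expansion difference.
#'
#' @param f1,f2 Clonal frequency distributions (numeric vectors or
#'   single-sample tibbles, see [hill_diversity()]).
#' @return A list of class `subrepertoire_delineation`:
#'   * `curves` — tibble with `rank`, `cumulative_1`, `cumulative_2`,
#'     `difference_pct` (|cum1 - cum2| in percentage points) and `dominant`
#'     (`"1"`, `"2"` or `"tie"`) over ranks 1..min(n1, n2);
#'   * `crossover_ranks` — ranks at which strict dominance switches;
#'   * `segments` — tibble of maximal runs of equal dominance (ties merged
#'     into the preceding segment).
#' @examples
#' cumulative_curves(c(0.6, 0.4), c(0.5, 0.5))
#' @export
cumulative_curves <- function(f1, f2) {
  f1 <- sort(as_frequency_vector(f1), decreasing = TRUE)
  f2 <- sort(as_frequency_vector(f2), decreasing = TRUE)
  n <- min(length(f1), length(f2))
  if (n == 0) abort("Empty distribution.")
  c1 <- cumsum(f1)[seq_len(n)]
  c2 <- cumsum(f2)[seq_len(n)]
  d <- c1 - c2
  dom <- ifelse(abs(d) <= 1e-12, "tie", ifelse(d > 0, "1", "2"))
  curves <- tibble::tibble(
    rank = seq_len(n),
    cumulative_1 = c1,
    cumulative_2 = c2,
    difference_pct = 100 * abs(d),
    dominant = dom
  )
  # merge tie ranks into the preceding segment for reporting
  eff <- dom
  for (k in seq_len(n)) {
    if (eff[k] == "tie" && k > 1) eff[k] <- eff[k - 1]
  }
  runs <- rle(eff)
  ends <- cumsum(runs$lengths)
  segments <- tibble::tibble(
    start_rank = c(1L, head(ends, -1) + 1L),
    end_rank = ends,
    dominant = runs$values
  )
  strict <- eff[eff != "tie"]
  cross_at <- which(eff[-1] != eff[-n] & eff[-1] != "tie" & eff[-n] != "tie") + 1L
  structure(
    list(curves = curves, crossover_ranks = cross_at, segments = segments),
    class = "subrepertoire_delineation"
  )
}

#' @export
print.subrepertoire_delineation <- function(x, ...) {
  cat("Cumulative frequency dominance segments:\n")
  print(x$segments)
  if (length(x$crossover_ranks)) {
    cat("Dominance switches at rank(s):",
        paste(x$crossover_ranks, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Schur-concavity consistency between profile and cumulative intersection
#'
#' Checks, for one pair of repertoires, the implication guaranteed by the
#' Schur-concavity of the Hill diversity: if the Diversity profiles intersect
#' then the rank-ordered cumulative frequency curves intersect as well.
#' Intended as a property-test harness — the return value should be TRUE for
#' every valid pair of distributions.
#'
#' @inheritParams cumulative_curves
#' @param alphas Alpha grid over which profiles are compared.
#' @param tolerance Passed to [detect_intersection()].
#' @return TRUE iff the implication holds for this pair (vacuously TRUE when
#'   the profiles do not intersect).
#' @export
schur_consistency_check <- function(f1, f2, alphas = alpha_grid(),
                                    tolerance = 1e-6) {
  f1 <- as_frequency_vector(f1)
  f2 <- as_frequency_vector(f2)
  rep_int <- detect_intersection(diversity_profile(f1, alphas),
                                 diversity_profile(f2, alphas),
                                 tolerance)
  if (!rep_int$intersects) return(TRUE)
  dom <- cumulative_curves(f1, f2)$curves$dominant
  dom <- dom[dom != "tie"]
  length(unique(dom)) > 1
}

#' Robustness of profiles to sequencing depth
#'
#' Quantifies how stable Diversity (or Evenness) profiles are under
#' technological undersampling. For each depth fraction, every repertoire is
#' subsampled without replacement and its profile recomputed; the summary then
#' reports, per fraction:
#'
#' * `intersection_change_probability` — the fraction of repertoire pairs
#'   whose profile-intersection status differs from the full-depth status
#'   (qualitative robustness; 0 means perfectly stable);
#' * `intersection_probability` — the raw fraction of intersecting pairs at
#'   that depth;
#' * `mean_profile_distance` — mean Euclidean distance between each
#'   repertoire's subsampled and full-depth profile (quantitative
#'   robustness), with a profile-norm-scaled variant in
#'   `mean_profile_distance_normalized`.
#'
#' @param cohort Long tibble of repertoires (`sample_id`, `clone_id`,
#'   `count`), e.g. from [simulate_cohort()].
#' @param depth_fractions Depth fractions in (0, 1].
#' @param profile_kind `"diversity"` or `"evenness"`.
#' @param alphas Alpha grid.
#' @param seed Integer seed for the subsampling draws.
#' @param tolerance Passed to [detect_intersection()].
#' @return A tibble of class `divprof_robustness`, one row per fraction.
#' @export
robustness_analysis <- function(cohort,
                                depth_fractions = seq(0.1, 1, by = 0.1),
                                profile_kind = c("diversity", "evenness"),
                                alphas = alpha_grid(), seed = NULL,
                                tolerance = 1e-6) {
  profile_kind <- match.arg(profile_kind)
  if (any(depth_fractions <= 0 | depth_fractions > 1)) {
    abort("`depth_fractions` must lie in (0, 1].")
  }
  samples <- unique(cohort$sample_id)
  reps <- split(cohort[c("sample_id", "clone_id", "count")],
                factor(cohort$sample_id, levels = samples))
  full_mat <- t(vapply(reps, function(r) {
    profile_of(r$count / sum(r$count), alphas, profile_kind)
  }, numeric(length(alphas))))
  full_status <- pair_intersections(full_mat, alphas, tolerance)

  run <- function() {
    purrr::map_dfr(depth_fractions, function(fr) {
      sub_mat <- t(vapply(reps, function(r) {
        s <- subsample_reads(r, fr, seed = NULL)
        profile_of(s$frequency, alphas, profile_kind)
      }, numeric(length(alphas))))
      status <- pair_intersections(sub_mat, alphas, tolerance)
      dists <- sqrt(rowSums((sub_mat - full_mat)^2))
      tibble::tibble(
        fraction = fr,
        profile = profile_kind,
        intersection_change_probability = mean(status != full_status),
        intersection_probability = mean(status),
        mean_profile_distance = mean(dists),
        mean_profile_distance_normalized =
          mean(dists / sqrt(rowSums(full_mat^2)))
      )
    })
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  class(out) <- unique(c("divprof_robustness", class(out)))
  out
}

profile_of <- function(f, alphas, kind) {
  d <- hill_diversity(f, alphas)
  if (kind == "evenness") d / length(f) else d
}

# logical vector of intersection status over all row pairs of a profile matrix
pair_intersections <- function(mat, alphas, tolerance) {
  n <- nrow(mat)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  vapply(seq_len(nrow(idx)), function(k) {
    i <- idx[k, 1]; j <- idx[k, 2]
    d <- mat[i, ] - mat[j, ]
    scale <- max(abs(c(mat[i, ], mat[j, ])))
    s <- ifelse(abs(d) <= tolerance * scale, 0L, sign(d))
    any(s[-length(s)] * s[-1] == -1)
  }, logical(1))
}
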