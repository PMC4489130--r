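#' Hill diversity of a clonal frequency distribution
#'
#' Computes the Hill number of order `alpha`,
#' \deqn{{}^{\alpha}D(f) = \left(\sum_i f_i^{\alpha}\right)^{1/(1-\alpha)},}
#' the effective number of equally abundant clones reproducing the
#' repertoire's order-alpha diversity. Special orders are evaluated by their
#' closed forms: alpha = 0 gives the species richness n, alpha = 1 the limit
#' exp(Shannon entropy) (by L'Hopital's rule the general formula tends to the
#' exponential of the Shannon entropy as alpha tends to 1), alpha = 2 the
#' inverse Simpson index, and alpha = Inf the inverse Berger-Parker index
#' 1 / max(f). For all orders 1 <= D <= n, and D is non-increasing in alpha.
#'
#' Generic orders are evaluated in log space (log-sum-exp) so that very large
#' repertoires and large alpha neither underflow nor overflow.
#'
#' @param f A clonal frequency distribution: a numeric vector of positive
#'   frequencies summing to 1, or a single-sample tibble with a `frequency`
#'   (or `count`) column, e.g. from [clonal_frequencies()].
#' @param alpha Diversity order(s): finite values >= 0, or `Inf`. Vectorized.
#' @return A numeric vector of Hill numbers, one per `alpha`.
#' @examples
#' f <- c(0.33, 0.29, 0.28, 0.05, 0.04, 0.01)
#' hill_diversity(f, 0) # species richness: 6
#' hill_diversity(f, 1) # exp(Shannon entropy)
#' hill_diversity(f, Inf) # 1 / 0.33
#' @export
hill_diversity <- function(f, alpha) {
  f <- as_frequency_vector(f)
  if (length(alpha) == 0 || anyNA(alpha) || any(alpha < 0)) {
    abort("`alpha` must be >= 0 (Inf allowed).")
  }
  lf <- log(f)
  vapply(alpha, function(a) {
    if (a == 0) return(length(f))
    if (a == 1) return(exp(-sum(f * lf)))
    if (is.infinite(a)) return(1 / max(f))
    # log-sum-exp of alpha * log(f), then the 1/(1 - alpha) power
    la <- a * lf
    m <- max(la)
    exp((m + log(sum(exp(la - m)))) / (1 - a))
  }, numeric(1))
}

#' Renyi entropy of a clonal frequency distribution
#'
#' The Renyi entropy of order alpha, `log(hill_diversity(f, alpha))`. At
#' alpha = 1 this is the Shannon entropy; as alpha tends to infinity it tends
#' to `-log(max(f))` (min-entropy).
#'
#' @inheritParams hill_diversity
#' @return Numeric vector of entropies (natural log units).
#' @export
renyi_entropy <- function(f, alpha) {
  log(hill_diversity(f, alpha))
}

new_profile_tbl <- function(tbl) {
  class(tbl) <- unique(c("divprof_profile", class(tbl)))
  tbl
}

#' Diversity profile over an alpha grid
#'
#' Evaluates the Hill diversity of one repertoire over a grid of alpha values,
#' producing the Diversity profile — a fixed-length vector representation of
#' the repertoire that is comparable across samples regardless of clonal
#' composition.
#'
#' @inheritParams hill_diversity
#' @param alphas Alpha grid, see [alpha_grid()]. The default has 51 values
#'   (0 to 10, step 0.2).
#' @param sample_id Sample identifier attached to the profile.
#' @return A tibble with columns `sample_id`, `alpha`, `diversity`.
#' @seealso [evenness_profile()], [repertoire_profiles()]
#' @export
diversity_profile <- function(f, alphas = alpha_grid(), sample_id = "sample") {
  alphas <- check_alpha_grid(alphas)
  new_profile_tbl(tibble::tibble(
    sample_id = sample_id,
    alpha = alphas,
    diversity = hill_diversity(f, alphas)
  ))
}

#' Evenness profile over an alpha grid
#'
#' The Evenness profile is the Diversity profile scaled by species richness:
#' D = SR x E with SR = D at alpha 0, so E lies in (0, 1] and measures how far
#' the repertoire is from a uniform clonal frequency distribution — i.e. the
#' extent of clonal expansion, independent of repertoire size.
#'
#' @inheritParams diversity_profile
#' @return A tibble with columns `sample_id`, `alpha`, `evenness`, and the
#'   species richness in column `richness`.
#' @export
evenness_profile <- function(f, alphas = alpha_grid(), sample_id = "sample") {
  p <- diversity_profile(f, alphas, sample_id)
  sr <- hill_diversity(f, 0)
  new_profile_tbl(tibble::tibble(
    sample_id = p$sample_id,
    alpha = p$alpha,
    evenness = p$diversity / sr,
    richness = sr
  ))
}

#' Diversity and Evenness profiles for a table of repertoires
#'
#' The main tidy driver: takes a (possibly multi-sample) clonal frequency
#' table and returns one profile row per sample and alpha value.
#'
#' @param distributions A tibble with columns `sample_id`, `clone_id` and
#'   `frequency` (or `count`), e.g. from [clonal_frequencies()] or
#'   [simulate_cohort()].
#' @param alphas Alpha grid, see [alpha_grid()].
#' @return A tibble with columns `sample_id`, `alpha`, `diversity`,
#'   `evenness`, `richness`.
#' @examples
#' tbl <- tibble::tibble(
#'   sample_id = rep(c("s1", "s2"), each = 2),
#'   clone_id = c("A", "B", "A", "B"),
#'   count = c(3L, 1L, 2L, 2L)
#' )
#' repertoire_profiles(clonal_frequencies(tbl), alpha_grid(0, 2, 1))
#' @export
repertoire_profiles <- function(distributions, alphas = alpha_grid()) {
  alphas <- check_alpha_grid(alphas)
  if (!"sample_id" %in% names(distributions)) {
    distributions$sample_id <- "sample"
  }
  out <- distributions |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(function(g, key) {
      f <- as_frequency_vector(g)
      d <- hill_diversity(f, alphas)
      tibble::tibble(alpha = alphas, diversity = d,
                     evenness = d / length(f), richness = length(f))
    }) |>
    dplyr::ungroup()
  new_profile_tbl(out)
}

#' Profile feature matrix
#'
#' Pivots a long profile tibble into the samples-by-alphas matrix used by the
#' clustering and classification modules.
#'
#' @param profiles Profile tibble from [repertoire_profiles()],
#'   [diversity_profile()] or [evenness_profile()].
#' @param feature Which profile to extract: `"diversity"` or `"evenness"`.
#' @return A numeric matrix with samples as rows (rownames = sample ids) and
#'   alpha values as columns (colnames = alpha).
#' @export
profile_matrix <- function(profiles, feature = c("diversity", "evenness")) {
  feature <- match.arg(feature)
  if (!feature %in% names(profiles)) {
    abort(paste0("Column `", feature, "` not found in `profiles`."))
  }
  wide <- profiles |>
    dplyr::select("sample_id", "alpha", dplyr::all_of(feature)) |>
    tidyr::pivot_wider(names_from = "alpha", values_from = dplyr::all_of(feature))
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$sample_id
  if (anyNA(m)) abort("Profiles do not share a common alpha grid.")
  m
}
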