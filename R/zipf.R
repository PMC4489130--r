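#' Zipf-Mandelbrot model of clonal expansion
#'
#' Defines the clone probabilities of a power-law (Zipf-Mandelbrot) repertoire
#' population. The type density is g(pi) = C * pi^(-zipf_alpha - 1) on
#' 0 <= pi <= zipf_b, so `zipf_b` is the probability of the most frequent
#' clone and `zipf_alpha` in (0, 1) controls how steeply clone probabilities
#' decay with rank: inverting the cumulative type count gives the rank law
#' \deqn{\pi_k = \left(\frac{\alpha (k - 1)}{C} + B^{-\alpha}\right)^{-1/\alpha},}
#' with the normalizing constant C fixed numerically so that the clone
#' probabilities sum to 1. Low `zipf_b` corresponds to a polyclonal, weakly
#' expanded repertoire; high `zipf_b` to strong clonal expansion.
#'
#' The (infinite) rank series is truncated at the smallest rank whose
#' analytic tail mass falls below `tail_mass` (capped at `max_rank`) and the
#' residual mass renormalized.
#'
#' @param zipf_alpha Shape parameter in (0, 1).
#' @param zipf_b Probability of the most frequent clone, in (0, 1).
#' @param tail_mass Truncation tolerance for the rank series.
#' @param max_rank Hard cap on the truncation rank.
#' @return An object of class `zipf_model` with elements `zipf_alpha`,
#'   `zipf_b`, `C`, `max_rank` and the probability vector `probs`.
#' @examples
#' m <- zipf_model(0.1, 0.05)
#' m$probs[1] # equals zipf_b
#' sum(m$probs) # 1
#' @export
zipf_model <- function(zipf_alpha, zipf_b, tail_mass = 1e-9, max_rank = 1e7) {
  if (!is.numeric(zipf_alpha) || zipf_alpha <= 0 || zipf_alpha >= 1) {
    abort("`zipf_alpha` must lie in (0, 1).")
  }
  if (!is.numeric(zipf_b) || zipf_b <= 0 || zipf_b >= 1) {
    abort("`zipf_b` must lie in (0, 1).")
  }
  total <- function(C) sum(zm_rank_probs(zipf_alpha, zipf_b, C,
                                         tail_mass, max_rank))
  # sum(pi) is increasing in C; bracket then root-find on log C
  lo <- log(1e-8); hi <- log(1)
  while (total(exp(hi)) < 1) hi <- hi + 1
  while (total(exp(lo)) > 1) lo <- lo - 1
  C <- exp(uniroot(function(lc) total(exp(lc)) - 1, c(lo, hi),
                   tol = 1e-12)$root)
  probs <- zm_rank_probs(zipf_alpha, zipf_b, C, tail_mass, max_rank)
  probs <- probs / sum(probs)
  structure(
    list(zipf_alpha = zipf_alpha, zipf_b = zipf_b, C = C,
         max_rank = length(probs), probs = probs),
    class = "zipf_model"
  )
}

# Rank-law probabilities pi_k = (alpha*(k-1)/C + B^-alpha)^(-1/alpha),
# truncated where the analytic tail integral drops below tail_mass.
zm_rank_probs <- function(a, B, C, tail_mass, max_rank) {
  t0 <- B^(-a)
  tail_beyond <- function(K) C / (1 - a) * (a * K / C + t0)^(-(1 - a) / a)
  K <- 1024
  while (tail_beyond(K) > tail_mass && K < max_rank) K <- K * 2
  K <- min(K, max_rank)
  (a * (seq_len(K) - 1) / C + t0)^(-1 / a)
}

#' @export
print.zipf_model <- function(x, ...) {
  cat(sprintf(
    "Zipf-Mandelbrot clone model: zipf_alpha = %g, zipf_b = %g, C = %.4g, %d ranks\n",
    x$zipf_alpha, x$zipf_b, x$C, x$max_rank))
  invisible(x)
}

#' Clone probabilities of a Zipf-Mandelbrot model
#'
#' @param model A [zipf_model()].
#' @return Strictly decreasing probabilities summing to 1; the first equals
#'   the model's `zipf_b` up to truncation renormalization.
#' @export
zipf_clone_probabilities <- function(model) {
  stopifnot(inherits(model, "zipf_model"))
  model$probs
}

#' Simulate a sequenced repertoire from a Zipf-Mandelbrot model
#'
#' Draws `n_reads` sequencing reads i.i.d. from the model's clone
#' probabilities (a single multinomial draw) and converts the observed
#' per-clone read counts into a clonal frequency distribution. Clone identity
#' is the population rank, shared across repertoires simulated from any model
#' of the same family ("equal clonal composition"), so simulated cohorts can
#' be compared clone-by-clone.
#'
#' @param model A [zipf_model()].
#' @param n_reads Number of reads to draw (>= 1).
#' @param seed Integer seed; the draw is reproducible given
#'   (model, n_reads, seed). `NULL` uses the current RNG state.
#' @param sample_id Sample identifier attached to the simulated repertoire.
#' @return A tibble with columns `sample_id`, `clone_id` (e.g. `clone_0000001`
#'   = most probable population clone), `count`, `frequency`, sorted by
#'   descending frequency. Attributes `zipf_alpha`, `zipf_b`, `n_reads`,
#'   `seed` record the simulation parameters.
#' @export
simulate_repertoire <- function(model, n_reads, seed = NULL,
                                sample_id = "sim") {
  stopifnot(inherits(model, "zipf_model"))
  if (n_reads < 1) abort("`n_reads` must be >= 1.")
  draw <- function() rmultinom(1, n_reads, model$probs)[, 1]
  counts <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  observed <- which(counts > 0)
  out <- tibble::tibble(
    sample_id = sample_id,
    clone_id = sprintf("clone_%07d", observed),
    count = counts[observed],
    frequency = counts[observed] / n_reads
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$frequency), .data$clone_id)
  attr(out, "zipf_alpha") <- model$zipf_alpha
  attr(out, "zipf_b") <- model$zipf_b
  attr(out, "n_reads") <- n_reads
  attr(out, "seed") <- seed
  out
}

#' Simulate a cohort of repertoires across clonal-expansion states
#'
#' Simulates `n_repertoires` Zipf-Mandelbrot repertoires whose top-clone
#' probability `zipf_b` spans `zipf_b_range`, i.e. a gradient of clonal
#' expansion from polyclonal to strongly expanded, each sequenced at
#' `n_reads` reads. Because `zipf_b` spans two orders of magnitude, the
#' default spacing is logarithmically equidistant; `"linear"` and `"random"`
#' (uniform in the range) spacings are also available. All repertoires share
#' the rank-based clone identity, so their frequency vectors can be laid on a
#' common (union) clone index for clustering via [cohort_matrix()].
#'
#' @param n_repertoires Number of repertoires (>= 2).
#' @param zipf_alpha Shared shape parameter.
#' @param zipf_b_range Length-2 numeric range for `zipf_b`.
#' @param n_reads Reads per repertoire.
#' @param seed Integer seed governing all draws.
#' @param spacing `"log"` (default), `"linear"`, or `"random"`.
#' @return A long tibble (`sample_id`, `clone_id`, `count`, `frequency`) with
#'   a `manifest` attribute: a tibble of per-repertoire parameters.
#' @examples
#' coh <- simulate_cohort(4, n_reads = 1e4, seed = 1)
#' cohort_manifest(coh)
#' @export
simulate_cohort <- function(n_repertoires = 1000, zipf_alpha = 0.1,
                            zipf_b_range = c(0.001, 0.1), n_reads = 1e6,
                            seed = NULL,
                            spacing = c("log", "linear", "random")) {
  spacing <- match.arg(spacing)
  if (n_repertoires < 2) abort("`n_repertoires` must be >= 2.")
  bs <- switch(spacing,
    log = exp(seq(log(zipf_b_range[1]), log(zipf_b_range[2]),
                  length.out = n_repertoires)),
    linear = seq(zipf_b_range[1], zipf_b_range[2],
                 length.out = n_repertoires),
    random = {
      draw <- function() sort(stats::runif(n_repertoires, zipf_b_range[1],
                                           zipf_b_range[2]))
      if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    }
  )
  ids <- sprintf("rep_%04d", seq_len(n_repertoires))
  sim_all <- function() {
    purrr::map2(bs, ids, function(b, id) {
      simulate_repertoire(zipf_model(zipf_alpha, b), n_reads, seed = NULL,
                          sample_id = id)
    })
  }
  reps <- if (is.null(seed)) sim_all() else withr::with_seed(seed, sim_all())
  out <- dplyr::bind_rows(reps)
  attr(out, "manifest") <- tibble::tibble(
    sample_id = ids, zipf_alpha = zipf_alpha, zipf_b = bs,
    n_reads = n_reads, spacing = spacing, seed = if (is.null(seed)) NA_integer_ else seed
  )
  out
}

#' Cohort simulation manifest
#'
#' @param cohort A cohort tibble from [simulate_cohort()].
#' @return The per-repertoire parameter tibble.
#' @export
cohort_manifest <- function(cohort) attr(cohort, "manifest")

#' Equal-composition frequency matrix of a cohort
#'
#' Expresses every repertoire of a cohort on the union clone index, filling
#' unobserved clones with frequency 0. The zero-filled matrix is meant for
#' clustering and distance computations only — diversity computations always
#' use the strictly positive frequencies of each repertoire.
#'
#' @param distributions Long tibble with `sample_id`, `clone_id`, `frequency`.
#' @return A samples-by-clones numeric matrix of frequencies, clones ordered
#'   by clone id (population rank for simulated cohorts).
#' @export
cohort_matrix <- function(distributions) {
  clones <- sort(unique(distributions$clone_id))
  samples <- unique(distributions$sample_id)
  m <- matrix(0, length(samples), length(clones),
              dimnames = list(samples, clones))
  m[cbind(match(distributions$sample_id, samples),
          match(distributions$clone_id, clones))] <- distributions$frequency
  m
}

#' Subsample sequencing reads from a repertoire
#'
#' Draws `round(fraction * total_reads)` reads without replacement from the
#' repertoire's read pool (multivariate hypergeometric sampling), modelling a
#' shallower sequencing run of the same library. Clones with no sampled reads
#' are dropped, so species richness can only decrease.
#'
#' @param distribution Single-sample tibble with `clone_id` and `count`.
#' @param fraction Fraction of reads to keep, in (0, 1].
#' @param seed Integer seed, or `NULL`.
#' @return A tibble with columns `sample_id`, `clone_id`, `count`,
#'   `frequency` for the subsampled reads.
#' @export
subsample_reads <- function(distribution, fraction, seed = NULL) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    abort("`fraction` must lie in (0, 1].")
  }
  counts <- distribution$count
  total <- sum(counts)
  target <- round(fraction * total)
  if (target == total) {
    sub <- counts
  } else {
    draw <- function() {
      sub <- integer(length(counts))
      remaining <- total
      to_draw <- target
      for (i in seq_along(counts)) {
        if (to_draw == 0) break
        # draws from clone i vs the rest of the remaining pool
        sub[i] <- rhyper(1, counts[i], remaining - counts[i], to_draw)
        to_draw <- to_draw - sub[i]
        remaining <- remaining - counts[i]
      }
      sub
    }
    sub <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  }
  keep <- sub > 0
  out <- tibble::tibble(
    sample_id = if ("sample_id" %in% names(distribution)) {
      distribution$sample_id[keep]
    } else "sample",
    clone_id = distribution$clone_id[keep],
    count = sub[keep],
    frequency = sub[keep] / sum(sub)
  )
  dplyr::arrange(out, dplyr::desc(.data$frequency), .data$clone_id)
}
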