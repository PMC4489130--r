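#' Hyperparameter grid for the sparse profile classifier
#'
#' The default grid varies the misclassification cost c from 1 to 17 in five
#' equally spaced steps and the sparsity (regularization) parameter epsilon
#' over 2^i for i = -3, ..., 4. To keep models compact, any (c, epsilon)
#' combination for which more than `max_violations` inner-loop models select
#' more than `max_selected_features` alpha values is excluded from model
#' selection.
#'
#' @param cost Numeric vector of cost values.
#' @param epsilon Numeric vector of regularization values.
#' @param max_selected_features Upper limit on selected alpha values.
#' @param max_violations Number of inner models allowed to exceed the limit.
#' @return A list of class `hyperparameter_grid`.
#' @export
hyperparameter_grid <- function(cost = c(1, 5, 9, 13, 17),
                                epsilon = 2^(-3:4),
                                max_selected_features = 20,
                                max_violations = 3) {
  structure(
    list(cost = cost, epsilon = epsilon,
         max_selected_features = max_selected_features,
         max_violations = max_violations),
    class = "hyperparameter_grid"
  )
}

#' Fit a sparse linear profile classifier
#'
#' Fits an L1-regularized squared-hinge linear classifier: the misclassification
#' cost `cost` weights the hinge loss while `epsilon` penalizes the L1 norm of
#' the weights, so that larger `epsilon` yields sparser models — features with
#' non-zero weight are the "selected" alpha values. Features are standardized
#' (zero mean, unit variance) on the training data inside the fit, so no
#' information from any held-out sample enters the scaling.
#'
#' @param x Numeric feature matrix (samples x alpha values).
#' @param y Binary labels: a factor, or a vector coercible to one. The first
#'   level (or the `positive` argument) is the positive class.
#' @param cost Misclassification cost (> 0).
#' @param epsilon Sparsity penalty (> 0).
#' @param positive Label treated as the positive class.
#' @return An object of class `sparse_hinge` with elements `weights` (in
#'   standardized feature space), `intercept`, `selected` (column indices with
#'   non-zero weight), `center`, `scale`, `levels`, `positive`.
#' @seealso [nested_loocv()] for honest performance estimation.
#' @export
fit_sparse_hinge <- function(x, y, cost, epsilon, positive = NULL) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (nlevels(y) != 2) abort("`y` must contain exactly two classes.")
  if (is.null(positive)) positive <- levels(y)[1]
  if (!positive %in% levels(y)) abort("`positive` is not a label level.")
  ysign <- ifelse(y == positive, 1, -1)
  if (length(unique(ysign)) < 2) abort("Training data has a single class.")

  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  scale[scale == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")

  fit <- .sparse_hinge_fit(xs, as.numeric(ysign), cost, epsilon)
  structure(
    list(weights = as.numeric(fit$weights), intercept = fit$intercept,
         objective = fit$objective,
         selected = which(abs(fit$weights) > 0),
         center = center, scale = scale,
         levels = levels(y), positive = positive,
         cost = cost, epsilon = epsilon,
         feature_names = colnames(x)),
    class = "sparse_hinge"
  )
}

#' @export
predict.sparse_hinge <- function(object, newdata, type = c("class", "score"),
                                 ...) {
  type <- match.arg(type)
  newdata <- matrix(as.numeric(as.matrix(newdata)), ncol = length(object$center))
  xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  score <- drop(xs %*% object$weights + object$intercept)
  if (type == "score") return(score)
  neg <- setdiff(object$levels, object$positive)
  # scores within the tie tolerance of zero (e.g. from a degenerate
  # intercept-only model, whose intercept is zero up to rounding) are
  # resolved to the positive class uniformly, so that floating-point noise
  # cannot correlate with the training-set composition
  factor(ifelse(score >= -score_tie_tol, object$positive, neg),
         levels = object$levels)
}

#' @export
print.sparse_hinge <- function(x, ...) {
  cat(sprintf("Sparse hinge classifier (cost = %g, epsilon = %g): %d selected feature(s)\n",
              x$cost, x$epsilon, length(x$selected)))
  invisible(x)
}

#' Build a profile feature matrix with status labels
#'
#' Joins a long profile table with sample metadata into the samples-by-alphas
#' feature matrix and binary label vector consumed by [nested_loocv()].
#'
#' @param profiles Profile tibble from [repertoire_profiles()].
#' @param metadata Tibble with `sample_id` and `status_label`.
#' @param feature `"diversity"` or `"evenness"`.
#' @param positive_label Status label treated as the positive class; defaults
#'   to the first label in metadata order.
#' @return A list with `x` (matrix), `y` (factor, positive level first) and
#'   `alphas` (numeric column grid).
#' @export
profile_features <- function(profiles, metadata,
                             feature = c("diversity", "evenness"),
                             positive_label = NULL) {
  feature <- match.arg(feature)
  x <- profile_matrix(profiles, feature)
  meta <- metadata[match(rownames(x), metadata$sample_id), ]
  if (anyNA(meta$status_label)) abort("Metadata is missing some samples.")
  labels <- unique(meta$status_label)
  if (length(labels) != 2) abort("Exactly two status labels are required.")
  if (is.null(positive_label)) positive_label <- labels[1]
  y <- factor(meta$status_label,
              levels = c(positive_label, setdiff(labels, positive_label)))
  list(x = x, y = y, alphas = as.numeric(colnames(x)))
}

#' Nested leave-one-out cross-validated classification
#'
#' Estimates the out-of-sample performance of the sparse profile classifier
#' without test-set leakage. The outer loop leaves one sample out; an inner
#' leave-one-out loop over the remaining samples scores every (cost, epsilon)
#' combination by inner balanced accuracy. Combinations for which more than
#' `max_violations` inner models select more than `max_selected_features`
#' alpha values are excluded; among the survivors the best inner-BACC pair is
#' chosen (ties resolved toward larger epsilon — the sparser model — then
#' smaller cost), refit on all inner samples, and used to predict the held-out
#' sample. Sensitivity, specificity and balanced accuracy
#' BACC = (Sensitivity + Specificity) / 2 are computed from the pooled outer
#' predictions.
#'
#' @param x Feature matrix (samples x alpha values).
#' @param y Binary labels (factor; first level = positive class unless
#'   `positive` is given).
#' @param grid A [hyperparameter_grid()].
#' @param positive Positive class label.
#' @return An object of class `repertoire_classification` with percent-scale
#'   `bacc`, `sensitivity`, `specificity`, the outer `predictions` tibble,
#'   `selected_alphas_per_fold`, and `median_n_alphas`.
#' @export
nested_loocv <- function(x, y, grid = hyperparameter_grid(),
                         positive = NULL) {
  x <- as.matrix(x)
  y <- as.factor(y)
  n <- nrow(x)
  if (n < 6) abort("Nested leave-one-out cross-validation needs >= 6 samples.")
  if (nlevels(y) != 2) abort("`y` must contain exactly two classes.")
  if (min(table(y)) < 3) {
    abort("Each class needs >= 3 samples so every inner training set contains both classes.")
  }
  if (is.null(positive)) positive <- levels(y)[1]
  costs <- grid$cost
  epsilons <- grid$epsilon
  pairs <- expand.grid(epsilon = epsilons, cost = costs)
  yall <- ifelse(y == positive, 1, -1)

  # every leave-two-out inner model, fit once per unordered sample pair in
  # C++ with warm starts; dimensions: epsilon (fastest), cost, inner, outer
  cv <- .sparse_hinge_nested_cv(x, as.numeric(yall), costs, epsilons)
  dims <- c(length(epsilons), length(costs), n, n)
  score_arr <- array(cv$score, dim = dims)
  nsel_arr <- array(cv$n_selected, dim = dims)

  fold <- function(i) {
    xtr <- x[-i, , drop = FALSE]
    ytr <- y[-i]
    ysign <- yall[-i]
    stats_pair <- purrr::map_dfr(seq_len(nrow(pairs)), function(k) {
      e <- match(pairs$epsilon[k], epsilons)
      cc <- match(pairs$cost[k], costs)
      pred_pos <- score_arr[e, cc, -i, i] >= -score_tie_tol
      sens <- 100 * mean(pred_pos[ysign == 1])
      spec <- 100 * mean(!pred_pos[ysign == -1])
      tibble::tibble(
        k = k,
        bacc = (sens + spec) / 2,
        violations = sum(nsel_arr[e, cc, -i, i] > grid$max_selected_features)
      )
    })
    admissible <- stats_pair$violations <= grid$max_violations
    if (!any(admissible)) {
      abort("No admissible (cost, epsilon) combination: every pair exceeded the selected-feature limit.")
    }
    cand <- stats_pair[admissible, ]
    ord <- order(-cand$bacc, -pairs$epsilon[cand$k], pairs$cost[cand$k])
    best <- cand$k[ord[1]]
    m <- fit_sparse_hinge(xtr, ytr, pairs$cost[best], pairs$epsilon[best],
                          positive)
    tibble::tibble(
      sample = if (!is.null(rownames(x))) rownames(x)[i] else as.character(i),
      truth = as.character(y[i]),
      predicted = as.character(predict(m, x[i, , drop = FALSE])),
      cost = pairs$cost[best],
      epsilon = pairs$epsilon[best],
      inner_bacc = cand$bacc[ord[1]],
      n_selected = length(m$selected),
      selected = list(m$selected)
    )
  }

  predictions <- purrr::map_dfr(seq_len(n), fold)
  metrics <- bacc_percent(factor(predictions$predicted, levels = levels(y)),
                          y, positive)
  sel <- purrr::map(predictions$selected, function(ix) {
    if (!is.null(colnames(x))) as.numeric(colnames(x))[ix] else ix
  })
  structure(
    list(bacc = metrics$bacc, sensitivity = metrics$sensitivity,
         specificity = metrics$specificity,
         predictions = predictions[, setdiff(names(predictions), "selected")],
         selected_alphas_per_fold = sel,
         median_n_alphas = median(predictions$n_selected),
         positive = positive, grid = grid, n = n),
    class = "repertoire_classification"
  )
}

# decision scores this close to zero count as ties (resolved to the positive
# class); real margins are on the scale of 1 after standardization
score_tie_tol <- 1e-9

# pooled sensitivity/specificity/BACC in percent
bacc_percent <- function(predicted, truth, positive) {
  pos <- truth == positive
  sens <- 100 * mean(predicted[pos] == positive)
  spec <- 100 * mean(predicted[!pos] != positive)
  list(bacc = (sens + spec) / 2, sensitivity = sens, specificity = spec)
}

#' @export
print.repertoire_classification <- function(x, ...) {
  cat(sprintf(
    "Nested LOOCV classification (n = %d, positive = %s)\n  BACC %.1f%%  sensitivity %.1f%%  specificity %.1f%%  median #alphas %.1f\n",
    x$n, x$positive, x$bacc, x$sensitivity, x$specificity, x$median_n_alphas))
  if (!is.null(x$permutation_p)) {
    cat(sprintf("  permutation p = %.4g (%d shuffles)%s\n", x$permutation_p,
                x$n_permutations, if (x$significant) " *" else ""))
  }
  invisible(x)
}

#' Permutation test for classification significance
#'
#' Shuffles the label vector `n_permutations` times, reruns the full nested
#' leave-one-out pipeline on each shuffle, and reports
#' p = (number of permuted BACCs strictly exceeding the observed BACC) /
#' n_permutations. With 1000 shuffles, a result is flagged significant when
#' fewer than 10 permuted BACCs exceed the observed one (p < 0.01); the
#' strict "exceeding" comparison is used at the boundary.
#'
#' @inheritParams nested_loocv
#' @param n_permutations Number of label shuffles (default 1000; fewer than
#'   100 triggers a resolution warning).
#' @param seed Integer seed for the shuffles.
#' @param result Optional precomputed [nested_loocv()] result for (x, y) to
#'   avoid refitting the observed model.
#' @return The `repertoire_classification` object augmented with
#'   `permutation_p`, `n_permutations`, `n_exceeding`, `permuted_baccs` and
#'   the `significant` flag (p < 0.01).
#' @export
permutation_test <- function(x, y, grid = hyperparameter_grid(),
                             n_permutations = 1000, seed = NULL,
                             positive = NULL, result = NULL) {
  if (n_permutations < 100) {
    warn("Fewer than 100 permutations: the p-value resolution is coarse.")
  }
  if (is.null(result)) result <- nested_loocv(x, y, grid, positive)
  run <- function() {
    vapply(seq_len(n_permutations), function(b) {
      yb <- sample(y)
      nested_loocv(x, yb, grid, positive)$bacc
    }, numeric(1))
  }
  perm <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  exceeding <- sum(perm > result$bacc)
  result$permutation_p <- exceeding / n_permutations
  result$n_permutations <- n_permutations
  result$n_exceeding <- exceeding
  result$permuted_baccs <- perm
  result$significant <- exceeding < 0.01 * n_permutations
  result
}

#' Single-index classification baseline
#'
#' Runs the same nested leave-one-out pipeline with the feature set restricted
#' to conventional single diversity indices (by default alpha in {1, 2}:
#' Shannon and Simpson), for profile-versus-single-index comparisons.
#'
#' @inheritParams nested_loocv
#' @param alphas_keep Alpha values (matching the column names of `x`) to
#'   retain.
#' @return A `repertoire_classification` object.
#' @export
single_index_baseline <- function(x, y, grid = hyperparameter_grid(),
                                  alphas_keep = c(1, 2), positive = NULL) {
  cols <- as.numeric(colnames(x))
  keep <- which(cols %in% alphas_keep)
  if (length(keep) == 0) {
    abort("None of `alphas_keep` is a column of `x`.")
  }
  nested_loocv(x[, keep, drop = FALSE], y, grid, positive)
}
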