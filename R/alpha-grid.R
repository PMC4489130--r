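#' Grid of diversity orders (alpha values)
#'
#' Builds the ordered grid of Hill orders over which Diversity and Evenness
#' profiles are evaluated. The default grid runs from alpha = 0 to alpha = 10
#' in steps of 0.2 (51 values); most repertoire profiles have levelled off by
#' alpha = 10, so a wider range adds little information.
#'
#' @param min,max Lower and upper bound of the grid (both >= 0).
#' @param step Spacing between consecutive alpha values.
#' @return A strictly increasing numeric vector of alpha values.
#' @examples
#' length(alpha_grid()) # 51
#' alpha_grid(0, 2, 0.5)
#' @export
alpha_grid <- function(min = 0, max = 10, step = 0.2) {
  if (min < 0 || max <= min || step <= 0) {
    abort("`alpha_grid()` needs 0 <= min < max and step > 0.")
  }
  seq(min, max, by = step)
}

# validate an alpha grid supplied by the user
check_alpha_grid <- function(alphas) {
  if (length(alphas) == 0 || anyNA(alphas)) {
    abort("The alpha grid must be a non-empty numeric vector without NA.")
  }
  if (any(alphas < 0)) abort("Alpha values must be >= 0.")
  if (is.unsorted(alphas, strictly = TRUE)) {
    abort("The alpha grid must be strictly increasing.")
  }
  as.numeric(alphas)
}
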