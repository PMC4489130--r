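# naive O(n^3) complete-linkage agglomeration used as an independent oracle:
# returns the matrix of first-merge heights (cophenetic distances)
naive_complete_cophenetic <- function(d) {
  m <- as.matrix(d)
  n <- nrow(m)
  groups <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(groups) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (a in seq_along(groups)) {
      for (b in seq_len(a - 1)) {
        h <- max(m[groups[[a]], groups[[b]]])
        if (h < best_h) { best_h <- h; best <- c(b, a) }
      }
    }
    ga <- groups[[best[1]]]; gb <- groups[[best[2]]]
    coph[ga, gb] <- best_h
    coph[gb, ga] <- best_h
    groups[[best[1]]] <- c(ga, gb)
    groups[[best[2]]] <- NULL
  }
  coph
}

test_that("distance metrics match their definitions", {
  v <- c(1, 2, 3)
  x <- rbind(a = v, b = v)
  expect_equal(as.vector(profile_distance(x, "euclidean")), 0)
  expect_equal(as.vector(profile_distance(x, "correlation")), 0)
  # scaling leaves the correlation distance at 0 but not the euclidean one
  y <- rbind(a = v, b = 2 * v)
  expect_equal(as.vector(profile_distance(y, "correlation")), 0)
  expect_equal(as.vector(profile_distance(y, "euclidean")), sqrt(sum(v^2)))
  # perfectly anti-correlated vectors sit at the metric's maximum of 2
  z <- rbind(a = c(1, 2, 3), b = c(3, 2, 1))
  expect_equal(as.vector(profile_distance(z, "correlation")), 2)
  flat <- rbind(a = c(1, 1, 1), b = v)
  expect_error(profile_distance(flat, "correlation"), "Zero-variance.*a")
})

test_that("complete linkage reproduces hand agglomeration", {
  d <- as.dist(matrix(c(0, 1, 5, 1, 0, 6, 5, 6, 0), 3, 3,
                      dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  tree <- hierarchical_cluster(d)
  expect_equal(tree$height, c(1, 6))  # A,B merge at 1; C joins at max = 6
  expect_equal(sort(tree$labels), c("A", "B", "C"))
  two <- hierarchical_cluster(as.dist(matrix(c(0, 3, 3, 0), 2, 2,
                                             dimnames = list(c("x", "y")))))
  expect_equal(two$height, 3)
})

test_that("cophenetic distances agree with a brute-force agglomeration oracle", {
  withr::local_seed(5)
  for (rep in 1:10) {
    n <- sample(4:9, 1)
    x <- matrix(rnorm(n * 4), n)
    rownames(x) <- paste0("s", seq_len(n))
    d <- profile_distance(x, "euclidean")
    got <- as.matrix(cophenetic(hierarchical_cluster(d)))
    want <- naive_complete_cophenetic(d)
    dimnames(want) <- dimnames(got)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("cophenetic correlation is 1 for identical trees and symmetric", {
  withr::local_seed(8)
  x <- matrix(rnorm(40), 8); rownames(x) <- paste0("s", 1:8)
  t1 <- hierarchical_cluster(profile_distance(x, "euclidean"))
  expect_equal(cophenetic_correlation(t1, t1), 1)
  t1b <- hierarchical_cluster(profile_distance(x, "euclidean"))
  expect_equal(cophenetic_correlation(t1, t1b), 1)
  y <- matrix(rnorm(40), 8); rownames(y) <- paste0("s", 1:8)
  t2 <- hierarchical_cluster(profile_distance(y, "euclidean"))
  expect_equal(cophenetic_correlation(t1, t2), cophenetic_correlation(t2, t1))
  expect_lt(abs(cophenetic_correlation(t1, t2)), 1)
  z <- hierarchical_cluster(profile_distance(y[1:6, ], "euclidean"))
  expect_error(cophenetic_correlation(t1, z), "leaf")
})

test_that("trees from unrelated random data correlate near zero on average", {
  withr::local_seed(31)
  rs <- replicate(30, {
    a <- matrix(rnorm(15 * 6), 15)
    b <- matrix(rnorm(15 * 6), 15)
    rownames(a) <- rownames(b) <- paste0("s", 1:15)
    cophenetic_correlation(
      hierarchical_cluster(profile_distance(a, "euclidean")),
      hierarchical_cluster(profile_distance(b, "euclidean")))
  })
  expect_lt(abs(mean(rs)), 0.15)
})

test_that("the alpha sweep tracks dendrogram fidelity and is reproducible", {
  coh <- simulate_cohort(12, n_reads = 2e4, seed = 17)
  grid <- alpha_grid()
  sw <- alpha_sweep(coh, grid, c(2, 10, 51))
  expect_s3_class(sw, "divprof_sweep")
  expect_equal(sw$n_alphas, c(2L, 10L, 51L))
  expect_true(all(abs(sw$cophenetic_r) <= 1 + 1e-12))
  sw2 <- alpha_sweep(coh, grid, c(2, 10, 51))
  expect_equal(tibble::as_tibble(sw), tibble::as_tibble(sw2))
  expect_error(alpha_sweep(coh, grid, c(1, 10)), "between 2")
  # spread subsets pick evenly spaced alphas and stay in bounds
  sp <- alpha_sweep(coh, grid, c(5, 26), scheme = "spread")
  expect_true(all(abs(sp$cophenetic_r) <= 1 + 1e-12))
})
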