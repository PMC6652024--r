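test_that("cluster-number approximation recovers separated components and collapses degenerate input", {
  set.seed(4)
  three <- c(rnorm(100, 0, 0.5), rnorm(100, 50, 0.5), rnorm(100, 100, 0.5))
  k_hat <- approximate_k(three, seed = 2)
  expect_identical(k_hat, 3L)
  expect_identical(k_hat, oracle_silhouette_k(three))

  expect_identical(approximate_k(rep(3.2, 100)), 1L)

  one <- rnorm(200)
  expect_lte(approximate_k(one, seed = 2), 3L)

  # deterministic given seed
  expect_identical(approximate_k(three, seed = 9), approximate_k(three, seed = 9))
})

test_that("cluster-number approximation is equivariant under affine maps", {
  set.seed(21)
  cases <- list(
    c(rnorm(150, 0, 0.4), rnorm(150, 30, 0.4)),
    rlnorm(200),
    c(rnorm(80), rnorm(80, 12), rnorm(80, 24))
  )
  for (v in cases) {
    k0 <- approximate_k(v, seed = 5)
    expect_identical(approximate_k(-2.5 * v + 7, seed = 5), k0)
    expect_identical(approximate_k(v / 1000 - 4, seed = 5), k0)
  }
})

test_that("hierarchical cut centroids match the exhaustive 1-D optimum on small inputs", {
  expect_equal(hierarchical_centroids(c(0, 1, 10, 11), 2), c(0.5, 10.5))
  expect_equal(hierarchical_centroids(c(0, 0, 0, 9), 2), c(0, 9))
  expect_equal(hierarchical_centroids(c(3, 9, 4), 1), mean(c(3, 9, 4)))
  expect_warning(cen <- hierarchical_centroids(c(1, 1, 2), 3), "distinct")
  expect_length(cen, 2L)
})

test_that("the DP partition oracle agrees with brute-force enumeration on tiny inputs", {
  set.seed(31)
  for (rep in 1:8) {
    n <- sample(3:7, 1)
    k <- sample(2:3, 1)
    v <- rnorm(n, sd = 3)
    expect_equal(oracle_kmeans_ss(v, k), oracle_bruteforce_ss(v, k), tolerance = 1e-10)
  }
})

test_that("Lloyd refinement reproduces the worked example and its fixed points", {
  m <- kmeans_refine(c(0, 1, 10, 11), c(0.5, 10.5))
  expect_equal(m$assignments, c(1L, 1L, 2L, 2L))
  expect_equal(m$distortion, 1.0)
  expect_equal(m$populations, c(2L, 2L))

  # k = n with centroids at the points: zero distortion
  v <- c(2, 4, 9)
  m0 <- kmeans_refine(v, v)
  expect_equal(m0$distortion, 0)

  # a converged model is a fixed point of refinement
  m2 <- kmeans_refine(c(0, 1, 10, 11), m$centroids)
  expect_equal(m2$centroids, m$centroids)
  expect_equal(m2$assignments, m$assignments)

  # distortion equals the within-cluster SS recomputed from assignments
  recomputed <- sum((c(0, 1, 10, 11) - m$centroids[m$assignments])^2)
  expect_equal(m$distortion, recomputed)
})

test_that("Lloyd refinement matches stats::kmeans run from the same initialization", {
  set.seed(17)
  for (rep in 1:20) {
    v <- c(rnorm(15, 0), rnorm(15, 6), rnorm(15, 14))
    cen <- hierarchical_centroids(v, 3)
    ours <- kmeans_refine(v, cen)
    ref <- stats::kmeans(v, matrix(cen, ncol = 1), algorithm = "Lloyd",
                         iter.max = 100)
    expect_equal(ours$distortion, ref$tot.withinss, tolerance = 1e-8)
  }
})

test_that("hybrid clustering separates gapped groups and never worsens the hierarchical cut", {
  m <- hkmeans(c(0, 1, 10, 11), 2)
  expect_equal(sort(m$populations), c(2L, 2L))
  expect_equal(sort(m$centroids), c(0.5, 10.5))

  set.seed(23)
  for (rep in 1:10) {
    v <- rnorm(20)
    cen <- hierarchical_centroids(v, 4)
    init_assign <- apply(abs(outer(v, cen, "-")), 1, which.min)
    init_ss <- sum((v - cen[init_assign])^2)
    expect_lte(hkmeans(v, 4)$distortion, init_ss + 1e-12)
  }
})

test_that("hybrid clustering finds the optimum on separated body-plus-outlier instances", {
  set.seed(41)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    v <- c(rnorm(n - 1, 0, 0.3), rnorm(1, 20, 0.3))
    m <- hkmeans(v, 2)
    expect_equal(m$distortion, oracle_kmeans_ss(v, 2), tolerance = 1e-8)
  }
})

test_that("1-D clusters are contiguous intervals of the sorted values", {
  set.seed(53)
  for (rep in 1:15) {
    v <- rlnorm(sample(10:50, 1))
    m <- hkmeans(v, 3)
    a_sorted <- m$assignments[order(v)]
    # each cluster occupies one consecutive run
    expect_equal(length(rle(a_sorted)$values), length(unique(a_sorted)))
  }
})

test_that("census populations always sum to the number of points", {
  set.seed(61)
  for (rep in 1:10) {
    v <- rnorm(sample(5:60, 1))
    m <- hkmeans(v, sample(1:4, 1))
    census <- cluster_census(m)
    expect_equal(sum(census$population), length(v))
    expect_true(all(census$population >= 1L))
  }
  m3 <- kmeans_refine(c(1, 1, 5), c(1, 5))
  expect_equal(cluster_census(m3)$population, c(2L, 1L))
})

test_that("flag threshold implements the floor of the population fraction", {
  expect_identical(flag_threshold(10000, 1 / 10000), 1L)
  expect_identical(flag_threshold(500, 1 / 500), 1L)
  expect_identical(flag_threshold(10000, 1 / 500), 20L)
  # alpha stored as 1/n must not lose the integer through rounding
  for (n in c(500, 1000, 2000, 3000, 4000, 5000, 6000, 10000)) {
    expect_identical(flag_threshold(n, 1 / n), 1L)
  }
  expect_identical(flag_threshold(9, 1 / 10), 0L)
  expect_error(flag_threshold(10, 2), class = "iodetect_validation_error")
})

test_that("sparse-cluster flagging selects exactly the under-populated clusters", {
  v <- c(rep(0, 9), 100)
  m <- hkmeans(v, 2)
  expect_equal(m$populations, c(9L, 1L))
  expect_identical(flag_sparse(m, 1L), 10L)      # the singleton point
  expect_identical(flag_sparse(m, 0L), integer(0))
  expect_identical(sort(flag_sparse(m, 10L)), 1:10)  # threshold = n flags all

  balanced <- hkmeans(c(rnorm(50, 0, 0.1), rnorm(50, 10, 0.1)), 2)
  expect_identical(flag_sparse(balanced, 1L), integer(0))

  # flagged count is bounded by threshold times cluster count
  set.seed(71)
  for (rep in 1:10) {
    v <- rlnorm(40)
    m <- hkmeans(v, 4)
    thr <- sample(0:3, 1)
    expect_lte(length(flag_sparse(m, thr)), thr * m$k)
  }
})
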