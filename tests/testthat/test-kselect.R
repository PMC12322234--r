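test_that("elbow choice matches distance-to-chord arithmetic", {
  expect_equal(elbow_k(c(100, 20, 18, 17), 1:4), 2)
  # linear decline is a flat tie -> smallest k
  expect_equal(elbow_k(c(30, 20, 10), 1:3), 1)
  # hand check: chord from (1,10) to (5,0); k = 2 farthest
  expect_equal(elbow_k(c(10, 2, 1.5, 1, 0), 1:5), 2)
  expect_error(elbow_k(c(3, 1), 1:2), "three points")
})

test_that("silhouettes match the hand example and singleton rule", {
  x <- c(0, 0.1, 10, 10.1)
  d <- abs(outer(x, x, "-"))
  rownames(d) <- colnames(d) <- paste0("s", 1:4)
  lab <- setNames(c(1L, 1L, 2L, 2L), rownames(d))
  s <- silhouette_widths(d, lab)
  expect_equal(s$width[1], (10.05 - 0.1) / 10.05, tolerance = 1e-12)

  # equidistant point has s = 0
  d2 <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3)
  rownames(d2) <- colnames(d2) <- paste0("s", 1:3)
  s2 <- silhouette_widths(d2, setNames(c(1L, 1L, 2L), rownames(d2)))
  expect_equal(s2$width[1], 0)
  # singleton cluster member gets 0
  expect_equal(s2$width[3], 0)

  expect_error(silhouette_widths(d, setNames(rep(1L, 4), rownames(d))),
               "two clusters")
})

test_that("vectorized silhouettes equal a brute-force recomputation", {
  brute_silhouette <- function(d, lab) {
    n <- length(lab)
    vapply(seq_len(n), function(i) {
      mine <- which(lab == lab[i])
      if (length(mine) == 1L) return(0)
      a <- mean(d[i, setdiff(mine, i)])
      b <- min(vapply(setdiff(unique(lab), lab[i]), function(k) {
        mean(d[i, lab == k])
      }, numeric(1)))
      if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }, numeric(1))
  }
  set.seed(10)
  for (rep in 1:50) {
    n <- sample(6:25, 1)
    X <- matrix(rnorm(n * 6), n, 6)
    rownames(X) <- paste0("s", seq_len(n))
    k <- sample(2:4, 1)
    lab <- setNames(sample(seq_len(k), n, replace = TRUE), rownames(X))
    if (length(unique(lab)) < 2) next
    d <- pearson_distance(X)
    s <- silhouette_widths(d, lab)
    expect_equal(s$width, brute_silhouette(d, lab), tolerance = 1e-12)
  }
})

test_that("silhouettes agree with the cluster package on Euclidean data", {
  skip_if_not_installed("cluster")
  set.seed(11)
  X <- matrix(rnorm(20 * 4), 20, 4)
  rownames(X) <- paste0("s", 1:20)
  lab <- setNames(rep(1:4, each = 5), rownames(X))
  d <- as.matrix(stats::dist(X))
  ours <- silhouette_widths(d, lab)
  ref <- cluster::silhouette(unname(lab), stats::dist(X))
  expect_equal(ours$width, unname(ref[, "sil_width"]), tolerance = 1e-12)
})

test_that("gap statistic separates one blob from two", {
  set.seed(12)
  one <- matrix(rnorm(60 * 2), 60, 2)
  g1 <- gap_statistic(one, k_range = 1:4, B = 30, n_restarts = 5, seed = 2,
                      distance = "euclidean")
  expect_equal(g1$k, 1)
  two <- rbind(matrix(rnorm(30 * 2), 30, 2), matrix(rnorm(30 * 2, 10), 30, 2))
  g2 <- gap_statistic(two, k_range = 1:4, B = 30, n_restarts = 5, seed = 2,
                      distance = "euclidean")
  expect_equal(g2$k, 2)
  expect_error(gap_statistic(one, k_range = integer(0)), "empty")
})

test_that("heuristic votes combine by majority with silhouette tiebreak", {
  expect_equal(combine_k_choices(5, 5, 4), 5)
  expect_equal(combine_k_choices(1, 1, 1), 1)
  expect_equal(combine_k_choices(3, 4, 5), 5)
  expect_equal(combine_k_choices(4, 7, 7), 7)
})
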