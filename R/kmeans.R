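# samples x features numeric matrix from any of the package's tabular types
as_feature_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) rownames(x) <- paste0("row", seq_len(nrow(x)))
    return(x)
  }
  if (inherits(x, "metabo_ratio")) return(ratio_values(x))
  if (inherits(x, "metabo_abundance")) return(abn_matrix(x))
  if (is.data.frame(x) && "sample_id" %in% names(x)) {
    m <- as.matrix(x[setdiff(names(x), "sample_id")])
    rownames(m) <- x$sample_id
    return(m)
  }
  abort("cannot interpret `x` as a samples-by-features matrix.")
}

# center each row to mean 0 and scale to unit Euclidean norm, so that
# squared distance between rows is 2 * (1 - Pearson r)
row_standardize <- function(X) {
  ctr <- X - rowMeans(X)
  nrm <- sqrt(rowSums(ctr^2))
  bad <- nrm == 0 | !is.finite(nrm)
  if (any(bad)) {
    abort(paste0("zero-variance rows: ",
                 paste(rownames(X)[bad], collapse = ", ")))
  }
  ctr / nrm
}

#' Correlation distance between samples
#'
#' `d(i, j) = 1 - Pearson r(row_i, row_j)`, the dissimilarity underlying
#' the package's clustering: 0 for perfectly correlated profiles, 2 for
#' perfectly anti-correlated ones. Insensitive to per-sample location and
#' positive scale.
#'
#' @param x Samples-by-features matrix, ratio tibble, or abundance tibble.
#' @return A symmetric matrix of distances in \[0, 2\] with zero diagonal.
#' @export
pearson_distance <- function(x) {
  X <- as_feature_matrix(x)
  if (ncol(X) < 2L) abort("need at least two features per sample.")
  Z <- row_standardize(X)
  d <- 1 - tcrossprod(Z)
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' K-means under the 1 - Pearson correlation distance
#'
#' Lloyd's algorithm on row-standardized data (each sample centered to
#' mean 0 and unit norm), where squared Euclidean distance is exactly
#' `2 * (1 - r)`; centroids are the means of their members, re-standardized
#' after every update so they stay on the correlation sphere. Initialization
#' is k-means++ driven by `seed`; an emptied cluster is re-seeded at the
#' point farthest from its current centroid. Iteration stops when
#' assignments are stable or after `max_iter` sweeps.
#'
#' @param x Samples-by-features data (matrix or ratio/abundance tibble).
#' @param k Number of clusters, `1 <= k <= n samples`.
#' @param seed Seed for the initialization draws.
#' @param max_iter Maximum Lloyd sweeps (default 300).
#' @param distance `"pearson"` (the default: Lloyd on row-standardized
#'   data, centroids re-standardized) or `"euclidean"` (plain K-means on
#'   the rows as given, for data where the correlation geometry is not
#'   meaningful, e.g. very low-dimensional point clouds).
#' @return A `metabo_kmeans` list: `labels` (named integer vector), `wss`
#'   (total within-cluster sum of squared distances on the standardized
#'   rows), `centers`, `iterations`.
#' @export
kmeans_correlation <- function(x, k, seed = NULL, max_iter = 300L,
                               distance = c("pearson", "euclidean")) {
  distance <- match.arg(distance)
  X <- as_feature_matrix(x)
  n <- nrow(X)
  check_number(k, "k", min = 1)
  k <- as.integer(k)
  if (k > n) abort(sprintf("k = %d exceeds the number of samples (%d).", k, n))
  Z <- if (distance == "pearson") row_standardize(X) else X
  with_rng(seed, {
    C <- Z[kmeanspp_init(Z, k), , drop = FALSE]
    labels <- rep(0L, n)
    iter <- 0L
    repeat {
      iter <- iter + 1L
      d2 <- dist2_to_centers(Z, C)
      new_labels <- max.col(-d2, ties.method = "first")
      # refill emptied clusters with the worst-fitted point
      guard <- 0L
      while (any(tabulate(new_labels, k) == 0L) && guard < k) {
        guard <- guard + 1L
        c_empty <- which(tabulate(new_labels, k) == 0L)[1L]
        far <- which.max(d2[cbind(seq_len(n), new_labels)])
        C[c_empty, ] <- Z[far, ]
        d2 <- dist2_to_centers(Z, C)
        new_labels <- max.col(-d2, ties.method = "first")
        new_labels[far] <- c_empty
      }
      if (identical(new_labels, labels) || iter >= max_iter) {
        labels <- new_labels
        break
      }
      labels <- new_labels
      counts <- tabulate(labels, k)
      sums <- rowsum(Z, labels)
      C[as.integer(rownames(sums)), ] <- sums / counts[counts > 0L]
      if (distance == "pearson") {
        C <- C - rowMeans(C)
        nrm <- sqrt(rowSums(C^2))
        nrm[nrm == 0] <- 1
        C <- C / nrm
      }
    }
    wss <- sum(rowSums((Z - C[labels, , drop = FALSE])^2))
    structure(list(labels = setNames(labels, rownames(X)),
                   wss = wss, centers = C, iterations = iter),
              class = "metabo_kmeans")
  })
}

# k-means++ seeding: each new center drawn with probability proportional to
# squared distance from the nearest chosen center
kmeanspp_init <- function(Z, k) {
  n <- nrow(Z)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  if (k == 1L) return(centers)
  d2 <- rowSums((Z - Z[rep(centers[1L], n), , drop = FALSE])^2)
  for (j in 2:k) {
    if (sum(d2) <= 0) {
      centers[j] <- sample.int(n, 1L)
    } else {
      centers[j] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, rowSums((Z - Z[rep(centers[j], n), , drop = FALSE])^2))
  }
  centers
}

dist2_to_centers <- function(Z, C) {
  d2 <- outer(rowSums(Z^2), rowSums(C^2), "+") - 2 * tcrossprod(Z, C)
  d2[d2 < 0] <- 0
  d2
}

# best of n_restarts runs by within-cluster sum of squares
kmeans_best <- function(x, k, n_restarts = 10L, seed = 1L,
                        distance = "pearson") {
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- kmeans_correlation(x, k, seed = derive_seed(seed, r - 1L),
                              distance = distance)
    if (is.null(best) || fit$wss < best$wss) best <- fit
  }
  best
}
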