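#' Gap statistic for choosing the number of clusters
#'
#' For each k, the observed within-cluster dispersion `W_k` (sum over
#' clusters of half the mean within-cluster pairwise squared distance,
#' computed on the row-standardized data — identical to the K-means
#' within-cluster sum of squares) is compared to its expectation under a
#' null with no cluster structure: `B` reference datasets drawn uniformly
#' over each feature's observed range and clustered by the same procedure.
#' `Gap(k) = mean_B log W_k(ref) - log W_k`, with simulation error
#' `s_k = sd_B(log W_k(ref)) * sqrt(1 + 1/B)`. The chosen k is the
#' smallest with `Gap(k) >= Gap(k+1) - s_(k+1)` (falling back to the
#' argmax of the gap curve if no k qualifies).
#'
#' @param x Samples-by-features data.
#' @param k_range Contiguous integer vector of candidate k (include 1 so a
#'   structureless dataset can be recognized).
#' @param B Number of reference datasets (default 50).
#' @param n_restarts K-means restarts per dataset and k (default 10).
#' @param seed Seed for references and K-means restarts.
#' @param distance Passed to [kmeans_correlation()].
#' @return A list: `table` (tibble `k`, `log_wss`, `gap`, `se`), `k` (the
#'   chosen value).
#' @export
gap_statistic <- function(x, k_range = 1:8, B = 50L, n_restarts = 10L,
                          seed = 1L, distance = c("pearson", "euclidean")) {
  distance <- match.arg(distance)
  if (length(k_range) < 1L) abort("`k_range` must not be empty.")
  X <- as_feature_matrix(x)
  if (nrow(X) < 2L) abort("need at least two samples.")
  check_number(B, "B", min = 2)
  k_range <- sort(unique(as.integer(k_range)))
  Z <- if (distance == "pearson") row_standardize(X) else X
  log_w_obs <- vapply(k_range, function(k) {
    log(max(kmeans_best(Z, k, n_restarts, seed = derive_seed(seed, 7000L + k),
                        distance = distance)$wss,
            .Machine$double.xmin))
  }, numeric(1))
  rng <- apply(Z, 2, range)
  log_w_ref <- with_rng(derive_seed(seed, 9001L), {
    vapply(seq_len(B), function(b) {
      ref <- matrix(runif(nrow(Z) * ncol(Z), rng[1, ], rng[2, ]),
                    nrow(Z), ncol(Z), byrow = TRUE)
      rownames(ref) <- rownames(Z)
      vapply(k_range, function(k) {
        log(max(kmeans_best(ref, k, n_restarts,
                            seed = derive_seed(seed, 100L * b + k),
                            distance = distance)$wss,
                .Machine$double.xmin))
      }, numeric(1))
    }, numeric(length(k_range)))
  })
  log_w_ref <- matrix(log_w_ref, nrow = length(k_range))
  gap <- rowMeans(log_w_ref) - log_w_obs
  se <- apply(log_w_ref, 1, sd) * sqrt(1 + 1 / B)
  chosen <- NA_integer_
  if (length(k_range) > 1L) {
    for (i in seq_len(length(k_range) - 1L)) {
      if (gap[i] >= gap[i + 1L] - se[i + 1L]) {
        chosen <- k_range[i]
        break
      }
    }
  }
  if (is.na(chosen)) chosen <- k_range[which.max(gap)]
  list(table = tibble(k = k_range, log_wss = log_w_obs, gap = gap, se = se),
       k = chosen)
}

#' Elbow choice from a WSS curve
#'
#' Picks the k whose point (k, WSS_k) lies farthest (perpendicular
#' distance) from the chord joining the first and last points of the
#' curve; ties go to the smallest k.
#'
#' @param wss Numeric vector of within-cluster dispersions.
#' @param k_range Integer vector of the same length (defaults to
#'   `seq_along(wss)`).
#' @return The chosen k.
#' @examples
#' elbow_k(c(100, 20, 18, 17), 1:4)  # 2
#' @export
elbow_k <- function(wss, k_range = seq_along(wss)) {
  if (length(wss) < 3L) abort("elbow selection needs at least three points.")
  if (length(wss) != length(k_range)) abort("`wss` and `k_range` lengths differ.")
  x1 <- k_range[1L]; y1 <- wss[1L]
  x2 <- k_range[length(k_range)]; y2 <- wss[length(wss)]
  num <- abs((y2 - y1) * k_range - (x2 - x1) * wss + x2 * y1 - y2 * x1)
  den <- sqrt((y2 - y1)^2 + (x2 - x1)^2)
  d <- num / den
  k_range[which.max(d)]          # which.max takes the first (smallest k) on ties
}

#' Silhouette widths
#'
#' Per-sample silhouette `s(i) = (b(i) - a(i)) / max(a(i), b(i))`, where
#' `a(i)` is the mean distance to the other members of i's cluster and
#' `b(i)` the smallest mean distance to any other cluster. Members of
#' singleton clusters get `s(i) = 0`.
#'
#' @param x A distance matrix (symmetric, zero diagonal) or
#'   samples-by-features data, in which case the correlation distance
#'   [pearson_distance()] is used.
#' @param labels Cluster labels (named vector, labels tibble, or
#'   `metabo_clusters`).
#' @return A tibble (`sample_id`, `cluster`, `width`) with the mean width
#'   in the `"mean_width"` attribute.
#' @export
silhouette_widths <- function(x, labels) {
  lab <- cluster_labels(labels)
  if (is.matrix(x) && nrow(x) == ncol(x) &&
      isTRUE(all.equal(unname(diag(x)), rep(0, nrow(x))))) {
    d <- x
  } else {
    d <- pearson_distance(x)
  }
  if (!is.null(rownames(d)) && all(names(lab) %in% rownames(d))) {
    d <- d[names(lab), names(lab)]
  } else if (nrow(d) != length(lab)) {
    abort("labels do not match the distance matrix.")
  }
  ks <- sort(unique(lab))
  if (length(ks) < 2L) abort("silhouettes need at least two clusters.")
  n <- length(lab)
  sizes <- table(factor(lab, ks))
  # mean distance from each sample to each cluster, vectorized as d %*% indicator
  ind <- outer(lab, ks, "==") * 1
  sums <- d %*% ind
  a <- numeric(n); b <- numeric(n)
  for (i in seq_len(n)) {
    ci <- match(lab[i], ks)
    if (sizes[ci] == 1L) { a[i] <- 0; b[i] <- 0; next }
    a[i] <- sums[i, ci] / (sizes[ci] - 1L)
    b[i] <- min(sums[i, -ci] / as.numeric(sizes[-ci]))
  }
  s <- as.vector(ifelse(sizes[match(lab, ks)] == 1L, 0,
                        ifelse(pmax(a, b) == 0, 0, (b - a) / pmax(a, b))))
  out <- tibble(sample_id = names(lab), cluster = unname(lab), width = s)
  attr(out, "mean_width") <- mean(s)
  out
}

#' Per-k clustering diagnostics and cluster-number selection
#'
#' Computes, for every candidate k, the within-cluster dispersion of the
#' best of `n_restarts` correlation K-means runs, the gap statistic with
#' its simulation error, and the mean silhouette width of the best run's
#' labels; then records the k chosen by each heuristic. k = 1 is always
#' probed for the WSS/gap curves even when `k_range` starts at 2.
#'
#' @param x Samples-by-features data.
#' @param k_range Candidate numbers of clusters (default 2:8).
#' @param B Gap reference datasets (default 50).
#' @param n_restarts K-means restarts per k (default 10).
#' @param seed Seed for every stochastic step.
#' @return A `metabo_kdiag` list: `table` (per-k tibble with `wss`, `gap`,
#'   `gap_se`, `silhouette`) and `chosen` (list with `gap`, `elbow`,
#'   `silhouette`, `combined`).
#' @export
cluster_diagnostics <- function(x, k_range = 2:8, B = 50L, n_restarts = 10L,
                                seed = 1L) {
  X <- as_feature_matrix(x)
  k_all <- sort(unique(c(1L, as.integer(k_range))))
  fits <- lapply(k_all, function(k) {
    kmeans_best(X, k, n_restarts, seed = derive_seed(seed, 500L + k))
  })
  wss <- vapply(fits, `[[`, numeric(1), "wss")
  d <- pearson_distance(X)
  sil <- vapply(seq_along(k_all), function(i) {
    if (k_all[i] < 2L) return(NA_real_)
    attr(silhouette_widths(d, fits[[i]]$labels), "mean_width")
  }, numeric(1))
  gap <- gap_statistic(X, k_range = k_all, B = B, n_restarts = n_restarts,
                       seed = seed)
  sil_k <- k_all[which.max(replace(sil, is.na(sil), -Inf))]
  chosen <- list(gap = gap$k,
                 elbow = elbow_k(wss, k_all),
                 silhouette = sil_k)
  chosen$combined <- combine_k_choices(chosen$gap, chosen$elbow, chosen$silhouette)
  gap_vals <- gap$table$gap
  gap_ses <- gap$table$se
  structure(list(table = tibble(k = k_all, wss = wss,
                                gap = gap_vals, gap_se = gap_ses,
                                silhouette = sil),
                 chosen = chosen),
            class = "metabo_kdiag")
}

#' Combine the three cluster-number heuristics
#'
#' Majority vote among the gap, elbow and silhouette choices; when all
#' three disagree, the silhouette's choice wins.
#'
#' @param gap_k,elbow_k,silhouette_k Integer choices of the heuristics.
#' @return The combined k.
#' @examples
#' combine_k_choices(5, 5, 4)  # 5
#' combine_k_choices(3, 4, 5)  # 5 (three-way tie -> silhouette)
#' @export
combine_k_choices <- function(gap_k, elbow_k, silhouette_k) {
  votes <- c(gap_k, elbow_k, silhouette_k)
  tab <- table(votes)
  if (max(tab) >= 2L) as.integer(names(tab)[which.max(tab)]) else silhouette_k
}

#' @export
print.metabo_kdiag <- function(x, ...) {
  cat("Cluster-number diagnostics\n")
  print(as.data.frame(x$table), row.names = FALSE, digits = 4)
  cat(sprintf("chosen k: gap = %d, elbow = %d, silhouette = %d -> combined = %d\n",
              x$chosen$gap, x$chosen$elbow, x$chosen$silhouette,
              x$chosen$combined))
  invisible(x)
}

#' @export
#' @method tidy metabo_kdiag
tidy.metabo_kdiag <- function(x, ...) x$table

#' @export
#' @method glance metabo_kdiag
glance.metabo_kdiag <- function(x, ...) {
  tibble(gap_k = x$chosen$gap, elbow_k = x$chosen$elbow,
         silhouette_k = x$chosen$silhouette, combined_k = x$chosen$combined)
}

#' Cluster cell lines end to end
#'
#' Convenience wrapper: computes the per-k diagnostics (unless `k` is
#' fixed), selects the number of clusters by the combined heuristic, and
#' runs the consensus clustering at that k.
#'
#' @param x Samples-by-features data (typically the scaled ratio matrix).
#' @param k `"auto"` (default) or a fixed integer.
#' @param k_range,B,n_restarts Passed to [cluster_diagnostics()].
#' @param n_reps Consensus repetitions (default 1000).
#' @param seed Seed for all stochastic steps.
#' @return A `metabo_clusters` object with diagnostics attached.
#' @export
cluster_cells <- function(x, k = "auto", k_range = 2:8, n_reps = 1000L,
                          B = 50L, n_restarts = 10L, seed = 1L) {
  diag_ <- cluster_diagnostics(x, k_range = k_range, B = B,
                               n_restarts = n_restarts, seed = seed)
  k_use <- if (identical(k, "auto")) diag_$chosen$combined else as.integer(k)
  consensus_cluster(x, k = k_use, n_reps = n_reps, seed = seed,
                    diagnostics = diag_)
}
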