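#' Unpaired two-sample Student's t-test
#'
#' Equal-variance (pooled) unpaired t-test with `df = n_a + n_b - 2` and a
#' two-sided p-value, the test used for cluster contrasts. When both
#' groups are constant and equal the statistic is defined as 0 with p = 1.
#' Welch's unequal-variance variant is available via `welch = TRUE`.
#'
#' @param a,b Numeric vectors with at least two values each.
#' @param welch Use Welch's t instead of the pooled form (default `FALSE`).
#' @return A list with elements `t`, `df`, `p`.
#' @examples
#' student_t(c(1, 2, 3), c(2, 3, 4))  # t = -1.2247, df = 4
#' @export
student_t <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L) {
    abort("both groups need at least two values.")
  }
  if (anyNA(a) || anyNA(b)) abort("missing values in the groups.")
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2L, p = 1))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2L, p = 0))
  }
  fit <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = unname(fit$p.value))
}

#' Benjamini-Krieger-Yekutieli two-stage FDR control
#'
#' The adaptive two-stage linear step-up procedure: stage 1 runs
#' Benjamini-Hochberg at the deflated level `q' = q_star / (1 + q_star)`
#' and counts `r1` rejections, giving the estimate `m0 = m - r1` of the
#' number of true nulls; stage 2 re-runs the linear step-up with the
#' threshold slope inflated by `m / m0`. If stage 1 rejects nothing
#' (or everything) the procedure stops there. Reported `q` values are
#' step-up adjusted so that `reject <=> q <= q_star`; like the procedure
#' itself they depend on `q_star`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param q_star Target FDR level (default 0.05).
#' @return A tibble in input order: `p`, `q`, `reject`.
#' @examples
#' bky_fdr(c(0.001, 0.01, 0.02, 0.8))  # rejects the first three
#' @export
bky_fdr <- function(p, q_star = 0.05) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    abort("`p` must be numeric in [0, 1].")
  }
  check_number(q_star, "q_star", min = 0)
  m <- length(p)
  q_prime <- q_star / (1 + q_star)
  ord <- order(p)
  ps <- p[ord]
  # BH step-up adjustment at unit scale: min_{j >= i} p_(j) * m / j
  bh_adjust <- function(ps, m_eff) {
    pmin(1, rev(cummin(rev(ps * m_eff / seq_along(ps)))))
  }
  q1 <- bh_adjust(ps, m)
  r1 <- sum(q1 <= q_prime)
  if (r1 == 0L || r1 == m) {
    # short-circuit: reject none / all; scale stage-1 q to the q_star scale
    q_sorted <- pmin(1, q1 * (1 + q_star))
  } else {
    m0 <- m - r1
    q_sorted <- pmin(1, bh_adjust(ps, m0) * (1 + q_star))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  tibble(p = p, q = q, reject = q <= q_star)
}

#' Feature-wise contrast of two clusters
#'
#' Runs an unpaired Student's t-test per feature between the members of
#' clusters `a` and `b` and controls the FDR across all tested features
#' jointly with [bky_fdr()] (the family is one contrast's worth of
#' features). Features constant in both clusters are reported with t = 0,
#' p = 1 rather than dropped.
#'
#' @param x Samples-by-features data (unscaled ratio matrix for
#'   interpretable means, or any feature tibble/matrix).
#' @param labels Cluster labels (named vector, tibble, or
#'   `metabo_clusters`).
#' @param a,b Cluster ids to contrast (difference is mean A minus mean B).
#' @param q_star FDR level (default 0.05).
#' @param welch Use Welch's t (default `FALSE`).
#' @return A `metabo_contrast` tibble: `feature`, `mean_a`, `mean_b`,
#'   `diff`, `t`, `df`, `p`, `q`, `reject`.
#' @export
contrast_clusters <- function(x, labels, a, b, q_star = 0.05, welch = FALSE) {
  X <- as_feature_matrix(x)
  lab <- cluster_labels(labels)
  common <- intersect(rownames(X), names(lab))
  lab <- lab[common]
  ia <- common[lab == a]
  ib <- common[lab == b]
  if (length(ia) < 2L || length(ib) < 2L) {
    abort(sprintf("clusters %s and %s need at least two members each (have %d and %d).",
                  a, b, length(ia), length(ib)))
  }
  res <- purrr::map(colnames(X), function(f) {
    va <- X[ia, f]; vb <- X[ib, f]
    tt <- student_t(va, vb, welch = welch)
    tibble(feature = f, mean_a = mean(va), mean_b = mean(vb),
           diff = mean(va) - mean(vb), t = tt$t, df = tt$df, p = tt$p)
  })
  out <- dplyr::bind_rows(res)
  adj <- bky_fdr(out$p, q_star = q_star)
  out$q <- adj$q
  out$reject <- adj$reject
  attr(out, "clusters") <- c(a = a, b = b)
  attr(out, "q_star") <- q_star
  class(out) <- unique(c("metabo_contrast", class(out)))
  out
}

#' @export
#' @method tidy metabo_contrast
tidy.metabo_contrast <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "metabo_contrast")
  as_tibble(out)
}

#' @export
#' @method glance metabo_contrast
glance.metabo_contrast <- function(x, ...) {
  tibble(n_features = nrow(x),
         n_rejected = sum(x$reject),
         q_star = attr(x, "q_star"))
}
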