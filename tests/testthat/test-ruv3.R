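toy_meta <- function(groups, ids = paste0("s", seq_along(groups))) {
  tibble::tibble(sample_id = ids, cell_line = groups, batch = 1,
                 replicate_group = groups)
}

test_that("replicate design matrices follow sample and group order", {
  meta <- toy_meta(c("A", "A", "B", "B"))
  des <- build_replicate_design(meta, meta$sample_id)
  expect_equal(unname(des$M), matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 4, 2))
  expect_equal(des$groups, c("A", "B"))

  meta2 <- toy_meta(c("a", "b", "c"))
  des2 <- build_replicate_design(meta2, meta2$sample_id)
  expect_equal(unname(des2$M), diag(3))

  expect_error(build_replicate_design(meta, character(0)), "at least one")
  expect_error(build_replicate_design(meta, c("s1", "nope")), "nope")
})

test_that("k = 0 is the identity and k out of range errors", {
  panel <- generate_panel(small_cfg(seed = 2))
  logged <- log10_transform(panel$abundance)
  des <- build_replicate_design(panel$metadata, logged$sample_id)
  ruv0 <- ruv3_correct(logged, des, k = 0)
  expect_identical(ruv0$corrected, logged)

  n <- nrow(logged); g <- length(des$groups)
  expect_error(ruv3_correct(logged, des, k = n - g + 1), "exceeds")
  expect_error(ruv3_correct(logged, des, controls = c("glucose", "pyruvate"),
                            k = 3), "control features")
})

test_that("a constructed batch shift on replicated samples is removed", {
  # same four profiles measured twice; batch 2 shifted by a constant vector
  set.seed(8)
  base <- matrix(rnorm(4 * 10), 4, 10)
  shift <- rnorm(10, 2, 0.5)
  Y <- rbind(base, sweep(base, 2, shift, "+"))
  colnames(Y) <- paste0("m", 1:10)
  rownames(Y) <- paste0("s", 1:8)
  y <- toy_log_abundance(Y)
  meta <- toy_meta(rep(paste0("cl", 1:4), 2), ids = rownames(Y))
  des <- build_replicate_design(meta, rownames(Y))
  ruv <- ruv3_correct(y, des, controls = "all", k = 1)
  M <- as.matrix(ruv$corrected[-1])
  expect_lt(max(abs(M[1:4, ] - M[5:8, ])), 1e-8)
})

test_that("correction is equivariant under sample permutation", {
  panel <- generate_panel(small_cfg(seed = 4))
  logged <- log10_transform(panel$abundance)
  des <- build_replicate_design(panel$metadata, logged$sample_id)
  ruv <- ruv3_correct(logged, des, k = 5)

  perm <- sample(seq_len(nrow(logged)))
  logged_p <- as_abundance(as.data.frame(logged)[perm, ], scale = "log10")
  des_p <- build_replicate_design(panel$metadata, logged_p$sample_id)
  ruv_p <- ruv3_correct(logged_p, des_p, k = 5)
  a <- as.matrix(ruv$corrected[-1])
  rownames(a) <- ruv$corrected$sample_id
  b <- as.matrix(ruv_p$corrected[-1])
  rownames(b) <- ruv_p$corrected$sample_id
  expect_equal(b[rownames(a), ], a, tolerance = 1e-8)
})

test_that("correction never inflates within-replicate distances on batchy panels", {
  for (seed in 1:20) {
    panel <- generate_panel(small_cfg(seed = seed))
    logged <- log10_transform(panel$abundance)
    des <- build_replicate_design(panel$metadata, logged$sample_id)
    ruv <- ruv3_correct(logged, des, k = 4)
    mean_rep_dist <- function(tbl) {
      M <- as.matrix(tbl[-1])
      rownames(M) <- tbl$sample_id
      grp <- split(tbl$sample_id,
                   panel$metadata$replicate_group[
                     match(tbl$sample_id, panel$metadata$sample_id)])
      mean(vapply(grp, function(ids) {
        mean(stats::dist(M[ids, , drop = FALSE]))
      }, numeric(1)))
    }
    expect_lte(mean_rep_dist(ruv$corrected), mean_rep_dist(logged))
  }
})

test_that("replicate cohesion gate flags split replicate groups", {
  panel <- generate_panel(small_cfg(seed = 6))
  logged <- log10_transform(panel$abundance)
  des <- build_replicate_design(panel$metadata, logged$sample_id)
  ruv <- ruv3_correct(logged, des, k = 4)
  report <- replicate_cohesion(ruv$corrected, panel$metadata, k = 3, seed = 1)
  expect_true(all(report$coherent))

  # uncorrected, strongly batched data should split at least one group
  cfg_bad <- small_cfg(seed = 6, batch_effect_sd = 1.2)
  panel_bad <- generate_panel(cfg_bad)
  logged_bad <- log10_transform(panel_bad$abundance)
  expect_warning(replicate_cohesion(logged_bad, panel_bad$metadata,
                                    k = 3, seed = 1),
                 "split")
})
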