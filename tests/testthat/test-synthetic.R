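test_that("the generator is deterministic and structurally consistent", {
  p1 <- generate_panel(small_cfg(seed = 42))
  p2 <- generate_panel(small_cfg(seed = 42))
  expect_identical(p1$abundance, p2$abundance)
  expect_identical(p1$metadata, p2$metadata)
  expect_identical(p1$truth$cell_lines, p2$truth$cell_lines)

  cfg <- small_cfg(seed = 42)
  n_cells <- cfg$n_clusters * cfg$cell_lines_per_cluster
  expect_equal(nrow(p1$truth$cell_lines), n_cells)
  # anchors appear in every batch, others in exactly one
  per_cell <- dplyr::summarise(dplyr::group_by(p1$metadata, cell_line),
                               n_batches = dplyr::n_distinct(batch),
                               anchor = unique(is_anchor))
  expect_true(all(per_cell$n_batches[per_cell$anchor] == cfg$n_batches))
  expect_true(all(per_cell$n_batches[!per_cell$anchor] == 1))
  # replicate group ties all samples of a cell line together
  expect_equal(p1$metadata$replicate_group, p1$metadata$cell_line)
  expect_true(all(as.matrix(p1$abundance[-1]) > 0))
})

test_that("a null configuration plants no between-cluster ratio signal", {
  cfg <- small_cfg(seed = 9, delta_magnitude = 0, batch_effect_sd = 0,
                   sample_scaling_sd = 0)
  panel <- generate_panel(cfg)
  res <- run_ratio_pipeline(panel, ruv_k = 0)
  truth <- panel$truth$cell_lines
  vals <- as.matrix(res$ratios[-1])
  cl <- truth$cluster[match(res$ratios$sample_id, truth$cell_line)]
  tstats <- apply(vals, 2, function(v) student_t(v[cl == 1], v[cl == 2])$t)
  # no feature should show a large standardized difference
  expect_lt(max(abs(tstats)), 6)
  expect_gt(mean(abs(tstats) < 2.5), 0.9)
})

test_that("planted ratio differences match the configured deltas", {
  cfg <- synthetic_config(seed = 5)
  panel <- generate_panel(cfg)
  res <- run_ratio_pipeline(panel, ruv_k = 0)
  truth <- panel$truth$cell_lines
  cl <- truth$cluster[match(res$ratios$sample_id, truth$cell_line)]
  feat <- "succinate/pyruvate@tca_cycle"
  v <- res$ratios[[feat]]
  # clusters 4 (+0.5 on tca) and 3 (-0.5 on tca) differ by ~1 in log10 units
  planted <- cfg$delta["cluster_4", "tca_cycle"] -
    cfg$delta["cluster_3", "tca_cycle"]
  observed <- mean(v[cl == 4]) - mean(v[cl == 3])
  se <- 3 * cfg$technical_noise_sd / sqrt(sum(cl == 4))
  expect_lt(abs(observed - planted), 3 * se + 0.05)
})

test_that("per-sample scaling cancels out of the ratio matrix", {
  cfg0 <- small_cfg(seed = 3, sample_scaling_sd = 0)
  cfg1 <- small_cfg(seed = 3, sample_scaling_sd = 0.6)
  r0 <- run_ratio_pipeline(generate_panel(cfg0), ruv_k = 0)$ratios
  r1 <- run_ratio_pipeline(generate_panel(cfg1), ruv_k = 0)$ratios
  expect_equal(as.matrix(r0[-1]), as.matrix(r1[-1]), tolerance = 1e-8)
})

test_that("uncorrected samples cluster by batch more than by planted cluster", {
  cfg <- synthetic_config(seed = 21)
  panel <- generate_panel(cfg)
  logged <- log10_transform(panel$abundance)
  fit <- consensus_cluster(logged, k = cfg$n_batches, n_reps = 30, seed = 2)
  lab <- cluster_labels(fit)
  meta <- panel$metadata
  batch <- meta$batch[match(names(lab), meta$sample_id)]
  truth <- panel$truth$cell_lines
  cl <- truth$cluster[match(meta$cell_line[match(names(lab), meta$sample_id)],
                            truth$cell_line)]
  expect_gt(adjusted_rand_index(lab, batch), adjusted_rand_index(lab, cl))
})

test_that("synthetic screens carry the planted vulnerabilities", {
  cfg <- small_cfg(seed = 13)
  panel <- generate_panel(cfg)
  scr <- generate_screens(panel$truth, n_targets_per_pathway = 5,
                          effect = -1, noise_sd = 0.1, seed = 99)
  expect_setequal(names(scr$screens),
                  c("DEMETER", "ProjectScore", "PRISM", "GDSC2"))
  scr2 <- generate_screens(panel$truth, n_targets_per_pathway = 5,
                           effect = -1, noise_sd = 0.1, seed = 99)
  expect_identical(scr$screens$DEMETER, scr2$screens$DEMETER)

  # null effect: per-target cluster-mean differences center on zero
  null_scr <- generate_screens(panel$truth, n_targets_per_pathway = 5,
                               effect = 0, noise_sd = 0.1,
                               databases = "DEMETER", seed = 7)
  db <- null_scr$screens$DEMETER
  truth <- panel$truth$cell_lines
  cl <- truth$cluster[match(db$cell_line, truth$cell_line)]
  diffs <- vapply(split(seq_len(nrow(db)), db$target), function(i) {
    mean(db$score[i][cl[i] == 1]) - mean(db$score[i][cl[i] == 2])
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.1)

  # strong effect: every vulnerable-pathway target leads the differential rank
  labels <- setNames(truth$cluster, truth$cell_line)
  filt <- join_screens(scr$screens$DEMETER, labels, scr$pathway_map)
  dt <- differential_response(filt, labels, a = 1, b = 2,
                              pathway_map = scr$pathway_map)
  planted <- panel$truth$vulnerable_pathways$pathway[
    panel$truth$vulnerable_pathways$cluster == 1]
  planted_targets <- scr$pathway_map$target[
    scr$pathway_map$kegg_pathway %in% planted]
  expect_true(all(dt$rank[dt$target %in% planted_targets] <=
                    length(planted_targets)))

  expect_error(generate_screens(panel$truth, databases = character(0)),
               "at least one")
})
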