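mk_screen <- function(df, dir = "lower_is_more_sensitive") {
  as_screen_table(df, score_direction = dir)
}

test_that("screen filtering keeps labeled cells and mapped targets", {
  scr <- mk_screen(tibble::tibble(
    cell_line = rep(c("c1", "c2", "c3", "c4", "c5"), each = 2),
    target = rep(c("t1", "t2"), 5),
    score = rnorm(10),
    database = "DEMETER"))
  labels <- setNames(c(1L, 1L, 2L), c("c1", "c2", "c3"))
  map <- tibble::tibble(target = "t1", kegg_pathway = "oxphos")
  filt <- join_screens(scr, labels, map)
  expect_setequal(unique(filt$cell_line), c("c1", "c2", "c3"))
  expect_equal(unique(filt$target), "t1")
  counts <- attr(filt, "filter_counts")
  expect_equal(unname(counts["retained"]), 3)
  expect_equal(unname(counts["dropped_unmapped_target"]), 3)

  other <- setNames(1L, "nope")
  expect_error(join_screens(scr, other, map), "overlap")
})

test_that("differential z-scores follow the hand example and invariances", {
  scr <- mk_screen(tibble::tibble(
    cell_line = c("a1", "a2", "b1", "b2"),
    target = "t1",
    score = c(-2, -2, 0, 0),
    database = "DEMETER"))
  labels <- setNames(c(1L, 1L, 2L, 2L), c("a1", "a2", "b1", "b2"))
  dt <- differential_response(scr, labels, a = 1, b = 2)
  expect_equal(dt$mean_z_a, -0.866, tolerance = 1e-3)
  expect_equal(dt$differential, -1.732, tolerance = 1e-3)

  # anti-symmetry under cluster swap is exact
  dt_swap <- differential_response(scr, labels, a = 2, b = 1)
  expect_identical(dt$differential, -dt_swap$differential)

  # adding a constant to a target's scores leaves its differential unchanged
  scr2 <- mk_screen(dplyr::mutate(tibble::as_tibble(scr), score = score + 57))
  dt2 <- differential_response(scr2, labels, a = 1, b = 2)
  expect_equal(dt2$differential, dt$differential, tolerance = 1e-12)

  # identical scores in both clusters: zero variance -> excluded
  flat <- mk_screen(tibble::tibble(
    cell_line = c("a1", "a2", "b1", "b2"), target = "t1",
    score = rep(1, 4), database = "DEMETER"))
  expect_error(suppressWarnings(differential_response(flat, labels, 1, 2)),
               "no target")
})

test_that("top lists rank deterministically with lexicographic ties", {
  dt <- tibble::tibble(
    database = "DEMETER",
    target = c("zeta", "alpha", "mid"),
    pathways = NA_character_,
    n_a = 2, n_b = 2, mean_z_a = 0, mean_z_b = 0,
    differential = c(-1, -1, 0))
  dt <- dt[order(dt$differential, dt$target), ]
  dt$rank <- seq_len(nrow(dt))
  class(dt) <- unique(c("metabo_screen_diff", class(dt)))
  top <- top_n_targets(dt, 2)
  expect_equal(top$target, c("alpha", "zeta"))
  expect_equal(nrow(top_n_targets(dt, 100)), 3)
  expect_equal(top_n_targets(dt, 1)$target, "alpha")
  expect_error(top_n_targets(dt, 0), "n")
})

test_that("pathway consolidation counts top-list membership per database", {
  map <- tibble::tibble(target = paste0("t", 1:40),
                        kegg_pathway = rep(c("oxphos", "gln"), each = 20))
  mk_top <- function(db, targets) {
    out <- tibble::tibble(database = db, target = targets,
                          pathways = NA_character_,
                          differential = seq_along(targets) * -1e-3)
    out$rank <- seq_len(nrow(out))
    class(out) <- unique(c("metabo_screen_diff", class(out)))
    out
  }
  # one database, all 20 targets in oxphos -> score 1, rank 1
  sc1 <- consolidate_pathways(mk_top("d1", paste0("t", 1:20)), map, n = 20)
  expect_equal(sc1$score[sc1$kegg_pathway == "oxphos"], 1)
  expect_equal(sc1$rank[sc1$kegg_pathway == "oxphos"], 1)

  # two databases with 10 oxphos targets each -> 10/20 + 10/20 = 1
  two <- dplyr::bind_rows(mk_top("d1", paste0("t", c(1:10, 21:30))),
                          mk_top("d2", paste0("t", c(11:20, 31:40))))
  class(two) <- unique(c("metabo_screen_diff", class(two)))
  sc2 <- consolidate_pathways(two, map, n = 20)
  expect_equal(sc2$score[sc2$kegg_pathway == "oxphos"], 1)
  expect_equal(sc2$score[sc2$kegg_pathway == "gln"], 1)
  # tie broken alphabetically
  expect_equal(sc2$kegg_pathway, c("gln", "oxphos"))
})

test_that("strong planted effects put vulnerable targets on top of every list", {
  panel <- generate_panel(small_cfg(seed = 31))
  truth <- panel$truth
  labels <- setNames(truth$cell_lines$cluster, truth$cell_lines$cell_line)
  scr <- generate_screens(truth, n_targets_per_pathway = 20, effect = -1,
                          noise_sd = 0.1, seed = 5)
  planted <- truth$vulnerable_pathways$pathway[
    truth$vulnerable_pathways$cluster == 1]
  for (db in names(scr$screens)) {
    filt <- join_screens(scr$screens[[db]], labels, scr$pathway_map)
    dt <- differential_response(filt, labels, a = 1, b = 2,
                                pathway_map = scr$pathway_map)
    top <- top_n_targets(dt, 20)
    frac_planted <- mean(grepl(paste0("^", planted, "_"), top$target))
    expect_gte(frac_planted, 0.9)
  }
})
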