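test_that("abundance tables read in file order and round-trip exactly", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tglucose\tpyruvate",
               "s1\t1\t2", "s2\t3\t4", "s3\t5\t6"), path)
  abn <- read_abundance_table(path)
  expect_equal(abundance_scale(abn), "raw")
  expect_equal(abn$sample_id, c("s1", "s2", "s3"))
  expect_equal(abn$glucose, c(1, 3, 5))
  expect_equal(abn$pyruvate, c(2, 4, 6))

  # transposed layout reads to the same matrix
  tpath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("metabolite\ts1\ts2\ts3",
               "glucose\t1\t3\t5", "pyruvate\t2\t4\t6"), tpath)
  abn_t <- read_abundance_table(tpath, orientation = "metabolites_in_rows")
  expect_equal(as.data.frame(abn_t), as.data.frame(abn))

  # bit-identical write/read round trip for finite decimals
  out <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_table(abn, out)
  expect_identical(as.data.frame(read_abundance_table(out)),
                   as.data.frame(abn))
})

test_that("malformed abundance files are rejected with informative errors", {
  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tglucose\tglucose", "s1\t1\t2"), dup)
  expect_error(read_abundance_table(dup), "glucose")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,glucose", "s1,1", "s2,oops"), bad)
  expect_error(read_abundance_table(bad), "s2.*glucose")
})

test_that("log10 transform applies the half-minimum LOD rule", {
  abn <- as_abundance(tibble::tibble(
    sample_id = c("a", "b", "c"),
    met = c(10, 1000, 0)
  ), scale = "raw")
  expect_error(log10_transform(abn), "impute_lod")
  logged <- log10_transform(abn, impute_lod = TRUE)
  expect_equal(logged$met, c(1, 3, log10(5)), tolerance = 1e-12)
  expect_equal(abundance_scale(logged), "log10")

  clean <- as_abundance(tibble::tibble(sample_id = "a", met = 100), "raw")
  expect_equal(log10_transform(clean)$met, 2)
})

test_that("percent RSD follows the n-1 formula and is scale invariant", {
  abn <- as_abundance(tibble::tibble(
    sample_id = c("a", "b", "c"),
    pyruvate = c(1, 2, 3),
    flat = c(5, 5, 5)
  ), scale = "raw")
  expect_equal(compute_rsd(abn, c("a", "b", "c"), "pyruvate"), 50)
  expect_equal(compute_rsd(abn, c("a", "b", "c"), "flat"), 0)
  expect_error(compute_rsd(abn, "a", "pyruvate"), "two samples")

  for (c_mult in c(0.01, 3, 1e4)) {
    scaled <- as_abundance(tibble::tibble(
      sample_id = c("a", "b", "c"),
      pyruvate = c(1, 2, 3) * c_mult
    ), scale = "raw")
    expect_equal(compute_rsd(scaled, c("a", "b", "c"), "pyruvate"), 50,
                 tolerance = 1e-10)
  }
})

test_that("cross-dataset correlations use shared ids and flag zero variance", {
  a <- toy_log_abundance(cbind(m1 = c(1, 2, 3, 4), m2 = c(4, 1, 3, 2),
                               flat = c(1, 1, 1, 1)))
  r_self <- correlate_shared_metabolites(a, a)
  expect_equal(r_self$r[r_self$metabolite %in% c("m1", "m2")], c(1, 1))
  expect_true(is.na(r_self$r[r_self$metabolite == "flat"]))
  expect_false(r_self$defined[r_self$metabolite == "flat"])
  expect_equal(attr(r_self, "n_shared_samples"), 4)

  # negating one metabolite around its center flips that r to -1
  b <- a
  b$m2 <- mean(a$m2) - (a$m2 - mean(a$m2))
  r_neg <- correlate_shared_metabolites(a, b)
  expect_equal(r_neg$r[r_neg$metabolite == "m1"], 1)
  expect_equal(r_neg$r[r_neg$metabolite == "m2"], -1)

  # affine rescaling with positive slope leaves r unchanged
  b2 <- a
  b2$m1 <- 3.7 * a$m1 + 11
  expect_equal(correlate_shared_metabolites(a, b2)$r[1], 1, tolerance = 1e-12)

  few <- toy_log_abundance(cbind(m1 = c(1, 2)), mets = "m1")
  expect_error(correlate_shared_metabolites(a, few), "shared samples")
})

test_that("pathway sets enforce the precursor and duplication rules", {
  ok <- as_pathway_set(tibble::tibble(
    pathway = c("tca", "tca", "gly"),
    precursor = c("pyruvate", "pyruvate", "glucose"),
    member = c("citrate", "malate", "pyruvate")
  ))
  expect_equal(nrow(ok), 3)

  expect_error(as_pathway_set(tibble::tibble(
    pathway = "tca", precursor = "pyruvate", member = "pyruvate"
  )), "own members")
  expect_error(as_pathway_set(tibble::tibble(
    pathway = c("tca", "tca"), precursor = c("pyruvate", "pyruvate"),
    member = c("malate", "malate")
  )), "duplicated")

  shipped <- read_pathways(system.file("extdata", "pathways_example.tsv",
                                       package = "metaboratio"))
  expect_setequal(unique(shipped$pathway),
                  c("glycolysis", "pentose_phosphate", "tca_cycle",
                    "proline_metabolism", "serine_metabolism",
                    "glutamine_metabolism", "methionine_metabolism"))
})
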