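test_that("expression shares are plain accumulated-RPKM arithmetic", {
  one <- expression_share(tibble::tibble(group = "a", rpkm = c(1, 2)))
  expect_equal(one$share_pct, 100)
  two <- expression_share(tibble::tibble(group = c("a", "a", "b"),
                                         rpkm = c(50, 25, 25)))
  expect_equal(two$share_pct[two$group == "a"], 75)
  expect_equal(two$share_pct[two$group == "b"], 25)
  expect_warning(res <- expression_share(tibble::tibble(group = "a", rpkm = 0)))
  expect_equal(nrow(res), 0)
})

test_that("shares sum to 100 over random partitions", {
  withr::local_seed(13)
  for (i in 1:100) {
    n <- sample(5:80, 1)
    x <- tibble::tibble(group = sample(letters[1:sample(2:6, 1)], n, TRUE),
                        rpkm = rlnorm(n, 3, 2))
    expect_equal(sum(expression_share(x)$share_pct), 100, tolerance = 1e-6)
  }
})

test_that("the family table counts secreted proteins and marks species", {
  ann <- tibble::tibble(
    protein_id = c("p1", "p2", "p3"),
    description = c("Trypsin", "Trypsin", "Annexin"),
    signal_peptide = TRUE, signal_peptide_after_cds_repair = TRUE,
    domain_ids = c("Tryp_SPc", "", ""))
  profiles <- dplyr::bind_rows(
    make_profile("p1", signal_peptide = TRUE),
    make_profile("p2", signal_peptide = TRUE),
    make_profile("p3", signal_peptide = TRUE))
  res <- classify_sfps(profiles)
  marks <- cross_species_marks(ann, tibble::tibble(species = "DMEL",
                                                   domain_id = "Tryp_SPc"),
                               tibble::tibble(query_id = character(),
                                              subject_id = character(),
                                              subject_species = character(),
                                              evalue = numeric(),
                                              tool = character(),
                                              identity_pct = numeric()))
  tbl <- family_species_table(res, ann, marks)
  expect_equal(tbl$n[tbl$gene == "Trypsin"], 2L)
  expect_equal(tbl$DMEL[tbl$gene == "Trypsin"], "T")
  expect_equal(tbl$DMEL[tbl$gene == "Annexin"], "")
  lines <- render_family_table(tbl)
  expect_match(lines[grepl("Trypsin", lines)], "Trypsin \\(2\\)")
  # empty calls give a header-only render
  empty <- family_species_table(res$calls[0, ], ann, marks)
  expect_equal(length(render_family_table(empty)), 1)
})

test_that("the pipeline is deterministic and monotone in replicate_min", {
  ds <- generate_sfp_dataset(sfp_sim_params(
    n_per_class = c(SECRETED_SP = 5L, UNCONFIRMED_HOMOLOG = 5L,
                    NON_SFP_BACKGROUND = 5L), random_seed = 8L))
  dir <- withr::local_tempdir()
  write_sfp_dataset(ds, dir)
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  run_sfp_pipeline(dir, out1, quiet = TRUE)
  run_sfp_pipeline(dir, out2, quiet = TRUE)
  for (f in list.files(out1)) {
    expect_identical(readLines(file.path(out1, f)), readLines(file.path(out2, f)),
                     info = f)
  }
  expect_true(file.exists(file.path(out1, "calls.tsv")))
  # a stricter replicate rule can only lose detections
  res2 <- run_sfp_pipeline(dir, NULL, sfp_config(replicate_min = 2L), quiet = TRUE)
  res3 <- run_sfp_pipeline(dir, NULL, sfp_config(replicate_min = 3L), quiet = TRUE)
  expect_lte(glance(res3$result)$n_candidates, glance(res2$result)$n_candidates)
  expect_lte(glance(res3$result)$n_secreted, glance(res2$result)$n_secreted)
  # a missing table is fatal and names the file
  file.remove(file.path(dir, "homology.tsv"))
  expect_error(run_sfp_pipeline(dir, NULL, quiet = TRUE), "homology",
               class = "sfp_io_error")
})

test_that("plot constructors return ggplot objects", {
  res <- classify_sfps(dplyr::bind_rows(
    make_profile("p1", signal_peptide = TRUE), make_profile("p2")))
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
  expect_s3_class(plot_expression_share(class_expression_share(res)), "ggplot")
  expect_s3_class(plot_score_distributions(make_psms(c(9, 10), 5)), "ggplot")
})
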