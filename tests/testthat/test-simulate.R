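small_params <- function(...) {
  sfp_sim_params(n_per_class = c(SECRETED_SP = 6L, SECRETED_SP_IN_UNMATED = 3L,
                                 SECRETED_MALE_SPECIFIC = 3L,
                                 UNCONFIRMED_HOMOLOG = 8L, MAG_ONLY_SP = 2L,
                                 NON_SFP_BACKGROUND = 9L),
                 random_seed = 42L, ...)
}

run_on <- function(dataset, config = sfp_config()) {
  dir <- withr::local_tempdir()
  write_sfp_dataset(dataset, dir)
  run_sfp_pipeline(dir, output_dir = NULL, config = config, quiet = TRUE)
}

test_that("same parameters and seed give byte-identical dataset files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_sfp_dataset(generate_sfp_dataset(small_params()), d1)
  write_sfp_dataset(generate_sfp_dataset(small_params()), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("with zero dropout the classifier recovers every planted class", {
  ds <- generate_sfp_dataset(small_params())
  out <- run_on(ds)
  calls <- tidy(out$result)
  merged <- dplyr::inner_join(calls, ds$truth, by = "protein_id")
  expect_equal(nrow(merged), nrow(ds$truth))
  # diagonal confusion matrix: predicted class == planted expectation
  expect_equal(as.character(merged$sfp_class), merged$expected_class)
})

test_that("generated tables pass the io schema validation round-trip", {
  ds <- generate_sfp_dataset(small_params())
  dir <- withr::local_tempdir()
  write_sfp_dataset(ds, dir)
  inputs <- read_sfp_input_dir(dir) # readers validate every row
  expect_equal(nrow(inputs$psm), nrow(ds$psm))
  expect_equal(inputs$annotation, ds$annotation)
  expect_equal(inputs$expression$rpkm, ds$expression$rpkm)
})

test_that("planted secreted share of candidate MAG expression is honoured", {
  ds <- generate_sfp_dataset(small_params(secreted_share = 0.85))
  cand <- ds$truth$protein_id[ds$truth$planted_class %in%
                                c("SECRETED_SP", "SECRETED_SP_IN_UNMATED",
                                  "SECRETED_MALE_SPECIFIC", "UNCONFIRMED_HOMOLOG")]
  mag <- ds$expression[ds$expression$library == "MAG" &
                         ds$expression$gene_id %in% cand, ]
  sec <- ds$truth$protein_id[startsWith(ds$truth$planted_class, "SECRETED")]
  share <- sum(mag$rpkm[mag$gene_id %in% sec]) / sum(mag$rpkm)
  # integer read counts round the planted share a whisker off exactness
  expect_equal(share, 0.85, tolerance = 1e-3)
})

test_that("degradation is deterministic, monotone and the identity at zero", {
  ds <- generate_sfp_dataset(small_params())
  expect_identical(degrade_dataset(ds, 0, seed = 1L)$psm, ds$psm)
  expect_identical(degrade_dataset(ds, 0.2, seed = 5L)$psm,
                   degrade_dataset(ds, 0.2, seed = 5L)$psm)
  presence_cells <- function(d) {
    p <- d$psm[!d$psm$is_decoy, ]
    unique(paste(p$protein_id, p$tissue, p$replicate))
  }
  # at harsh dropout no candidate survives; the share step warns by design
  secreted_count <- function(d) suppressWarnings(glance(run_on(d)$result)$n_secreted)
  prev_cells <- presence_cells(ds)
  prev_secreted <- secreted_count(ds)
  for (p in c(0.1, 0.3, 0.6, 0.9)) {
    deg <- degrade_dataset(ds, p, seed = 99L)
    cells <- presence_cells(deg)
    expect_true(all(cells %in% prev_cells)) # coupled: presence only shrinks
    s <- secreted_count(deg)
    expect_lte(s, prev_secreted)
    prev_cells <- cells
    prev_secreted <- s
  }
  expect_error(degrade_dataset(ds, 1), class = "sfp_precondition_error")
})

test_that("parameter validation rejects malformed simulations", {
  expect_error(sfp_sim_params(replicate_dropout = 1),
               class = "sfp_precondition_error")
  expect_error(sfp_sim_params(n_per_class = c(BOGUS = 5L)),
               class = "sfp_precondition_error")
  expect_error(sfp_sim_params(n_per_class = c(SECRETED_SP = -1L)),
               class = "sfp_precondition_error")
})
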