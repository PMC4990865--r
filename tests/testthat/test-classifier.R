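test_that("candidate filter requires detection in both MAG and mated-FRT", {
  grid <- tidyr::expand_grid(detected_mag = c(TRUE, FALSE),
                             detected_mated = c(TRUE, FALSE))
  expect_equal(candidate_filter(grid), grid$detected_mag & grid$detected_mated)
})

test_that("the cascade matches an independent oracle over all 2^6 profiles", {
  grid <- tidyr::expand_grid(detected_mag = c(FALSE, TRUE),
                             detected_mated = c(FALSE, TRUE),
                             detected_unmated = c(FALSE, TRUE),
                             signal_peptide = c(FALSE, TRUE),
                             male_specific = c(FALSE, TRUE),
                             has_sfp_homolog = c(FALSE, TRUE)) |>
    dplyr::mutate(protein_id = sprintf("p%02d", dplyr::row_number()),
                  rpkm_mag = 1)
  calls <- tidy(classify_sfps(grid))
  want <- t(mapply(oracle_classify, grid$detected_mag, grid$detected_mated,
                   grid$detected_unmated, grid$signal_peptide,
                   grid$male_specific, grid$has_sfp_homolog))
  expect_equal(as.character(calls$sfp_class), want[, 1])
  expect_equal(as.character(calls$fired_criterion), want[, 2])
  # totality: every protein gets exactly one class
  expect_false(anyNA(calls$sfp_class))
  expect_equal(nrow(calls), 64)
})

test_that("worked examples of each rule classify as documented", {
  expect_call <- function(profile, class, criterion) {
    call <- tidy(classify_sfps(profile))
    expect_equal(as.character(call$sfp_class), class)
    expect_equal(as.character(call$fired_criterion), criterion)
  }
  # signal peptide wins even when the protein appears in unmated females
  expect_call(make_profile(detected_unmated = TRUE, signal_peptide = TRUE),
              "SECRETED", "SIGNAL_PEPTIDE")
  # no signal peptide: male-specific + absent from unmated females
  expect_call(make_profile(male_specific = TRUE),
              "SECRETED", "MALE_SPECIFIC_ABSENT_UNMATED")
  # homology to another insect's SFP set
  expect_call(make_profile(detected_unmated = TRUE, has_sfp_homolog = TRUE),
              "UNCONFIRMED", "HOMOLOG")
  # male-specific but seen in unmated females, no homolog: unclassified
  expect_call(make_profile(detected_unmated = TRUE, male_specific = TRUE),
              "CANDIDATE_UNCLASSIFIED", "NONE")
})

test_that("MAG-only signal-peptide proteins are flagged but never SECRETED", {
  profiles <- dplyr::bind_rows(
    make_profile("a", detected_mated = FALSE, signal_peptide = TRUE),
    make_profile("b", detected_mated = FALSE, signal_peptide = FALSE),
    make_profile("c", detected_mated = TRUE, signal_peptide = TRUE))
  res <- classify_sfps(profiles)
  mo <- mag_only_secreted(res)
  expect_equal(mo$protein_id, "a")
  expect_equal(as.character(tidy(res)$sfp_class), c("MAG_ONLY_SECRETED",
                                                    "NOT_SFP", "SECRETED"))
})

test_that("incomplete profiles are rejected", {
  expect_error(classify_sfps(make_profile(signal_peptide = NA)),
               class = "sfp_precondition_error")
  expect_error(classify_sfps(make_profile()[, 1:3]),
               class = "sfp_precondition_error")
})

test_that("summaries partition the calls and satisfy the secreted identity", {
  withr::local_seed(5)
  for (i in 1:20) {
    n <- 40
    profiles <- tibble::tibble(
      protein_id = sprintf("p%03d", 1:n),
      detected_mag = runif(n) < 0.8, detected_mated = runif(n) < 0.7,
      detected_unmated = runif(n) < 0.5, signal_peptide = runif(n) < 0.4,
      male_specific = runif(n) < 0.3, has_sfp_homolog = runif(n) < 0.5,
      rpkm_mag = rlnorm(n))
    res <- classify_sfps(profiles)
    expect_equal(sum(res$summary$n), n)
    g <- glance(res)
    expect_equal(g$n_secreted,
                 g$n_secreted_signal_peptide + g$n_secreted_male_specific)
    # flipping signal_peptide on never removes a candidate from SECRETED
    res_sp <- classify_sfps(dplyr::mutate(profiles, signal_peptide = TRUE))
    was <- tidy(res)$sfp_class == "SECRETED"
    now <- tidy(res_sp)$sfp_class == "SECRETED"
    expect_false(any(was & !now))
  }
  empty <- summarize_calls(tidy(classify_sfps(make_profile()[0, ])))
  expect_true(all(empty$n == 0))
})
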