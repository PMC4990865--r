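test_that("fdr_threshold handles the edge cases directly", {
  # no decoys: everything is kept at the lowest observed score
  res <- fdr_threshold(make_psms(c(10, 9, 8)), 0.01)
  expect_equal(res$score_cutoff, 8)
  expect_equal(res$n_targets_kept, 3L)
  expect_equal(res$achieved_fdr, 0)

  # a decoy outscoring the only target: nothing can pass
  res2 <- fdr_threshold(make_psms(5, 6), 0.01)
  expect_equal(res2$n_targets_kept, 0L)
  expect_equal(res2$score_cutoff, Inf)

  # one decoy at 150 among targets 1..200: the brute-force scan fixes the cutoff
  psms <- make_psms(1:200, 150)
  expect_equal(as.list(fdr_threshold(psms, 0.01)),
               oracle_fdr(psms$score, psms$is_decoy, 0.01))

  expect_error(fdr_threshold(make_psms(numeric(), 5), 0.01),
               class = "sfp_precondition_error")
  expect_error(fdr_threshold(make_psms(5), 1), class = "sfp_precondition_error")
})

test_that("fdr_threshold equals the exhaustive scan on random instances", {
  withr::local_seed(101)
  for (i in 1:1000) {
    nt <- sample(1:60, 1)
    nd <- sample(0:30, 1)
    tied <- runif(1) < 0.3 # tied scores stress the >= convention
    draw <- function(n, mean) {
      s <- rnorm(n, mean, 3)
      if (tied) round(s) else s
    }
    psms <- make_psms(draw(nt, 10), draw(nd, 7))
    alpha <- sample(c(0.01, 0.05, 0.2), 1)
    got <- fdr_threshold(psms, alpha)
    want <- oracle_fdr(psms$score, psms$is_decoy, alpha)
    expect_equal(as.list(got), want)
    expect_lte(got$achieved_fdr, alpha)
  }
})

test_that("lowering alpha never keeps more targets", {
  withr::local_seed(7)
  for (i in 1:50) {
    psms <- make_psms(rnorm(40, 10, 3), rnorm(15, 8, 3))
    kept <- vapply(c(0.3, 0.1, 0.05, 0.01),
                   function(a) fdr_threshold(psms, a)$n_targets_kept, integer(1))
    expect_true(all(diff(kept) <= 0))
  }
})

test_that("presence rolls up kept target PSMs per sample, never decoys", {
  psms <- tibble::tibble(
    peptide = paste0("PEP", 1:8),
    protein_id = c("P1", rep("P3", 5), "DECOY_X", "DECOY_X"),
    tissue = c("MAG", rep("MAG", 3), "MATED_FRT", "MATED_FRT", "MAG", "MAG"),
    replicate = c(1L, 1L, 1L, 2L, 1L, 1L, 1L, 2L),
    score = 20, is_decoy = c(rep(FALSE, 6), TRUE, TRUE))
  pres <- presence_from_psms(psms)
  expect_equal(nrow(pres), 4) # P1 MAG r1; P3 MAG r1, MAG r2, MATED r1
  expect_false(any(startsWith(pres$protein_id, "DECOY_")))
  expect_equal(pres$n_psms[pres$protein_id == "P3" & pres$tissue == "MAG" &
                             pres$replicate == 1], 2L)
})

test_that("replicate rule: all 2^3 presence patterns, detected iff >= 2 present", {
  for (bits in 0:7) {
    reps <- which(as.logical(bitwAnd(bits, c(1L, 2L, 4L)) > 0))
    pres <- tibble::tibble(protein_id = "P1",
                           tissue = rep("MAG", length(reps)),
                           replicate = as.integer(reps))
    if (length(reps) == 0) pres <- pres[0, ]
    det <- replicate_filter(dplyr::bind_rows(
      pres, tibble::tibble(protein_id = "P1", tissue = "MATED_FRT", replicate = 1L)),
      replicate_min = 2L)
    got <- det$detected[det$tissue == "MAG"]
    expect_identical(got, length(reps) >= 2,
                     info = sprintf("pattern %d", bits))
  }
})

test_that("replicate detection is monotone in presence and per tissue", {
  withr::local_seed(11)
  for (i in 1:30) {
    pres <- tidyr::expand_grid(protein_id = paste0("P", 1:5),
                               tissue = sfp_tissues(), replicate = 1:3) |>
      dplyr::slice_sample(prop = 0.5)
    det <- replicate_filter(pres, 2L)
    # add one more presence row; no detection may flip to FALSE
    missing <- dplyr::anti_join(
      tidyr::expand_grid(protein_id = paste0("P", 1:5),
                         tissue = sfp_tissues(), replicate = 1:3),
      pres, by = c("protein_id", "tissue", "replicate"))
    if (nrow(missing) == 0) next
    det2 <- replicate_filter(dplyr::bind_rows(pres, missing[1, ]), 2L)
    both <- dplyr::inner_join(det, det2, by = c("protein_id", "tissue"),
                              suffix = c("", "_after"))
    expect_false(any(both$detected & !both$detected_after))
  }
})

test_that("per-sample FDR scope thresholds each sample independently", {
  psms <- dplyr::bind_rows(
    make_psms(c(10, 9, 8), tissue = "MAG", replicate = 1L),
    make_psms(c(30, 29), c(31), tissue = "MAG", replicate = 2L))
  kept <- filter_psms_fdr(psms, 0.01, scope = "per_sample")
  # sample 1 keeps all three targets; sample 2 is blocked by its top decoy
  expect_equal(sum(kept$replicate == 1), 3)
  expect_equal(sum(kept$replicate == 2), 0)
})
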