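# Shared fixture builders and independent oracles.  Oracles are deliberately
# naive (full scans / enumerations) and never call the code paths they check.

make_psms <- function(target_scores, decoy_scores = numeric(),
                      tissue = "MAG", replicate = 1L) {
  tibble::tibble(
    peptide = sprintf("PEP%d", seq_len(length(target_scores) + length(decoy_scores))),
    protein_id = c(sprintf("P%d", seq_along(target_scores)),
                   sprintf("DECOY_P%d", seq_along(decoy_scores))),
    tissue = tissue, replicate = replicate,
    score = c(target_scores, decoy_scores),
    is_decoy = rep(c(FALSE, TRUE), c(length(target_scores), length(decoy_scores))))
}

# Brute-force FDR oracle: try every observed score as the cutoff, keep the
# smallest one whose decoys/targets ratio is within alpha.
oracle_fdr <- function(scores, is_decoy, alpha) {
  best <- NULL
  for (c0 in sort(unique(scores))) {
    nt <- sum(scores >= c0 & !is_decoy)
    nd <- sum(scores >= c0 & is_decoy)
    if (nd / max(1, nt) <= alpha) {
      best <- list(score_cutoff = c0, n_targets_kept = nt,
                   n_decoys_kept = nd, achieved_fdr = nd / max(1, nt))
      break # smallest qualifying cutoff keeps the most targets
    }
  }
  if (is.null(best)) {
    best <- list(score_cutoff = Inf, n_targets_kept = 0L,
                 n_decoys_kept = 0L, achieved_fdr = 0)
  }
  best
}

# Independent restatement of the decision cascade over aggregated evidence
# bits, written straight from the classification rules.
oracle_classify <- function(mag, mated, unmated, sp, ms, hom) {
  if (mag && mated) {
    if (sp) return(c("SECRETED", "SIGNAL_PEPTIDE"))
    if (!unmated && ms) return(c("SECRETED", "MALE_SPECIFIC_ABSENT_UNMATED"))
    if (hom) return(c("UNCONFIRMED", "HOMOLOG"))
    return(c("CANDIDATE_UNCLASSIFIED", "NONE"))
  }
  if (mag && !mated && sp) return(c("MAG_ONLY_SECRETED", "SIGNAL_PEPTIDE"))
  c("NOT_SFP", "NONE")
}

make_profile <- function(protein_id = "p1", detected_mag = TRUE,
                         detected_mated = TRUE, detected_unmated = FALSE,
                         signal_peptide = FALSE, male_specific = FALSE,
                         has_sfp_homolog = FALSE, rpkm_mag = 1) {
  tibble::tibble(protein_id = protein_id, detected_mag = detected_mag,
                 detected_mated = detected_mated,
                 detected_unmated = detected_unmated,
                 signal_peptide = signal_peptide, male_specific = male_specific,
                 has_sfp_homolog = has_sfp_homolog, rpkm_mag = rpkm_mag)
}

write_tsv_text <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
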