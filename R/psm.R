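# Target-decoy FDR filtering of PSMs and the replicate-consistency rule that
# turns per-sample presence into per-tissue detection.

#' Target-decoy FDR threshold
#'
#' Finds the score cutoff at which the estimated false discovery rate
#' (number of decoy PSMs at or above the cutoff divided by the number of
#' target PSMs at or above it) is at most `alpha`.  Candidate cutoffs are
#' the observed scores; the returned cutoff is the smallest qualifying one,
#' which maximizes the number of targets kept.  Ties at the cutoff are kept
#' (the comparison is `>=`).
#'
#' @param psms A PSM tibble as returned by [read_psm_table()] (only `score`
#'   and `is_decoy` are used).
#' @param alpha FDR level in (0, 1); default 0.01.
#' @return A one-row tibble with `score_cutoff`, `n_targets_kept`,
#'   `n_decoys_kept` and `achieved_fdr`.  If no cutoff attains `alpha` the
#'   result keeps nothing (`score_cutoff = Inf`).
#' @examples
#' psms <- tibble::tibble(score = c(10, 9, 8), is_decoy = FALSE)
#' fdr_threshold(psms, 0.01)
#' @export
fdr_threshold <- function(psms, alpha = 0.01) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single number in (0, 1)",
          class = "sfp_precondition_error")
  }
  if (!any(!psms$is_decoy)) {
    abort("no target PSMs: cannot estimate an FDR",
          class = "sfp_precondition_error")
  }
  score <- psms$score
  decoy <- psms$is_decoy
  # Scan candidate cutoffs from highest to lowest observed score; cumulative
  # counts give #targets and #decoys with score >= cutoff.
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]
  d <- decoy[ord]
  n_dec <- cumsum(d)
  n_tar <- cumsum(!d)
  # Last index of each tied score block = counts at that cutoff.
  last <- which(!duplicated(s, fromLast = TRUE))
  fdr <- n_dec[last] / pmax(1L, n_tar[last])
  ok <- fdr <= alpha
  if (!any(ok)) {
    return(tibble(score_cutoff = Inf, n_targets_kept = 0L,
                  n_decoys_kept = 0L, achieved_fdr = 0))
  }
  i <- max(which(ok)) # lowest qualifying cutoff keeps the most targets
  tibble(score_cutoff = s[last][i],
         n_targets_kept = as.integer(n_tar[last][i]),
         n_decoys_kept = as.integer(n_dec[last][i]),
         achieved_fdr = fdr[i])
}

#' Filter PSMs at an FDR level
#'
#' Applies [fdr_threshold()] and keeps the target PSMs at or above the
#' cutoff.  With `scope = "per_sample"` the threshold is computed within
#' each tissue/replicate sample instead of globally.
#'
#' @inheritParams fdr_threshold
#' @param scope `"global"` (one cutoff for the run) or `"per_sample"`.
#' @return The kept target PSMs, with an attribute `"fdr"` holding the
#'   [fdr_threshold()] result(s).
#' @export
filter_psms_fdr <- function(psms, alpha = 0.01, scope = c("global", "per_sample")) {
  scope <- match.arg(scope)
  if (scope == "global") {
    res <- fdr_threshold(psms, alpha)
    kept <- psms[!psms$is_decoy & psms$score >= res$score_cutoff, , drop = FALSE]
  } else {
    groups <- split(psms, interaction(psms$tissue, psms$replicate, drop = TRUE))
    res_list <- lapply(groups, function(g) fdr_threshold(g, alpha))
    kept <- bind_rows(lapply(seq_along(groups), function(i) {
      g <- groups[[i]]
      g[!g$is_decoy & g$score >= res_list[[i]]$score_cutoff, , drop = FALSE]
    }))
    res <- bind_rows(res_list, .id = "sample")
  }
  attr(kept, "fdr") <- res
  kept
}

#' Per-sample protein presence from kept PSMs
#'
#' A protein is present in a sample iff at least one kept target PSM maps to
#' it in that sample; decoy PSMs never create presence.
#'
#' @param psms_kept FDR-filtered PSM tibble.
#' @return A tibble with one row per (`protein_id`, `tissue`, `replicate`)
#'   presence, plus `n_psms` supporting it.
#' @export
presence_from_psms <- function(psms_kept) {
  psms_kept |>
    filter(!.data$is_decoy) |>
    count(.data$protein_id, .data$tissue, .data$replicate, name = "n_psms") |>
    arrange(.data$protein_id, .data$tissue, .data$replicate)
}

#' Replicate-consistency detection filter
#'
#' A protein counts as detected in a tissue iff it is present in at least
#' `replicate_min` replicates of that tissue, evaluated independently per
#' tissue.
#'
#' @param presence Presence tibble from [presence_from_psms()] (columns
#'   `protein_id`, `tissue`, `replicate`).
#' @param replicate_min Minimum number of presence replicates (default 2).
#' @return A detection tibble with one row per protein and tissue:
#'   `protein_id`, `tissue`, `n_replicates_present`, `detected`.  Every
#'   protein appearing in `presence` gets a row for each of the three
#'   tissues.
#' @export
replicate_filter <- function(presence, replicate_min = 2L) {
  if (replicate_min < 1L) {
    abort("`replicate_min` must be >= 1", class = "sfp_precondition_error")
  }
  proteins <- unique(presence$protein_id)
  counts <- presence |>
    distinct(.data$protein_id, .data$tissue, .data$replicate) |>
    count(.data$protein_id, .data$tissue, name = "n_replicates_present")
  tidyr::expand_grid(protein_id = proteins, tissue = .sfp_tissues) |>
    left_join(counts, by = c("protein_id", "tissue")) |>
    mutate(n_replicates_present = tidyr::replace_na(.data$n_replicates_present, 0L),
           detected = .data$n_replicates_present >= replicate_min) |>
    arrange(.data$protein_id, match(.data$tissue, .sfp_tissues))
}

#' Detection evidence in one step
#'
#' Convenience wrapper: FDR-filter a raw PSM table, roll up to per-sample
#' presence and apply the replicate filter.
#'
#' @param psms Raw PSM tibble (targets and decoys).
#' @param config An [sfp_config()].
#' @return The detection tibble of [replicate_filter()].
#' @export
detect_proteins <- function(psms, config = sfp_config()) {
  kept <- filter_psms_fdr(psms, config$fdr_alpha, config$fdr_scope)
  replicate_filter(presence_from_psms(kept), config$replicate_min)
}
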