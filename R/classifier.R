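# The decision cascade at the heart of the pipeline.  Candidate proteins are
# those detected in both MAG and mated-FRT; candidates are then classed, in
# order, by signal peptide (SECRETED), by male-specific expression combined
# with absence from unmated females (SECRETED), by cross-species SFP homology
# (UNCONFIRMED), else CANDIDATE_UNCLASSIFIED.  Non-candidates detected only
# in the MAG with a signal peptide are flagged MAG_ONLY_SECRETED and reported
# separately; everything else is NOT_SFP.

#' Assemble evidence profiles
#'
#' Joins detection evidence, expression flags, annotation and homology marks
#' into one row of aggregated booleans per protein — the classifier's input.
#' Proteins missing from a side table get conservative defaults (no signal
#' peptide, not male-specific, no homolog, zero MAG RPKM); detection flags
#' always come from the detection table.
#'
#' @param detection Detection tibble from [replicate_filter()] /
#'   [detect_proteins()].
#' @param flags Expression flags from [expression_flags()]; matched to
#'   proteins by `gene_id == protein_id` (the unigene namespace).
#' @param annotation Annotation tibble from [read_annotation_table()].
#' @param marks Cross-species marks from [cross_species_marks()], or `NULL`.
#' @return A tibble with one row per protein: `protein_id`, `detected_mag`,
#'   `detected_mated`, `detected_unmated`, `signal_peptide` (post-CDS-repair:
#'   predicted before or after repair), `male_specific`, `has_sfp_homolog`,
#'   `rpkm_mag`.
#' @export
build_evidence_profiles <- function(detection, flags = NULL, annotation = NULL,
                                    marks = NULL) {
  det <- detection |>
    select("protein_id", "tissue", "detected") |>
    tidyr::pivot_wider(names_from = "tissue", values_from = "detected",
                       values_fill = FALSE)
  for (t in .sfp_tissues) if (!t %in% names(det)) det[[t]] <- FALSE
  prof <- det |>
    rename(detected_mag = "MAG", detected_mated = "MATED_FRT",
           detected_unmated = "UNMATED_FRT")
  if (!is.null(annotation)) {
    prof <- prof |>
      left_join(annotation |>
                  mutate(signal_peptide = .data$signal_peptide |
                           .data$signal_peptide_after_cds_repair) |>
                  select("protein_id", "signal_peptide"),
                by = "protein_id")
  } else {
    prof$signal_peptide <- NA
  }
  if (!is.null(flags)) {
    prof <- prof |>
      left_join(flags |>
                  select(protein_id = "gene_id", "male_specific", "rpkm_mag"),
                by = "protein_id")
  } else {
    prof$male_specific <- NA
    prof$rpkm_mag <- NA_real_
  }
  if (!is.null(marks)) {
    prof <- prof |> left_join(has_sfp_homolog(marks), by = "protein_id")
  } else {
    prof$has_sfp_homolog <- NA
  }
  prof |>
    mutate(signal_peptide = if_else(is.na(.data$signal_peptide), FALSE,
                                    .data$signal_peptide),
           male_specific = if_else(is.na(.data$male_specific), FALSE,
                                   .data$male_specific),
           has_sfp_homolog = if_else(is.na(.data$has_sfp_homolog), FALSE,
                                     .data$has_sfp_homolog),
           rpkm_mag = if_else(is.na(.data$rpkm_mag), 0, .data$rpkm_mag)) |>
    select("protein_id", "detected_mag", "detected_mated", "detected_unmated",
           "signal_peptide", "male_specific", "has_sfp_homolog", "rpkm_mag") |>
    arrange(.data$protein_id)
}

#' Candidate filter
#'
#' A protein is an SFP candidate iff it was detected in both the MAG and the
#' mated-FRT samples.
#'
#' @param profiles Evidence-profile tibble (needs `detected_mag`,
#'   `detected_mated`).
#' @return Logical vector, one element per profile row.
#' @export
candidate_filter <- function(profiles) {
  profiles$detected_mag & profiles$detected_mated
}

#' Classify proteins as SFPs
#'
#' Applies the full decision cascade to every evidence profile and returns
#' an `sfp_result`.  The cascade is deterministic and total: every protein
#' receives exactly one class and one fired criterion.
#'
#' @param profiles Evidence-profile tibble from [build_evidence_profiles()].
#' @return An object of class `sfp_result`: a list with `calls` (tibble
#'   `protein_id`, `sfp_class`, `fired_criterion`, `rpkm_mag`), `profiles`,
#'   and `summary` (the [summarize_calls()] table).  Use [tidy()] for the
#'   calls and [glance()] for one-row counts.
#' @examples
#' profiles <- tibble::tibble(
#'   protein_id = c("p1", "p2"), detected_mag = TRUE, detected_mated = TRUE,
#'   detected_unmated = c(TRUE, FALSE), signal_peptide = c(TRUE, FALSE),
#'   male_specific = c(FALSE, TRUE), has_sfp_homolog = FALSE, rpkm_mag = 1)
#' tidy(classify_sfps(profiles))
#' @export
classify_sfps <- function(profiles) {
  needed <- c("protein_id", "detected_mag", "detected_mated", "detected_unmated",
              "signal_peptide", "male_specific", "has_sfp_homolog")
  missing <- setdiff(needed, names(profiles))
  if (length(missing) > 0) {
    abort(sprintf("profiles missing column(s): %s", paste(missing, collapse = ", ")),
          class = "sfp_precondition_error")
  }
  bools <- profiles[setdiff(needed, "protein_id")]
  if (any(vapply(bools, anyNA, logical(1)))) {
    abort("evidence profiles contain missing values; complete them first",
          class = "sfp_precondition_error")
  }
  cand <- candidate_filter(profiles)
  p <- profiles
  cls <- character(nrow(p))
  crit <- character(nrow(p))

  sp <- cand & p$signal_peptide
  ms <- cand & !p$signal_peptide & !p$detected_unmated & p$male_specific
  hom <- cand & !sp & !ms & p$has_sfp_homolog
  rest <- cand & !sp & !ms & !hom
  mag_only <- !cand & p$detected_mag & !p$detected_mated & p$signal_peptide

  cls[sp] <- "SECRETED";   crit[sp] <- "SIGNAL_PEPTIDE"
  cls[ms] <- "SECRETED";   crit[ms] <- "MALE_SPECIFIC_ABSENT_UNMATED"
  cls[hom] <- "UNCONFIRMED"; crit[hom] <- "HOMOLOG"
  cls[rest] <- "CANDIDATE_UNCLASSIFIED"; crit[rest] <- "NONE"
  cls[mag_only] <- "MAG_ONLY_SECRETED"; crit[mag_only] <- "SIGNAL_PEPTIDE"
  cls[cls == ""] <- "NOT_SFP"; crit[crit == ""] <- "NONE"

  calls <- tibble(
    protein_id = p$protein_id,
    sfp_class = factor(cls, levels = .sfp_classes),
    fired_criterion = factor(crit, levels = .sfp_criteria),
    rpkm_mag = if ("rpkm_mag" %in% names(p)) p$rpkm_mag else NA_real_)
  structure(list(calls = calls, profiles = profiles,
                 summary = summarize_calls(calls)),
            class = "sfp_result")
}

#' MAG-only secreted proteins
#'
#' The separately reported set: proteins detected only in MAG samples (not
#' in mated-FRT) that carry a signal peptide.  These are never counted among
#' the SECRETED class.
#'
#' @param x An `sfp_result` or a calls tibble.
#' @return The MAG_ONLY_SECRETED subset of the calls.
#' @export
mag_only_secreted <- function(x) {
  calls <- if (inherits(x, "sfp_result")) x$calls else x
  filter(calls, .data$sfp_class == "MAG_ONLY_SECRETED")
}

#' Summarize SFP calls
#'
#' Counts per class and fired criterion.  The counts partition the input:
#' they sum to the number of proteins, and
#' `SECRETED = SIGNAL_PEPTIDE + MALE_SPECIFIC_ABSENT_UNMATED` within the
#' SECRETED class.
#'
#' @param calls A calls tibble (or an `sfp_result`).
#' @return Tibble `sfp_class`, `fired_criterion`, `n`, covering every
#'   class/criterion combination that the cascade can emit (zero rows
#'   included).
#' @export
summarize_calls <- function(calls) {
  if (inherits(calls, "sfp_result")) calls <- calls$calls
  emitted <- tibble(
    sfp_class = factor(c("SECRETED", "SECRETED", "UNCONFIRMED",
                         "CANDIDATE_UNCLASSIFIED", "MAG_ONLY_SECRETED",
                         "NOT_SFP"), levels = .sfp_classes),
    fired_criterion = factor(c("SIGNAL_PEPTIDE", "MALE_SPECIFIC_ABSENT_UNMATED",
                               "HOMOLOG", "NONE", "SIGNAL_PEPTIDE", "NONE"),
                             levels = .sfp_criteria))
  calls |>
    count(.data$sfp_class, .data$fired_criterion, .drop = TRUE) |>
    dplyr::right_join(emitted, by = c("sfp_class", "fired_criterion")) |>
    mutate(n = tidyr::replace_na(.data$n, 0L)) |>
    arrange(match(.data$sfp_class, .sfp_classes),
            match(.data$fired_criterion, .sfp_criteria))
}

#' @export
print.sfp_result <- function(x, ...) {
  g <- glance(x)
  cat("<sfp_result>", g$n_proteins, "proteins;",
      g$n_candidates, "candidates (MAG & mated-FRT)\n")
  cat(sprintf("  SECRETED               %4d  (signal peptide %d + male-specific/absent-unmated %d)\n",
              g$n_secreted, g$n_secreted_signal_peptide, g$n_secreted_male_specific))
  cat(sprintf("  UNCONFIRMED            %4d\n", g$n_unconfirmed))
  cat(sprintf("  CANDIDATE_UNCLASSIFIED %4d\n", g$n_candidate_unclassified))
  cat(sprintf("  MAG_ONLY_SECRETED      %4d  (reported separately)\n", g$n_mag_only_secreted))
  cat(sprintf("  NOT_SFP                %4d\n", g$n_not_sfp))
  invisible(x)
}

#' Tidy an SFP classification result
#'
#' @param x An `sfp_result`.
#' @param ... Unused.
#' @return The calls tibble: `protein_id`, `sfp_class`, `fired_criterion`,
#'   `rpkm_mag`.
#' @method tidy sfp_result
#' @export
tidy.sfp_result <- function(x, ...) {
  x$calls
}

#' One-row summary of an SFP classification result
#'
#' @param x An `sfp_result`.
#' @param ... Unused.
#' @return A one-row tibble of headline counts.
#' @method glance sfp_result
#' @export
glance.sfp_result <- function(x, ...) {
  cl <- x$calls$sfp_class
  cr <- x$calls$fired_criterion
  tibble(
    n_proteins = nrow(x$calls),
    n_candidates = sum(candidate_filter(x$profiles)),
    n_secreted = sum(cl == "SECRETED"),
    n_secreted_signal_peptide = sum(cl == "SECRETED" & cr == "SIGNAL_PEPTIDE"),
    n_secreted_male_specific = sum(cl == "SECRETED" & cr == "MALE_SPECIFIC_ABSENT_UNMATED"),
    n_unconfirmed = sum(cl == "UNCONFIRMED"),
    n_candidate_unclassified = sum(cl == "CANDIDATE_UNCLASSIFIED"),
    n_mag_only_secreted = sum(cl == "MAG_ONLY_SECRETED"),
    n_not_sfp = sum(cl == "NOT_SFP"))
}
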