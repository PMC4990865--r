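# Summary surfaces: accumulated-RPKM expression shares, the per-family
# cross-species table, and the end-to-end pipeline driver.

#' Accumulated-RPKM expression shares
#'
#' For a grouping of proteins, the share of each group is the accumulated
#' RPKM of its members divided by the accumulated RPKM over all groups,
#' in percent.  Over a partition the shares sum to 100 (within 1e-6).
#'
#' @param x A tibble with one row per protein, a grouping column `group`
#'   and an expression column `rpkm`.
#' @return Tibble `group`, `accumulated_rpkm`, `share_pct`, ordered by
#'   decreasing share.  If the total RPKM is zero an empty tibble is
#'   returned with a warning.
#' @examples
#' expression_share(tibble::tibble(group = c("a", "a", "b"), rpkm = c(50, 25, 25)))
#' @export
expression_share <- function(x) {
  acc <- x |>
    group_by(.data$group) |>
    summarise(accumulated_rpkm = sum(.data$rpkm), .groups = "drop")
  total <- sum(acc$accumulated_rpkm)
  if (total <= 0) {
    warn("total RPKM is zero; returning an empty share table")
    return(tibble(group = character(), accumulated_rpkm = numeric(),
                  share_pct = numeric()))
  }
  acc |>
    mutate(share_pct = 100 * .data$accumulated_rpkm / total) |>
    arrange(dplyr::desc(.data$share_pct), .data$group)
}

#' Expression shares of the SFP classes
#'
#' The headline share summary: among the candidate set (proteins detected
#' in both MAG and mated-FRT), the share of accumulated MAG RPKM carried by
#' each class — predicted-secreted versus unconfirmed (and any unclassified
#' candidates).
#'
#' @param result An `sfp_result` (its calls must carry `rpkm_mag`).
#' @return Tibble `group`, `accumulated_rpkm`, `share_pct`.
#' @export
class_expression_share <- function(result) {
  calls <- if (inherits(result, "sfp_result")) result$calls else result
  calls |>
    filter(.data$sfp_class %in% c("SECRETED", "UNCONFIRMED",
                                  "CANDIDATE_UNCLASSIFIED")) |>
    mutate(group = as.character(.data$sfp_class), rpkm = .data$rpkm_mag) |>
    expression_share()
}

#' Expression shares of the functional categories
#'
#' @param result An `sfp_result`.
#' @param annotation Annotation tibble.
#' @param rules Category ruleset.
#' @return Tibble `group` (category), `accumulated_rpkm`, `share_pct`, over
#'   the candidate set.
#' @export
category_expression_share <- function(result, annotation,
                                      rules = read_category_rules()) {
  calls <- if (inherits(result, "sfp_result")) result$calls else result
  ann <- assign_categories(annotation, rules)
  calls |>
    filter(.data$sfp_class %in% c("SECRETED", "UNCONFIRMED",
                                  "CANDIDATE_UNCLASSIFIED")) |>
    left_join(select(ann, "protein_id", "category"), by = "protein_id") |>
    mutate(group = as.character(
             if_else(is.na(.data$category), factor("UNKNOWN", .sfp_categories),
                     .data$category)),
           rpkm = .data$rpkm_mag) |>
    expression_share()
}

#' Per-family cross-species summary table
#'
#' Groups SECRETED proteins by functional category and gene name, counts
#' proteins per name, and marks with "T" every reference species for which
#' any protein of the family carries Domain or Blast homology evidence.
#' Ordering is deterministic: category order, then descending count, then
#' gene name.
#'
#' @param result An `sfp_result` (or calls tibble).
#' @param annotation Annotation tibble.
#' @param marks Marks tibble from [cross_species_marks()] (may be empty).
#' @param rules Category ruleset.
#' @return A tibble with `category`, `gene`, `n` and one `T`/`""` column
#'   per species.
#' @export
family_species_table <- function(result, annotation, marks,
                                 rules = read_category_rules()) {
  calls <- if (inherits(result, "sfp_result")) result$calls else result
  secreted <- filter(calls, .data$sfp_class == "SECRETED")
  species <- sort(unique(marks$species))
  ann <- assign_categories(annotation, rules)
  base <- secreted |>
    left_join(select(ann, "protein_id", "description", "category"),
              by = "protein_id") |>
    mutate(description = if_else(is.na(.data$description), "Unknown",
                                 .data$description),
           category = if_else(is.na(.data$category),
                              factor("UNKNOWN", .sfp_categories), .data$category))
  fam <- base |>
    group_by(.data$category, gene = .data$description) |>
    summarise(n = n(), proteins = list(.data$protein_id), .groups = "drop")
  for (sp in species) {
    marked <- marks |>
      filter(.data$species == sp, .data$mark != "NONE") |>
      dplyr::pull(.data$protein_id)
    fam[[sp]] <- vapply(fam$proteins, function(p) {
      if (any(p %in% marked)) "T" else ""
    }, character(1))
  }
  fam |>
    select(-"proteins") |>
    arrange(match(.data$category, .sfp_categories), dplyr::desc(.data$n),
            .data$gene)
}

#' Render a family table as plain text
#'
#' @param tbl Output of [family_species_table()].
#' @return A character vector of lines, invisibly printed with `cat()`.
#' @export
render_family_table <- function(tbl) {
  species <- setdiff(names(tbl), c("category", "gene", "n"))
  header <- paste(c("Category", "Gene", species), collapse = "\t")
  lines <- vapply(seq_len(nrow(tbl)), function(i) {
    gene <- if (tbl$n[i] > 1) sprintf("%s (%d)", tbl$gene[i], tbl$n[i]) else tbl$gene[i]
    paste(c(as.character(tbl$category[i]), gene,
            unlist(tbl[i, species], use.names = FALSE)), collapse = "\t")
  }, character(1))
  c(header, lines)
}

#' Run the whole pipeline on an input directory
#'
#' Reads the input tables, applies FDR filtering and the replicate rule,
#' computes expression flags and homology marks, classifies every protein
#' and writes the output tables: `detection.tsv`, `profiles.tsv`,
#' `calls.tsv`, `summary.tsv`, `class_shares.tsv`, `family_table.tsv` and
#' a plain-text `family_table.txt`.  Thresholds in use are echoed to the
#' log.  The run is deterministic given the inputs.
#'
#' @param input_dir Directory holding `psms.tsv`, `expression.tsv`,
#'   `library_totals.tsv`, `annotation.tsv`, `homology.tsv`,
#'   `species_sfp_domains.tsv` (see [write_sfp_dataset()]).
#' @param output_dir Output directory, created if missing; `NULL` to skip
#'   writing.
#' @param config An [sfp_config()].
#' @param quiet Suppress log messages.
#' @return Invisibly, a list with the `sfp_result` (`result`), the marks,
#'   the class shares and the family table.
#' @export
run_sfp_pipeline <- function(input_dir, output_dir = NULL,
                             config = sfp_config(), quiet = FALSE) {
  log <- function(...) if (!quiet) message("[sfptools] ", sprintf(...))
  inputs <- read_sfp_input_dir(input_dir)
  log("FDR alpha %.3g (%s), replicate_min %d, RPKM expressed > %.3g, blastp E < %.3g",
      config$fdr_alpha, config$fdr_scope, config$replicate_min,
      config$rpkm_expressed_threshold, config$blastp_evalue_max)
  detection <- detect_proteins(inputs$psm, config)
  flags <- expression_flags(inputs$expression, config)
  marks <- cross_species_marks(inputs$annotation, inputs$species_sfp_domains,
                               inputs$homology, config$blastp_evalue_max)
  profiles <- build_evidence_profiles(detection, flags, inputs$annotation, marks)
  result <- classify_sfps(profiles)
  shares <- class_expression_share(result)
  fam <- family_species_table(result, inputs$annotation, marks)
  g <- glance(result)
  log("%d proteins, %d candidates: %d secreted (%d SP + %d male-specific), %d unconfirmed, %d MAG-only",
      g$n_proteins, g$n_candidates, g$n_secreted, g$n_secreted_signal_peptide,
      g$n_secreted_male_specific, g$n_unconfirmed, g$n_mag_only_secreted)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_sfp_table(detection, file.path(output_dir, "detection.tsv"))
    write_sfp_table(profiles, file.path(output_dir, "profiles.tsv"))
    write_sfp_table(result$calls, file.path(output_dir, "calls.tsv"))
    write_sfp_table(result$summary, file.path(output_dir, "summary.tsv"))
    write_sfp_table(shares, file.path(output_dir, "class_shares.tsv"))
    write_sfp_table(fam, file.path(output_dir, "family_table.tsv"))
    writeLines(render_family_table(fam), file.path(output_dir, "family_table.txt"))
  }
  invisible(list(result = result, marks = marks, shares = shares,
                 family_table = fam))
}
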