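# Functional categorisation from annotation text and cross-species homology
# marking.  Categories follow the standard seminal-fluid functional grouping
# (cell structure, metabolism, protein modification, proteolysis regulators,
# signal transduction, transport/export, RNA & protein synthesis, other,
# unknown); the mapping from description keywords to categories ships as an
# editable ruleset.

#' Load a functional-category ruleset
#'
#' A ruleset is a TSV with columns `pattern` (case-insensitive regular
#' expression over the protein description), `category` (one of
#' [sfp_categories()]), `subtype` (free text, may be empty) and `priority`
#' (unique integer; lower wins when picking the representative subtype).
#' The default ruleset shipped with the package covers the canonical
#' seminal-fluid families (trypsins, carboxylesterases, serpins, ...).
#'
#' @param path Ruleset path; default the packaged ruleset.
#' @return A ruleset tibble.
#' @export
read_category_rules <- function(path = system.file("extdata", "category_rules.tsv",
                                                   package = "sfptools")) {
  df <- read_raw_tsv(path, c("pattern", "category", "subtype", "priority"))
  priority <- coerce_col(df$priority, as.integer, path, "priority")
  if (anyDuplicated(priority)) {
    abort(sprintf("%s: rule priorities must be unique", path),
          class = "sfp_schema_error")
  }
  bad <- !(df$category %in% .sfp_categories)
  if (any(bad)) {
    abort(sprintf("%s: unknown category \"%s\" at line %d", path,
                  df$category[which(bad)[1]], which(bad)[1] + 1L),
          class = "sfp_row_error")
  }
  tibble(pattern = df$pattern, category = df$category,
         subtype = df$subtype, priority = priority)
}

#' Assign functional categories from description text
#'
#' All rules whose pattern matches the description are collected.  No match
#' gives UNKNOWN; matches that agree on a single top-level category give
#' that category (with the subtype of the highest-priority match); matches
#' spanning two or more distinct top-level categories give OTHER.  The
#' outcome is therefore independent of rule order.
#'
#' @param descriptions Character vector of protein descriptions.
#' @param rules Ruleset tibble from [read_category_rules()].
#' @return A tibble with `category` and `subtype`, one row per description.
#' @examples
#' assign_category("Trypsin", read_category_rules())
#' @export
assign_category <- function(descriptions, rules = read_category_rules()) {
  if (nrow(rules) == 0) {
    abort("empty category ruleset", class = "sfp_precondition_error")
  }
  rules <- arrange(rules, .data$priority)
  hit <- vapply(rules$pattern, function(p) {
    grepl(p, descriptions, ignore.case = TRUE, perl = TRUE)
  }, logical(length(descriptions)))
  hit <- matrix(hit, nrow = length(descriptions))
  one <- function(i) {
    m <- which(hit[i, ])
    if (length(m) == 0) return(c("UNKNOWN", ""))
    cats <- unique(rules$category[m])
    if (length(cats) > 1) return(c("OTHER", ""))
    c(cats, rules$subtype[m[1]])
  }
  res <- t(vapply(seq_along(descriptions), one, character(2)))
  tibble(category = factor(res[, 1], levels = .sfp_categories),
         subtype = res[, 2])
}

#' Categorise an annotation table
#'
#' @param annotation Annotation tibble from [read_annotation_table()].
#' @param rules Ruleset from [read_category_rules()].
#' @return The annotation with `category` and `subtype` columns appended.
#' @export
assign_categories <- function(annotation, rules = read_category_rules()) {
  dplyr::bind_cols(annotation, assign_category(annotation$description, rules))
}

#' Cross-species homology marks
#'
#' For every protein and species, a shared conserved-domain accession with
#' that species' SFP set gives a DOMAIN mark; otherwise a blastp hit against
#' that species' SFPs with E-value strictly below `blastp_evalue_max` gives
#' a BLAST mark; otherwise NONE.  DOMAIN always takes precedence over BLAST.
#'
#' @param annotation Annotation tibble (uses `protein_id`, `domain_ids`).
#' @param species_sfp_domains Tibble `species`, `domain_id`: the conserved
#'   domains present in each reference species' SFP catalogue.
#' @param hits Homology tibble from [read_homology_table()]; only BLASTP
#'   rows are consulted.  Hits must already be restricted to each species'
#'   SFP set.
#' @param blastp_evalue_max Strict E-value cutoff (default 1e-5).
#' @return Tibble `protein_id`, `species`, `mark` for every protein x
#'   species combination over the species appearing in either evidence
#'   source.
#' @export
cross_species_marks <- function(annotation, species_sfp_domains, hits,
                                blastp_evalue_max = 1e-5) {
  species <- sort(unique(c(species_sfp_domains$species, hits$subject_species)))
  if (length(species) == 0) {
    return(tibble(protein_id = character(), species = character(),
                  mark = factor(character(), levels = .sfp_marks)))
  }
  dom_list <- split_domain_ids(annotation$domain_ids)
  grid <- tidyr::expand_grid(protein_id = annotation$protein_id, species = species)
  dom_by_species <- split(species_sfp_domains$domain_id, species_sfp_domains$species)
  blast <- hits |>
    filter(.data$tool == "BLASTP", .data$evalue < blastp_evalue_max) |>
    distinct(.data$query_id, .data$subject_species)
  idx <- setNames(seq_along(annotation$protein_id), annotation$protein_id)
  grid |>
    mutate(
      has_domain = purrr::map2_lgl(.data$protein_id, .data$species, function(p, s) {
        length(intersect(dom_list[[idx[[p]]]], dom_by_species[[s]])) > 0
      }),
      has_blast = paste(.data$protein_id, .data$species) %in%
        paste(blast$query_id, blast$subject_species),
      mark = factor(dplyr::case_when(.data$has_domain ~ "DOMAIN",
                                     .data$has_blast ~ "BLAST",
                                     TRUE ~ "NONE"),
                    levels = .sfp_marks)) |>
    select("protein_id", "species", "mark")
}

#' Any cross-species SFP homology?
#'
#' Feeds the classifier's homolog bit: a protein has an SFP homolog iff any
#' species mark differs from NONE.
#'
#' @param marks Marks tibble from [cross_species_marks()].
#' @return Tibble `protein_id`, `has_sfp_homolog`.
#' @export
has_sfp_homolog <- function(marks) {
  marks |>
    group_by(.data$protein_id) |>
    summarise(has_sfp_homolog = any(.data$mark != "NONE"), .groups = "drop")
}

#' Scaffold-localization megablast filter
#'
#' Keeps megablast hits with E-value strictly below `evalue_max` and
#' identity percentage strictly above `identity_min` — the filter used to
#' place detected proteins on genome scaffolds.
#'
#' @param hits Homology tibble with `tool == "MEGABLAST"` rows.
#' @param evalue_max,identity_min Strict thresholds (defaults 1e-20, 95).
#' @return The kept hits.
#' @export
scaffold_localization_filter <- function(hits, evalue_max = 1e-20,
                                         identity_min = 95) {
  mb <- filter(hits, .data$tool == "MEGABLAST")
  if (anyNA(mb$identity_pct)) {
    abort(sprintf("MEGABLAST hit without identity_pct (query %s)",
                  mb$query_id[which(is.na(mb$identity_pct))[1]]),
          class = "sfp_row_error")
  }
  filter(mb, .data$evalue < evalue_max, .data$identity_pct > identity_min)
}

#' Gene-family counts among secreted SFPs
#'
#' Counts SECRETED proteins whose description matches each family pattern
#' (case-insensitive).  Families are not forced to be disjoint.
#'
#' @param result An `sfp_result` (or calls tibble).
#' @param annotation Annotation tibble.
#' @param family_patterns Named character vector: family name -> regular
#'   expression.
#' @return Tibble `family`, `n`, in the order of `family_patterns`.
#' @export
family_counts <- function(result, annotation,
                          family_patterns = c(trypsin = "trypsin",
                                              carboxylesterase = "carboxylesterase",
                                              serpin = "serpin")) {
  calls <- if (inherits(result, "sfp_result")) result$calls else result
  secreted <- filter(calls, .data$sfp_class == "SECRETED")
  desc <- annotation$description[match(secreted$protein_id, annotation$protein_id)]
  desc <- desc[!is.na(desc)]
  tibble(family = names(family_patterns),
         n = vapply(unname(family_patterns), function(p) {
           sum(grepl(p, desc, ignore.case = TRUE, perl = TRUE))
         }, integer(1), USE.NAMES = FALSE))
}
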