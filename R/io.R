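# Readers and writers for the tab-separated evidence tables.  All tables are
# UTF-8 TSV with a mandatory header; identifiers are opaque case-sensitive
# strings.  Every row either parses or raises an error naming the file line,
# so no malformed input is silently dropped.

read_raw_tsv <- function(path, required, optional = character()) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "sfp_io_error")
  }
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE, na = character())
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing required column(s): %s", path,
                  paste(missing, collapse = ", ")),
          class = "sfp_schema_error")
  }
  df
}

# Coerce a character column, reporting 1-based file lines (header is line 1).
coerce_col <- function(x, what, path, col, check) {
  out <- suppressWarnings(what(x))
  bad <- is.na(out) & !is.na(x) & x != "NA"
  if (!missing(check)) bad <- bad | (!is.na(out) & !check(out))
  if (any(bad)) {
    line <- which(bad)[1] + 1L
    abort(sprintf("%s: cannot parse column `%s` at line %d (value \"%s\")",
                  path, col, line, x[which(bad)[1]]),
          class = "sfp_row_error")
  }
  out
}

parse_logical_col <- function(x, path, col) {
  up <- toupper(trimws(x))
  out <- rep(NA, length(x))
  out[up %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[up %in% c("FALSE", "F", "0", "NO")] <- FALSE
  if (anyNA(out)) {
    line <- which(is.na(out))[1] + 1L
    abort(sprintf("%s: cannot parse logical column `%s` at line %d (value \"%s\")",
                  path, col, line, x[which(is.na(out))[1]]),
          class = "sfp_row_error")
  }
  as.logical(out)
}

check_tissue <- function(x, path) {
  bad <- !(x %in% .sfp_tissues)
  if (any(bad)) {
    line <- which(bad)[1] + 1L
    abort(sprintf("%s: unknown tissue \"%s\" at line %d (expected %s)",
                  path, x[which(bad)[1]], line,
                  paste(.sfp_tissues, collapse = "/")),
          class = "sfp_row_error")
  }
  x
}

#' Read a PSM table
#'
#' Reads a tab-separated table of peptide-spectrum matches with columns
#' `peptide`, `protein_id`, `tissue`, `replicate`, `score` and (optionally)
#' `is_decoy`.  When `is_decoy` is absent, decoy status is inferred from the
#' protein-id prefix `decoy_prefix`.
#'
#' @param path Path to a TSV file.
#' @param decoy_prefix Protein-id prefix marking decoy matches, used only if
#'   the file has no `is_decoy` column.
#' @return A tibble with columns `peptide`, `protein_id`, `tissue`
#'   (one of `r paste(sfp_tissues(), collapse = ", ")`), `replicate`
#'   (positive integer), `score` (finite numeric) and `is_decoy` (logical).
#' @export
read_psm_table <- function(path, decoy_prefix = "DECOY_") {
  df <- read_raw_tsv(path, c("peptide", "protein_id", "tissue", "replicate", "score"))
  score <- coerce_col(df$score, as.numeric, path, "score", check = is.finite)
  replicate <- coerce_col(df$replicate, as.integer, path, "replicate",
                          check = function(v) v >= 1L)
  check_tissue(df$tissue, path)
  if (any(df$peptide == "")) {
    abort(sprintf("%s: empty peptide at line %d", path,
                  which(df$peptide == "")[1] + 1L),
          class = "sfp_row_error")
  }
  is_decoy <- if ("is_decoy" %in% names(df)) {
    parse_logical_col(df$is_decoy, path, "is_decoy")
  } else {
    startsWith(df$protein_id, decoy_prefix)
  }
  tibble(peptide = df$peptide, protein_id = df$protein_id,
         tissue = df$tissue, replicate = replicate,
         score = score, is_decoy = is_decoy)
}

#' Read an expression table and compute RPKM
#'
#' Reads per-gene, per-library read counts (columns `gene_id`, `library`,
#' `readcount`, `length_bp`) and normalizes them to RPKM using the total
#' mapped reads of each library.
#'
#' @param path Path to a TSV file.
#' @param library_totals Named numeric vector (or two-column data frame
#'   `library`, `total_mapped`) of total mapped reads per library; totals
#'   must be strictly positive for every library present in the table.
#' @return A tibble with columns `gene_id`, `library`, `readcount`,
#'   `length_bp` and the derived `rpkm`.
#' @export
read_expression_table <- function(path, library_totals) {
  df <- read_raw_tsv(path, c("gene_id", "library", "readcount", "length_bp"))
  totals <- as_library_totals(library_totals)
  readcount <- coerce_col(df$readcount, as.numeric, path, "readcount",
                          check = function(v) v >= 0 & v == floor(v))
  length_bp <- coerce_col(df$length_bp, as.numeric, path, "length_bp",
                          check = function(v) v >= 1)
  unknown <- setdiff(unique(df$library), names(totals))
  if (length(unknown) > 0) {
    abort(sprintf("%s: no library total declared for: %s", path,
                  paste(unknown, collapse = ", ")),
          class = "sfp_schema_error")
  }
  tibble(gene_id = df$gene_id, library = df$library,
         readcount = readcount, length_bp = length_bp,
         rpkm = rpkm(readcount, length_bp, unname(totals[df$library])))
}

as_library_totals <- function(library_totals) {
  if (is.data.frame(library_totals)) {
    totals <- setNames(as.numeric(library_totals$total_mapped),
                       library_totals$library)
  } else {
    totals <- library_totals
  }
  if (is.null(names(totals)) || any(!is.finite(totals)) || any(totals <= 0)) {
    abort("library totals must be named, finite and strictly positive",
          class = "sfp_precondition_error")
  }
  totals
}

#' Read library totals
#'
#' Two-column TSV (`library`, `total_mapped`) giving total mapped reads per
#' expression library.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `library` and `total_mapped`.
#' @export
read_library_totals <- function(path) {
  df <- read_raw_tsv(path, c("library", "total_mapped"))
  total <- coerce_col(df$total_mapped, as.numeric, path, "total_mapped",
                      check = function(v) v > 0)
  tibble(library = df$library, total_mapped = total)
}

#' Read a protein annotation table
#'
#' Columns: `protein_id`, `description` (free text), `signal_peptide`,
#' `signal_peptide_after_cds_repair` (logical; CDS repair may only upgrade a
#' missing signal peptide to present, never remove one), and `domain_ids`
#' (comma-separated conserved-domain accessions, empty for none).
#'
#' @param path Path to a TSV file.
#' @return A tibble; `domain_ids` stays a comma-separated string, use
#'   [split_domain_ids()] for a list of accessions.
#' @export
read_annotation_table <- function(path) {
  df <- read_raw_tsv(path, c("protein_id", "description", "signal_peptide",
                             "signal_peptide_after_cds_repair", "domain_ids"))
  sp <- parse_logical_col(df$signal_peptide, path, "signal_peptide")
  sp_repair <- parse_logical_col(df$signal_peptide_after_cds_repair, path,
                                 "signal_peptide_after_cds_repair")
  downgrade <- sp & !sp_repair
  if (any(downgrade)) {
    abort(sprintf("%s: line %d: CDS repair may not remove a signal peptide",
                  path, which(downgrade)[1] + 1L),
          class = "sfp_row_error")
  }
  tibble(protein_id = df$protein_id, description = df$description,
         signal_peptide = sp, signal_peptide_after_cds_repair = sp_repair,
         domain_ids = df$domain_ids)
}

#' Split comma-separated domain accessions
#'
#' @param domain_ids Character vector of comma-separated accessions.
#' @return A list of character vectors (empty vector for an empty string).
#' @export
split_domain_ids <- function(domain_ids) {
  lapply(strsplit(domain_ids, ",", fixed = TRUE), function(v) {
    v <- trimws(v)
    v[nzchar(v)]
  })
}

#' Read a homology hit table
#'
#' Blast-style tabular hits with columns `query_id`, `subject_id`,
#' `subject_species`, `evalue`, `tool` (`BLASTP` or `MEGABLAST`) and
#' `identity_pct` (required for `MEGABLAST` rows, empty otherwise).
#'
#' @param path Path to a TSV file.
#' @return A tibble of hits; `identity_pct` is `NA` for blastp rows.
#' @export
read_homology_table <- function(path) {
  df <- read_raw_tsv(path, c("query_id", "subject_id", "subject_species",
                             "evalue", "tool"))
  evalue <- coerce_col(df$evalue, as.numeric, path, "evalue",
                       check = function(v) v > 0)
  bad_tool <- !(df$tool %in% c("BLASTP", "MEGABLAST"))
  if (any(bad_tool)) {
    abort(sprintf("%s: unknown tool \"%s\" at line %d", path,
                  df$tool[which(bad_tool)[1]], which(bad_tool)[1] + 1L),
          class = "sfp_row_error")
  }
  identity_pct <- rep(NA_real_, nrow(df))
  if ("identity_pct" %in% names(df)) {
    has <- !is.na(df$identity_pct) & nzchar(df$identity_pct)
    identity_pct[has] <- coerce_col(df$identity_pct[has], as.numeric, path,
                                    "identity_pct",
                                    check = function(v) v >= 0 & v <= 100)
  }
  mb_missing <- df$tool == "MEGABLAST" & is.na(identity_pct)
  if (any(mb_missing)) {
    abort(sprintf("%s: line %d: MEGABLAST hit without identity_pct", path,
                  which(mb_missing)[1] + 1L),
          class = "sfp_row_error")
  }
  tibble(query_id = df$query_id, subject_id = df$subject_id,
         subject_species = df$subject_species, evalue = evalue,
         tool = df$tool, identity_pct = identity_pct)
}

#' Write a pipeline table
#'
#' Writes any pipeline tibble as tab-separated UTF-8 with a header, the
#' format every `read_*_table()` function accepts, so a write/read
#' round-trip reproduces the records field-for-field.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sfp_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
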