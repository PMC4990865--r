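# RPKM normalization and the expressed / male-specific flags consumed by the
# classifier.

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = readcount * 1e9 / (length_bp * total_mapped)`.
#'
#' @param readcount Non-negative read count (vectorised).
#' @param length_bp Gene length in base pairs (>= 1).
#' @param total_mapped Total mapped reads of the library (>= 1).
#' @return RPKM, a non-negative numeric; zero iff `readcount` is zero.
#' @examples
#' rpkm(100, 1000, 1e6) # 100
#' @export
rpkm <- function(readcount, length_bp, total_mapped) {
  if (any(length_bp < 1) || any(total_mapped < 1)) {
    abort("`length_bp` and `total_mapped` must be >= 1",
          class = "sfp_precondition_error")
  }
  if (any(readcount < 0)) {
    abort("`readcount` must be non-negative", class = "sfp_precondition_error")
  }
  as.numeric(readcount) * 1e9 / (as.numeric(length_bp) * as.numeric(total_mapped))
}

#' Expression call at a strict RPKM cutoff
#'
#' A gene is expressed iff its RPKM is strictly greater than the threshold;
#' a value exactly at the threshold is not expressed.
#'
#' @param rpkm_value Numeric RPKM value(s).
#' @param threshold Strict cutoff, default 0.3.
#' @return Logical vector.
#' @examples
#' is_expressed(c(0.31, 0.3, 0)) # TRUE FALSE FALSE
#' @export
is_expressed <- function(rpkm_value, threshold = 0.3) {
  rpkm_value > threshold
}

#' Male-specific expression call
#'
#' A gene is male-specific iff it is expressed (strictly above the RPKM
#' threshold) in at least one male library and in no female library.
#'
#' @param expression Expression tibble (from [read_expression_table()] or
#'   the simulator) with columns `gene_id`, `library`, `rpkm`.
#' @param male_libraries,female_libraries Library names forming the male and
#'   female sides of the comparison; both sets must be non-empty and present.
#' @param threshold Strict expressed cutoff.
#' @return Tibble `gene_id`, `male_specific`.
#' @export
male_specific <- function(expression,
                          male_libraries = c("MALE"),
                          female_libraries = c("FEMALE"),
                          threshold = 0.3) {
  if (length(male_libraries) == 0 || length(female_libraries) == 0) {
    abort("need at least one male and one female library",
          class = "sfp_precondition_error")
  }
  expression |>
    group_by(.data$gene_id) |>
    summarise(
      male_specific =
        any(is_expressed(.data$rpkm[.data$library %in% male_libraries], threshold)) &&
        !any(is_expressed(.data$rpkm[.data$library %in% female_libraries], threshold)),
      .groups = "drop")
}

#' Per-gene expression flags
#'
#' Aggregates a long expression table into one row per gene: RPKM and
#' expressed flag per library (wide), the male-specific flag, and the MAG /
#' MRT RPKM values carried into the evidence profile.  A gene absent from a
#' library is treated as zero RPKM there.
#'
#' @param expression Long expression tibble with `gene_id`, `library`, `rpkm`.
#'   An optional `male_specific` column is honoured as-is (externally
#'   supplied call), bypassing the rule.
#' @param config An [sfp_config()]; supplies the threshold and the male /
#'   female library sets.
#' @return Tibble with `gene_id`, `rpkm_<lib>` and `expressed_<lib>` per
#'   library, `rpkm_mag`, `rpkm_mrt`, `male_specific`.
#' @export
expression_flags <- function(expression, config = sfp_config()) {
  thr <- config$rpkm_expressed_threshold
  wide <- expression |>
    distinct(.data$gene_id, .data$library, .keep_all = TRUE) |>
    select("gene_id", "library", "rpkm") |>
    tidyr::pivot_wider(names_from = "library", values_from = "rpkm",
                       names_prefix = "rpkm_", values_fill = 0)
  rpkm_cols <- grep("^rpkm_", names(wide), value = TRUE)
  for (col in rpkm_cols) {
    wide[[sub("^rpkm_", "expressed_", col)]] <- is_expressed(wide[[col]], thr)
  }
  ms <- if ("male_specific" %in% names(expression)) {
    distinct(expression, .data$gene_id, .data$male_specific)
  } else {
    male_specific(expression, config$male_libraries, config$female_libraries, thr)
  }
  wide |>
    left_join(ms, by = "gene_id") |>
    mutate(rpkm_mag = if ("rpkm_MAG" %in% rpkm_cols) .data$rpkm_MAG else 0,
           rpkm_mrt = if ("rpkm_MRT" %in% rpkm_cols) .data$rpkm_MRT else 0)
}
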