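#' Pipeline configuration
#'
#' Build the run configuration that every stage of the pipeline consults.
#' Defaults are the thresholds of the original study design: detection in at
#' least two of three replicates per tissue, an expression cutoff of
#' RPKM > 0.3 (strict), PSM filtering at 1 % target-decoy FDR, and strict
#' homology thresholds (blastp E-value < 1e-5; megablast E-value < 1e-20 with
#' identity > 95 %).
#'
#' @param replicate_min Minimum number of replicates a protein must be
#'   detected in, per tissue, to count as detected in that tissue.
#' @param n_replicates Number of replicates per tissue in the design.
#' @param rpkm_expressed_threshold A gene is "expressed" in a library iff its
#'   RPKM is strictly greater than this value.
#' @param fdr_alpha Target-decoy FDR level for PSM filtering.
#' @param blastp_evalue_max Blastp hits with E-value strictly below this mark
#'   cross-species homology ("Blast" mark).
#' @param megablast_evalue_max,megablast_identity_min Strict thresholds for
#'   the scaffold-localization megablast filter (E-value below, identity
#'   percentage above).
#' @param male_libraries,female_libraries Library names used to evaluate
#'   male-specific expression: expressed in at least one male library and in
#'   no female library.
#' @param decoy_prefix Protein-id prefix marking decoys when a PSM table has
#'   no explicit `is_decoy` column.
#' @param fdr_scope Apply the FDR threshold `"global"`ly across all PSMs of a
#'   run, or `"per_sample"` within each tissue/replicate sample.
#' @param share_basis Library whose RPKM is accumulated for expression
#'   shares (`"MAG"` by default; `"MRT"` available).
#' @param random_seed Integer seed used by any stochastic step.
#'
#' @return A list of class `sfp_config`.
#' @examples
#' cfg <- sfp_config()
#' cfg$rpkm_expressed_threshold
#' @export
sfp_config <- function(replicate_min = 2L,
                       n_replicates = 3L,
                       rpkm_expressed_threshold = 0.3,
                       fdr_alpha = 0.01,
                       blastp_evalue_max = 1e-5,
                       megablast_evalue_max = 1e-20,
                       megablast_identity_min = 95,
                       male_libraries = c("MALE"),
                       female_libraries = c("FEMALE"),
                       decoy_prefix = "DECOY_",
                       fdr_scope = c("global", "per_sample"),
                       share_basis = c("MAG", "MRT"),
                       random_seed = 1L) {
  fdr_scope <- match.arg(fdr_scope)
  share_basis <- match.arg(share_basis)
  cfg <- list(
    replicate_min = as.integer(replicate_min),
    n_replicates = as.integer(n_replicates),
    rpkm_expressed_threshold = rpkm_expressed_threshold,
    fdr_alpha = fdr_alpha,
    blastp_evalue_max = blastp_evalue_max,
    megablast_evalue_max = megablast_evalue_max,
    megablast_identity_min = megablast_identity_min,
    male_libraries = male_libraries,
    female_libraries = female_libraries,
    decoy_prefix = decoy_prefix,
    fdr_scope = fdr_scope,
    share_basis = share_basis,
    random_seed = as.integer(random_seed)
  )
  validate_config(cfg)
  structure(cfg, class = "sfp_config")
}

validate_config <- function(cfg) {
  thresholds <- c("rpkm_expressed_threshold", "fdr_alpha", "blastp_evalue_max",
                  "megablast_evalue_max", "megablast_identity_min")
  for (th in thresholds) {
    if (!is.numeric(cfg[[th]]) || length(cfg[[th]]) != 1 || cfg[[th]] <= 0) {
      abort(sprintf("config: `%s` must be a single strictly positive number", th),
            class = "sfp_config_error")
    }
  }
  if (cfg$fdr_alpha >= 1) {
    abort("config: `fdr_alpha` must lie in (0, 1)", class = "sfp_config_error")
  }
  if (cfg$replicate_min < 1L || cfg$replicate_min > cfg$n_replicates) {
    abort("config: `replicate_min` must lie in 1..n_replicates",
          class = "sfp_config_error")
  }
  invisible(cfg)
}

#' Read / write a configuration file
#'
#' Configurations are stored as YAML; every field of [sfp_config()] may be
#' overridden, unknown fields are rejected.
#'
#' @param path File path.
#' @return `read_sfp_config()` returns an `sfp_config`;
#'   `write_sfp_config()` returns `path` invisibly.
#' @export
read_sfp_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path), class = "sfp_io_error")
  }
  raw <- yaml::read_yaml(path)
  known <- names(formals(sfp_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(sprintf("config: unknown field(s): %s", paste(unknown, collapse = ", ")),
          class = "sfp_config_error")
  }
  do.call(sfp_config, raw)
}

#' @rdname read_sfp_config
#' @param config An `sfp_config` object.
#' @export
write_sfp_config <- function(config, path) {
  stopifnot(inherits(config, "sfp_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.sfp_config <- function(x, ...) {
  cat("<sfp_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-26s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
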