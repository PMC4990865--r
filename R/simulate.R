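# Synthetic-data generator with planted ground truth.  It emulates the study
# design the pipeline was built for: three proteomic sample types (MAG,
# mated-FRT, unmated-FRT) with three replicates each, scored target and decoy
# PSMs, tag-based expression libraries (MAG, MRT, whole male, whole female)
# with skewed RPKM and male-specific genes, planted signal-peptide flags and
# cross-species homology.  Truth lives only in the returned truth table;
# protein identifiers encode nothing.

.sfp_planted_classes <- c("SECRETED_SP", "SECRETED_SP_IN_UNMATED",
                          "SECRETED_MALE_SPECIFIC", "UNCONFIRMED_HOMOLOG",
                          "MAG_ONLY_SP", "NON_SFP_BACKGROUND")

.planted_to_expected <- c(
  SECRETED_SP = "SECRETED",
  SECRETED_SP_IN_UNMATED = "SECRETED",
  SECRETED_MALE_SPECIFIC = "SECRETED",
  UNCONFIRMED_HOMOLOG = "UNCONFIRMED",
  MAG_ONLY_SP = "MAG_ONLY_SECRETED",
  NON_SFP_BACKGROUND = "NOT_SFP")

#' Simulation parameters
#'
#' Parameters of the synthetic dataset generator.  Defaults reproduce the
#' composition of the study the pipeline models: 84 signal-peptide secreted
#' proteins (55 absent from unmated females, 29 also present there), 10
#' secreted by male-specific expression, 124 unconfirmed homologs, 14
#' MAG-only signal-peptide proteins, and 100 background proteins, in a
#' 3-tissue x 3-replicate design.
#'
#' @param n_per_class Named integer vector over the planted classes
#'   `r paste(.sfp_planted_classes, collapse = ", ")`.
#' @param n_replicates Replicates per tissue.
#' @param replicate_dropout Probability that a planted replicate presence is
#'   lost.  The default is 0: the tissue templates encode the observed
#'   detection patterns, which already reflect whatever missingness the real
#'   experiment had; raise it for robustness and degradation experiments.
#' @param n_psm_per_presence Target PSMs emitted per present protein/sample.
#' @param decoy_fraction Decoy PSMs as a fraction of target PSMs.
#' @param target_score_mean,target_score_sd,decoy_score_mean,decoy_score_sd
#'   Normal score distributions for target and decoy PSMs; separability is a
#'   parameter, not an assumption.
#' @param mag_rpkm_meanlog_secreted,mag_rpkm_meanlog_other,rpkm_sdlog
#'   Log-normal MAG expression: secreted proteins are drawn high, everything
#'   else low.
#' @param secreted_share Planted share of accumulated MAG RPKM carried by
#'   the secreted group within the candidate set (default 0.911); set `NULL`
#'   to leave the drawn values unscaled.
#' @param gene_length_range Uniform range of gene lengths in bp.
#' @param total_mapped Named vector of total mapped reads per library.
#' @param random_seed Mandatory integer seed.
#' @return A list of class `sfp_sim_params`.
#' @export
sfp_sim_params <- function(n_per_class = c(SECRETED_SP = 55L,
                                           SECRETED_SP_IN_UNMATED = 29L,
                                           SECRETED_MALE_SPECIFIC = 10L,
                                           UNCONFIRMED_HOMOLOG = 124L,
                                           MAG_ONLY_SP = 14L,
                                           NON_SFP_BACKGROUND = 100L),
                           n_replicates = 3L,
                           replicate_dropout = 0,
                           n_psm_per_presence = 3L,
                           decoy_fraction = 0.25,
                           target_score_mean = 30, target_score_sd = 4,
                           decoy_score_mean = 12, decoy_score_sd = 4,
                           mag_rpkm_meanlog_secreted = log(800),
                           mag_rpkm_meanlog_other = log(30),
                           rpkm_sdlog = 1,
                           secreted_share = 0.911,
                           gene_length_range = c(300L, 3000L),
                           total_mapped = c(MAG = 2e7, MRT = 2e7,
                                            MALE = 2e7, FEMALE = 2e7),
                           random_seed = 1L) {
  full <- setNames(rep(0L, length(.sfp_planted_classes)), .sfp_planted_classes)
  unknown <- setdiff(names(n_per_class), .sfp_planted_classes)
  if (length(unknown) > 0) {
    abort(sprintf("unknown planted class(es): %s", paste(unknown, collapse = ", ")),
          class = "sfp_precondition_error")
  }
  full[names(n_per_class)] <- as.integer(n_per_class)
  if (any(full < 0)) {
    abort("class counts must be non-negative", class = "sfp_precondition_error")
  }
  if (replicate_dropout < 0 || replicate_dropout >= 1) {
    abort("`replicate_dropout` must lie in [0, 1)", class = "sfp_precondition_error")
  }
  if (decoy_fraction <= 0 || decoy_fraction >= 1) {
    abort("`decoy_fraction` must lie in (0, 1)", class = "sfp_precondition_error")
  }
  if (missing(random_seed) && is.null(random_seed)) {
    abort("`random_seed` is mandatory", class = "sfp_precondition_error")
  }
  structure(list(n_per_class = full, n_replicates = as.integer(n_replicates),
                 replicate_dropout = replicate_dropout,
                 n_psm_per_presence = as.integer(n_psm_per_presence),
                 decoy_fraction = decoy_fraction,
                 target_score_mean = target_score_mean,
                 target_score_sd = target_score_sd,
                 decoy_score_mean = decoy_score_mean,
                 decoy_score_sd = decoy_score_sd,
                 mag_rpkm_meanlog_secreted = mag_rpkm_meanlog_secreted,
                 mag_rpkm_meanlog_other = mag_rpkm_meanlog_other,
                 rpkm_sdlog = rpkm_sdlog,
                 secreted_share = secreted_share,
                 gene_length_range = gene_length_range,
                 total_mapped = total_mapped,
                 random_seed = as.integer(random_seed)),
            class = "sfp_sim_params")
}

# Description pools; secreted proteins are named after canonical seminal
# fluid families so family counts have planted truth.
.secreted_name_pool <- c(rep("Trypsin", 20), rep("Carboxylesterase", 7),
                         "SERPIN", "SERPIN", "Aspartyl protease",
                         "Aspartyl protease", "Serine protease", "Cathepsin B",
                         "Aminopeptidase", "Chitinase", "Chitinase",
                         "Heat shock 70 kDa protein",
                         "Protein disulfide isomerase",
                         "Cysteine-rich secretory protein",
                         "Cysteine-rich secretory protein", "Apolipoprotein D",
                         "Apolipoprotein D", "Chemosensory protein",
                         "Ion transport peptide", "Annexin", "Prosaposin",
                         "Lysosomal acid lipase", "Selenoprotein",
                         "Nucleoside diphosphate kinase", "Calreticulin",
                         "Soluble trehalase", "Carbonic anhydrase")
.unconfirmed_name_pool <- c("Actin", "Tubulin", "Myosin", "Profilin",
                            "Tropomyosin", "Ribosomal protein",
                            "Translation initiation factor", "Thioredoxin",
                            "Cytochrome c", "ATP synthase",
                            "Malate dehydrogenase")
.background_name_pool <- c("hypothetical protein", "uncharacterized protein")

cycle_pool <- function(pool, n) {
  if (n == 0) return(character())
  rep_len(pool, n)
}

# Family names must not wrap (that would inflate planted family counts);
# overflow past the pool is filled with unannotated proteins.
fill_pool <- function(pool, n) {
  if (n == 0) return(character())
  c(pool, rep("Unknown", max(0, n - length(pool))))[seq_len(n)]
}

random_peptides <- function(n, min_len = 8, max_len = 15) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  lens <- sample(min_len:max_len, n, replace = TRUE)
  vapply(lens, function(l) paste(sample(aa, l, replace = TRUE), collapse = ""),
         character(1))
}

# Tissue presence template per planted class (before dropout).  Backgrounds
# cycle through three non-candidate patterns.
presence_template <- function(class, j) {
  switch(class,
         SECRETED_SP = c("MAG", "MATED_FRT"),
         SECRETED_SP_IN_UNMATED = c("MAG", "MATED_FRT", "UNMATED_FRT"),
         SECRETED_MALE_SPECIFIC = c("MAG", "MATED_FRT"),
         UNCONFIRMED_HOMOLOG = c("MAG", "MATED_FRT", "UNMATED_FRT"),
         MAG_ONLY_SP = "MAG",
         NON_SFP_BACKGROUND = list(c("UNMATED_FRT"), c("MATED_FRT"),
                                   c("MAG"))[[((j - 1) %% 3) + 1]])
}

#' Generate a complete synthetic dataset
#'
#' Draws every input table the pipeline consumes, with planted ground truth:
#' tissue-presence templates per planted class, independent replicate
#' dropout, scored target/decoy PSMs, skewed expression with male-specific
#' genes held under the expressed threshold in female libraries, and
#' homology evidence exactly for planted homolog proteins.  The same seed
#' yields identical output.
#'
#' @param params An [sfp_sim_params()].
#' @return A list of class `sfp_dataset` with tibbles `psm`, `expression`
#'   (long, with `readcount`, `length_bp`, `rpkm`), `library_totals`,
#'   `annotation`, `homology`, `species_sfp_domains` and `truth`
#'   (`protein_id`, `planted_class`, `expected_class`, plus the planted
#'   evidence bits).
#' @examples
#' ds <- generate_sfp_dataset(sfp_sim_params(
#'   n_per_class = c(SECRETED_SP = 3L), replicate_dropout = 0,
#'   random_seed = 7L))
#' ds$truth
#' @export
generate_sfp_dataset <- function(params = sfp_sim_params()) {
  stopifnot(inherits(params, "sfp_sim_params"))
  set.seed(params$random_seed)
  n <- sum(params$n_per_class)
  if (n == 0) abort("no proteins requested", class = "sfp_precondition_error")
  classes <- rep(names(params$n_per_class), params$n_per_class)
  ids <- sprintf("comp%05d_c0_seq1", sample.int(99999L, n))

  # Planted evidence bits.
  has_sp <- classes %in% c("SECRETED_SP", "SECRETED_SP_IN_UNMATED", "MAG_ONLY_SP")
  # Some signal peptides only appear after CDS repair of a truncated
  # N-terminus; the repaired flag may only upgrade.
  repaired_only <- has_sp & runif(n) < 0.3
  male_spec <- classes == "SECRETED_MALE_SPECIFIC"
  has_homolog <- classes == "UNCONFIRMED_HOMOLOG"

  within_class <- stats::ave(seq_len(n), classes, FUN = seq_along)
  truth <- tibble(
    protein_id = ids, planted_class = classes,
    expected_class = unname(.planted_to_expected[classes]),
    signal_peptide = has_sp, male_specific = male_spec,
    has_sfp_homolog = has_homolog)

  # --- detection: templates, dropout, PSMs -------------------------------
  reps <- seq_len(params$n_replicates)
  presence <- purrr::map_dfr(seq_len(n), function(i) {
    tidyr::expand_grid(tissue = presence_template(classes[i], within_class[i]),
                       replicate = reps) |>
      mutate(protein_id = ids[i])
  })
  keep <- runif(nrow(presence)) >= params$replicate_dropout
  presence <- presence[keep, , drop = FALSE]

  m <- nrow(presence)
  k <- params$n_psm_per_presence
  psm_target <- tibble(
    peptide = random_peptides(m * k),
    protein_id = rep(presence$protein_id, each = k),
    tissue = rep(presence$tissue, each = k),
    replicate = rep(presence$replicate, each = k),
    score = rnorm(m * k, params$target_score_mean, params$target_score_sd),
    is_decoy = FALSE)
  n_decoy <- max(1L, round(params$decoy_fraction * nrow(psm_target)))
  psm_decoy <- tibble(
    peptide = random_peptides(n_decoy),
    protein_id = sprintf("DECOY_comp%05d_c0_seq1", sample.int(99999L, n_decoy,
                                                              replace = TRUE)),
    tissue = sample(.sfp_tissues, n_decoy, replace = TRUE),
    replicate = sample(reps, n_decoy, replace = TRUE),
    score = rnorm(n_decoy, params$decoy_score_mean, params$decoy_score_sd),
    is_decoy = TRUE)
  psm <- bind_rows(psm_target, psm_decoy) |>
    arrange(.data$protein_id, .data$tissue, .data$replicate, .data$peptide)

  # --- expression ---------------------------------------------------------
  lens <- sample(params$gene_length_range[1]:params$gene_length_range[2], n,
                 replace = TRUE)
  secreted <- startsWith(classes, "SECRETED")
  candidate <- classes %in% c("SECRETED_SP", "SECRETED_SP_IN_UNMATED",
                              "SECRETED_MALE_SPECIFIC", "UNCONFIRMED_HOMOLOG")
  rpkm_mag <- rlnorm(n,
                     ifelse(secreted, params$mag_rpkm_meanlog_secreted,
                            params$mag_rpkm_meanlog_other),
                     params$rpkm_sdlog)
  if (!is.null(params$secreted_share)) {
    # Rescale the secreted group's MAG expression so that, within the
    # candidate set, its accumulated-RPKM share is exactly the planted one.
    s <- sum(rpkm_mag[secreted & candidate])
    u <- sum(rpkm_mag[!secreted & candidate])
    if (s > 0 && u > 0) {
      fac <- params$secreted_share / (1 - params$secreted_share) * u / s
      rpkm_mag[secreted] <- rpkm_mag[secreted] * fac
    }
  }
  rpkm_mrt <- pmax(rlnorm(n, log(50), params$rpkm_sdlog), 1)
  rpkm_male <- pmax(rlnorm(n, log(20), params$rpkm_sdlog), 1)
  rpkm_female <- ifelse(male_spec, 0,
                        pmax(rlnorm(n, log(20), params$rpkm_sdlog), 1))
  expr_wide <- list(MAG = rpkm_mag, MRT = rpkm_mrt,
                    MALE = rpkm_male, FEMALE = rpkm_female)
  expression <- purrr::imap_dfr(expr_wide, function(v, lib) {
    total <- params$total_mapped[[lib]]
    counts <- round(v * lens * total / 1e9)
    tibble(gene_id = ids, library = lib, readcount = as.integer(counts),
           length_bp = as.integer(lens),
           rpkm = rpkm(counts, lens, total))
  }) |>
    arrange(.data$gene_id, .data$library)
  library_totals <- tibble(library = names(params$total_mapped),
                           total_mapped = unname(params$total_mapped))

  # --- annotation ---------------------------------------------------------
  desc <- character(n)
  desc[secreted] <- fill_pool(.secreted_name_pool, sum(secreted))
  desc[classes == "UNCONFIRMED_HOMOLOG"] <-
    cycle_pool(.unconfirmed_name_pool, sum(classes == "UNCONFIRMED_HOMOLOG"))
  desc[classes == "NON_SFP_BACKGROUND"] <-
    cycle_pool(.background_name_pool, sum(classes == "NON_SFP_BACKGROUND"))
  desc[classes == "MAG_ONLY_SP"] <-
    cycle_pool(.secreted_name_pool, sum(classes == "MAG_ONLY_SP"))
  # Homolog evidence is realized half through a shared conserved domain,
  # half through a blastp hit below the E-value cutoff.
  hom_idx <- which(has_homolog)
  via_domain <- hom_idx[seq_along(hom_idx) %% 2 == 1]
  via_blast <- setdiff(hom_idx, via_domain)
  domain_ids <- rep("", n)
  domain_ids[via_domain] <- "Tryp_SPc"
  annotation <- tibble(
    protein_id = ids, description = desc,
    signal_peptide = has_sp & !repaired_only,
    signal_peptide_after_cds_repair = has_sp,
    domain_ids = domain_ids)

  species <- c("DMEL", "AAEG", "AALB", "AMEL")
  species_sfp_domains <- tibble(
    species = species,
    domain_id = rep("Tryp_SPc", length(species)))
  homology <- if (length(via_blast) > 0) {
    tibble(query_id = ids[via_blast],
           subject_id = sprintf("%s_sfp%03d",
                                sample(species, length(via_blast), replace = TRUE),
                                seq_along(via_blast)),
           subject_species = sample(species, length(via_blast), replace = TRUE),
           evalue = 10^runif(length(via_blast), -40, -8),
           tool = "BLASTP", identity_pct = NA_real_)
  } else {
    tibble(query_id = character(), subject_id = character(),
           subject_species = character(), evalue = numeric(),
           tool = character(), identity_pct = numeric())
  }

  structure(list(psm = psm, expression = expression,
                 library_totals = library_totals, annotation = annotation,
                 homology = homology,
                 species_sfp_domains = species_sfp_domains,
                 truth = truth, params = params),
            class = "sfp_dataset")
}

#' Re-apply replicate dropout to a dataset
#'
#' Removes target PSMs of randomly dropped (protein, sample) presence cells;
#' nothing else changes.  For a fixed seed the dropped set grows
#' monotonically with `dropout`, so presence can only shrink as dropout
#' increases.
#'
#' @param dataset An `sfp_dataset`.
#' @param dropout Dropout probability in \[0, 1).
#' @param seed Integer seed for the dropout draws.
#' @return The degraded `sfp_dataset`.
#' @export
degrade_dataset <- function(dataset, dropout, seed = 1L) {
  stopifnot(inherits(dataset, "sfp_dataset"))
  if (dropout < 0 || dropout >= 1) {
    abort("`dropout` must lie in [0, 1)", class = "sfp_precondition_error")
  }
  psm <- dataset$psm
  cells <- psm |>
    filter(!.data$is_decoy) |>
    distinct(.data$protein_id, .data$tissue, .data$replicate) |>
    arrange(.data$protein_id, .data$tissue, .data$replicate)
  set.seed(seed)
  u <- runif(nrow(cells))
  dropped <- cells[u < dropout, , drop = FALSE]
  key <- function(p, t, r) paste(p, t, r, sep = "\r")
  drop_keys <- key(dropped$protein_id, dropped$tissue, dropped$replicate)
  keep <- psm$is_decoy |
    !(key(psm$protein_id, psm$tissue, psm$replicate) %in% drop_keys)
  dataset$psm <- psm[keep, , drop = FALSE]
  dataset
}

#' Write / read a dataset directory
#'
#' `write_sfp_dataset()` writes every table of an `sfp_dataset` as TSV into
#' `dir` (`psms.tsv`, `expression.tsv`, `library_totals.tsv`,
#' `annotation.tsv`, `homology.tsv`, `species_sfp_domains.tsv`,
#' `truth.tsv`); `read_sfp_input_dir()` reads the pipeline inputs back
#' (truth excluded — the pipeline is blind to it).
#'
#' @param dataset An `sfp_dataset`.
#' @param dir Directory (created if missing).
#' @return `write_sfp_dataset()` returns `dir` invisibly;
#'   `read_sfp_input_dir()` a list of input tibbles.
#' @export
write_sfp_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sfp_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sfp_table(dataset$psm, file.path(dir, "psms.tsv"))
  write_sfp_table(select(dataset$expression, -"rpkm"),
                  file.path(dir, "expression.tsv"))
  write_sfp_table(dataset$library_totals, file.path(dir, "library_totals.tsv"))
  write_sfp_table(dataset$annotation, file.path(dir, "annotation.tsv"))
  write_sfp_table(dataset$homology, file.path(dir, "homology.tsv"))
  write_sfp_table(dataset$species_sfp_domains,
                  file.path(dir, "species_sfp_domains.tsv"))
  write_sfp_table(dataset$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' @rdname write_sfp_dataset
#' @export
read_sfp_input_dir <- function(dir) {
  need <- c("psms.tsv", "expression.tsv", "library_totals.tsv",
            "annotation.tsv", "homology.tsv", "species_sfp_domains.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0) {
    abort(sprintf("input directory %s is missing: %s", dir,
                  paste(missing, collapse = ", ")),
          class = "sfp_io_error")
  }
  totals <- read_library_totals(file.path(dir, "library_totals.tsv"))
  sp_dom <- read_raw_tsv(file.path(dir, "species_sfp_domains.tsv"),
                         c("species", "domain_id"))
  list(psm = read_psm_table(file.path(dir, "psms.tsv")),
       expression = read_expression_table(file.path(dir, "expression.tsv"), totals),
       library_totals = totals,
       annotation = read_annotation_table(file.path(dir, "annotation.tsv")),
       homology = read_homology_table(file.path(dir, "homology.tsv")),
       species_sfp_domains = tibble(species = sp_dom$species,
                                    domain_id = sp_dom$domain_id))
}
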