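#' Analysis configuration
#'
#' Bundles every threshold used by the terminus-calling and differential
#' pipeline. Defaults follow common practice for label-free degradomics of
#' small two-group cohorts: symmetric log2 fold-change cut-off of 0.57
#' (a 1.5-fold change), significance at p <= 0.05 with q <= 0.05 for
#' protein-level calls, peptide identification FDR <= 0.01, protein FDR
#' <= 0.05 with at least one unique peptide, presence in at least 3
#' subjects of a group for statistical testing, and exclusivity fractions
#' of 50% (discussion) and 75% (group-specific assignment).
#'
#' @param lfc_threshold absolute log2 fold-change cut-off for calling a
#'   feature up/down (inclusive).
#' @param alpha_p moderated p-value threshold (inclusive).
#' @param alpha_q Storey q-value threshold (inclusive).
#' @param peptide_fdr_max maximum peptide-level identification FDR.
#' @param protein_fdr_max maximum protein-level identification FDR.
#' @param min_unique_peptides minimum unique peptides for a master protein.
#' @param min_presence minimum number of samples (within at least one
#'   group) in which a terminus must be identified and quantified.
#' @param exclusivity_fraction fraction of a group's samples required for
#'   an "exclusive" label in discussion-level filtering.
#' @param specificity_fraction stricter fraction for "group-specific"
#'   assignment.
#' @param window_half_width residues on each side of the scissile bond in
#'   a cleavage window (5 gives the Schechter-Berger P5-P5' window).
#' @param dep_mode `"q"` requires both p and q thresholds (protein-level
#'   convention); `"p"` uses the p-value only (terminus-level convention).
#' @param allow_non_tryptic if `TRUE`, terminus calling accepts peptides
#'   whose opposite boundary is also non-tryptic.
#' @param zero_is_missing treat intensity zeros as missing values.
#' @param seed integer seed driving every stochastic step (imputation).
#' @return A list of class `"degradomics_config"`.
#' @export
pipeline_config <- function(lfc_threshold = 0.57,
                            alpha_p = 0.05,
                            alpha_q = 0.05,
                            peptide_fdr_max = 0.01,
                            protein_fdr_max = 0.05,
                            min_unique_peptides = 1,
                            min_presence = 3,
                            exclusivity_fraction = 0.50,
                            specificity_fraction = 0.75,
                            window_half_width = 5,
                            dep_mode = c("q", "p"),
                            allow_non_tryptic = FALSE,
                            zero_is_missing = TRUE,
                            seed = 1L) {
  dep_mode <- match.arg(dep_mode)
  cfg <- list(
    lfc_threshold = lfc_threshold, alpha_p = alpha_p, alpha_q = alpha_q,
    peptide_fdr_max = peptide_fdr_max, protein_fdr_max = protein_fdr_max,
    min_unique_peptides = min_unique_peptides, min_presence = min_presence,
    exclusivity_fraction = exclusivity_fraction,
    specificity_fraction = specificity_fraction,
    window_half_width = window_half_width, dep_mode = dep_mode,
    allow_non_tryptic = allow_non_tryptic, zero_is_missing = zero_is_missing,
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "degradomics_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$lfc_threshold >= 0,
    cfg$alpha_p >= 0, cfg$alpha_p <= 1,
    cfg$alpha_q >= 0, cfg$alpha_q <= 1,
    cfg$peptide_fdr_max >= 0, cfg$peptide_fdr_max <= 1,
    cfg$protein_fdr_max >= 0, cfg$protein_fdr_max <= 1,
    cfg$min_unique_peptides >= 0,
    cfg$min_presence >= 0,
    cfg$exclusivity_fraction >= 0, cfg$exclusivity_fraction <= 1,
    cfg$specificity_fraction >= 0, cfg$specificity_fraction <= 1,
    cfg$window_half_width >= 1
  )
  invisible(cfg)
}

#' Read or write a configuration file
#'
#' Configuration files are YAML or JSON mappings with the
#' [pipeline_config()] keys; unknown keys are rejected.
#'
#' @param path file path; format decided by extension (`.yaml`/`.yml`
#'   or `.json`).
#' @return [read_config()] returns a `degradomics_config`;
#'   [write_config()] returns `path` invisibly.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: ", ext)
  )
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @param config a `degradomics_config` object.
#' @export
write_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  x <- unclass(config)
  switch(ext,
    yaml = , yml = yaml::write_yaml(x, path),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE),
    stop("unsupported config format: ", ext)
  )
  invisible(path)
}
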