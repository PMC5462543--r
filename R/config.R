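#' Pipeline configuration of named thresholds
#'
#' Central store of every numeric threshold used by the reconstruction
#' rules. Defaults follow the published procedure: hit retention at an
#' expect value of 1e-5 for chimera components, at least three consecutive
#' same-lineage top hits for an unambiguous similarity-based origin,
#' inclusive majority fractions (2/3 of three sub-categories, 3/5 of five),
#' removal of members truncated by more than 50 N-terminal residues,
#' alignment columns kept at a non-gap fraction of at least 0.5, chimera
#' components grouped at mutual overlap above 70%, a mitochondrial
#' targeting-score cutoff of 0.35 with a 30-residue downstream-methionine
#' rescan window, and a 2/3 focal-share fraction for uniquely shared
#' residues.
#'
#' @param ... named overrides of the defaults listed below.
#' @return A named list of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config(mito_score_cutoff = 0.4)
#' cfg$mito_score_cutoff
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    hit_evalue_max            = 1e-5,
    consecutive_hits_min      = 3L,
    chrysista_majority        = 2 / 3,
    hypogyristea_majority     = 2 / 3,
    diatom_majority           = 3 / 5,
    haptophyte_majority       = 2 / 3,
    n_truncation_max          = 50L,
    column_gap_keep_fraction  = 0.5,
    conserved_domain_fraction = 0.7,
    chimera_overlap_fraction  = 0.7,
    chimera_top_n             = 3L,
    mito_score_cutoff         = 0.35,
    downstream_met_window     = 30L,
    focal_residue_fraction    = 2 / 3,
    family_consensus_fraction = 2 / 3,
    smoothing_window          = 3L,
    alpha                     = 0.05
  )
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  fracs <- c("chrysista_majority", "hypogyristea_majority", "diatom_majority",
             "haptophyte_majority", "column_gap_keep_fraction",
             "conserved_domain_fraction", "chimera_overlap_fraction",
             "focal_residue_fraction", "family_consensus_fraction")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v > 1)
      stop("configuration fraction '", f, "' must lie in (0, 1]")
  }
  for (k in c("consecutive_hits_min", "n_truncation_max",
              "downstream_met_window", "chimera_top_n", "smoothing_window")) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v))
      stop("configuration count '", k, "' must be a positive integer")
    cfg[[k]] <- as.integer(v)
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must lie in (0, 1)")
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (k in names(x)) cat(sprintf("  %-26s %s\n", k, format(x[[k]])))
  invisible(x)
}
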