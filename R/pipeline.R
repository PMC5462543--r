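#' Validate and normalise a pipeline run configuration
#'
#' A configuration is a list (or YAML file) with the keys `seed`,
#' `outdir` (optional), `simulation` (overrides for
#' [simulation_params()]), `thresholds` (overrides for
#' [pipeline_config()]) and `stages` (currently `decontam = TRUE/FALSE`).
#' Unknown keys raise an error; there are no silent defaults for unknown
#' settings.
#'
#' @param config list or path to a YAML file.
#' @return normalised list.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  known <- c("seed", "outdir", "simulation", "thresholds", "stages")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$stages)) config$stages <- list()
  if (is.null(config$stages$decontam)) config$stages$decontam <- TRUE
  unknown_st <- setdiff(names(config$stages), "decontam")
  if (length(unknown_st))
    stop("unknown stage key(s): ", paste(unknown_st, collapse = ", "))
  config
}

# family id encoded in the generator's sequence identifiers
.family_of_id <- function(seq_id) {
  sub("_c$", "", sub("^.*\\|", "", seq_id))
}

#' Run the full reconstruction pipeline on a synthetic dataset
#'
#' Executes the stages in order: simulate, decontaminate, targeting,
#' HPPG assembly (floating outgroup-capped thresholds), conservation,
#' alignment curation and clade check, origin assignment (consecutive
#' top-hit, tree sister-group, combined), synapomorphic residues for
#' green-origin HPPGs, chimera detection, and enrichment statistics.
#' Reruns with the same configuration and seed produce byte-identical
#' tabular outputs.
#'
#' @param config list or YAML path (see [read_pipeline_config()]).
#' @return list of class `pipeline_run` with the dataset, stage outputs
#'   and a per-stage summary; when `config$outdir` is set, TSV/JSON
#'   outputs are written there.
#' @export
run_pipeline <- function(config = list()) {
  config <- read_pipeline_config(config)
  cfg <- do.call(pipeline_config, as.list(config$thresholds))
  sim_args <- as.list(config$simulation)
  sim_args$seed <- config$seed
  params <- do.call(simulation_params, sim_args)
  taxonomy <- default_taxonomy()
  summary_rows <- list()
  note <- function(stage, key, value) {
    summary_rows[[length(summary_rows) + 1L]] <<- data.frame(
      stage = stage, key = key, value = as.character(value),
      stringsAsFactors = FALSE)
  }

  ## stage: simulate ---------------------------------------------------
  ds <- simulate_dataset(params, taxonomy = taxonomy)
  note("simulate", "n_sequences", nrow(ds$sequences))
  note("simulate", "n_families", nrow(ds$families))

  ## stage: decontam ---------------------------------------------------
  seqs <- ds$sequences
  if (isTRUE(config$stages$decontam)) {
    tlibs <- ds$species$library_id[ds$species$library_type == "transcriptome"]
    dec <- remove_cross_contaminants(seqs, ds$hits,
                                     libraries = tlibs,
                                     window = cfg$smoothing_window)
    seqs <- dec$sequences
    note("decontam", "n_removed", length(dec$removed))
  } else {
    dec <- list(removed = character(0), report = NULL, thresholds = NULL)
    note("decontam", "n_removed", "disabled")
  }
  hits <- ds$hits[!(ds$hits$query_id %in% dec$removed) &
                    !(ds$hits$subject_id %in% dec$removed), , drop = FALSE]

  ## stage: targeting --------------------------------------------------
  targ <- screen_dual_targeting(seqs, config = cfg)
  note("targeting", "n_plastid", sum(targ$plastid_call))
  note("targeting", "n_dual", sum(targ$dual_call))

  ## stage: assemble ---------------------------------------------------
  lineage_of_subject <- stats::setNames(
    lineage_of(seqs$sub_category, taxonomy), seqs$seq_id)
  plastid_ids <- targ$seq_id[targ$plastid_call]
  och_ids <- seqs$seq_id[is_ochrophyte(seqs$sub_category, taxonomy)]
  genome_species <- ds$species$species_id[
    ds$species$library_type == "genome"]
  seed_cand <- seqs[seqs$seq_id %in% intersect(plastid_ids, och_ids) &
                      seqs$species_id %in% genome_species, , drop = FALSE]
  caps <- lapply(seed_cand$seq_id, compute_outgroup_cap, hits = hits,
                 lineage_of_subject = lineage_of_subject,
                 outgroup_lineages = taxonomy$outgroup_lineages)
  names(caps) <- seed_cand$seq_id
  merged <- merge_seeds(seed_cand, hits, caps,
                        default_organism_precedence())
  hppgs <- lapply(merged$seeds, function(sid) {
    grow_hppg(sid, hits, caps[[sid]], seqs,
              candidate_ids = intersect(plastid_ids, och_ids),
              taxonomy = taxonomy)
  })
  names(hppgs) <- merged$seeds
  note("assemble", "n_seed_candidates", nrow(seed_cand))
  note("assemble", "n_hppgs", length(hppgs))

  ## stage: conserve ---------------------------------------------------
  patterns <- conservation_patterns(cfg)
  hppgs <- lapply(hppgs, evaluate_conservation, patterns = patterns,
                  taxonomy = taxonomy)
  conserved <- Filter(function(h) h$status == "conserved", hppgs)
  note("conserve", "n_conserved", length(conserved))

  ## stage: curate + clade check ---------------------------------------
  curated <- list()
  domains <- list()
  for (h in conserved) {
    fam <- .family_of_id(h$seed_id)
    aln <- ds$alignments[[fam]]
    if (is.null(aln)) next
    aln <- aln[intersect(rownames(aln), c(h$member_ids,
                                          setdiff(rownames(aln),
                                                  dec$removed))), ,
               drop = FALSE]
    have <- intersect(h$member_ids, rownames(aln))
    if (length(have) < length(h$member_ids)) {
      h$member_ids <- have
      h$members <- h$members[h$members$seq_id %in% have, , drop = FALSE]
      h$presence <- hppg_presence(h$members$sub_category, taxonomy)
    }
    cur <- curate_alignment(h, aln, cfg, patterns, taxonomy)
    if (is.null(cur$hppg)) next
    clade <- check_ochrophyte_clade(
      annotate_tree(ds$trees[[fam]], taxonomy), patterns, taxonomy, cfg)
    if (!clade$pass) next
    cur$hppg$status <- "ancestral"
    curated[[cur$hppg$hppg_id]] <- cur$hppg
    domains[[cur$hppg$hppg_id]] <- cur$domain
  }
  note("curate", "n_ancestral", length(curated))

  ## stage: origin -----------------------------------------------------
  origin_rows <- list()
  for (h in curated) {
    fam <- .family_of_id(h$seed_id)
    qh <- hits_for_query(hits, h$seed_id)
    own_species <- seqs$species_id[match(h$seed_id, seqs$seq_id)]
    sub_lin <- lineage_of_subject[qh$subject_id]
    sub_species <- seqs$species_id[match(qh$subject_id, seqs$seq_id)]
    usable <- !(qh$subject_id %in% h$member_ids) &
      !(sub_lin %in% c("ochrophytes", taxonomy$cash_lineages)) &
      sub_species != own_species & qh$evalue <= cfg$hit_evalue_max
    b <- blast_top_hit_origin(sub_lin[usable], cfg$consecutive_hits_min)
    tr <- annotate_tree(ds$trees[[fam]], taxonomy)
    tr <- ape::keep.tip(tr, intersect(tr$tip.label, seqs$seq_id))
    tr <- annotate_tree(tr, taxonomy)
    tcall <- tree_sister_origin(tr, "ochrophytes", taxonomy)
    oc <- combine_origins(b, tcall, hppg_id = h$hppg_id)
    origin_rows[[h$hppg_id]] <- data.frame(
      hppg_id = h$hppg_id, family = fam,
      blast_origin = oc$blast_origin,
      blast_consecutive = oc$blast_consecutive,
      tree_origin = oc$tree_origin,
      combined_origin = oc$combined_origin,
      annotation = if (is.na(oc$annotation)) "" else oc$annotation,
      confidence = oc$confidence, stringsAsFactors = FALSE)
  }
  origins <- if (length(origin_rows)) do.call(rbind, origin_rows) else
    data.frame(hppg_id = character(), family = character(),
               blast_origin = character(), blast_consecutive = integer(),
               tree_origin = character(), combined_origin = character(),
               annotation = character(), confidence = character(),
               stringsAsFactors = FALSE)
  rownames(origins) <- NULL
  origins <- origins[order(origins$hppg_id), , drop = FALSE]
  note("origin", "n_combined_resolved",
       sum(origins$combined_origin != "unresolved"))

  ## stage: synapomorphy (green-origin HPPGs) --------------------------
  set.seed(as.integer(config$seed) + 7919L)
  synap_rows <- list()
  green_hppgs <- origins$hppg_id[origins$combined_origin == "green_algae"]
  ref_green <- reference_green_topology()
  for (hid in green_hppgs) {
    fam <- origins$family[origins$hppg_id == hid]
    aln <- ds$alignments[[fam]]
    aln <- aln[setdiff(rownames(aln), dec$removed), , drop = FALSE]
    sub <- vapply(strsplit(rownames(aln), "|", fixed = TRUE), `[[`, "", 1L)
    # one randomly selected sequence per sub-category (seeded)
    pick <- unlist(lapply(split(seq_len(nrow(aln)), sub), function(ii)
      ii[sample.int(length(ii), 1L)]))
    aln <- aln[pick, , drop = FALSE]
    sub <- sub[pick]
    lin <- lineage_of(sub, taxonomy)
    focal <- rownames(aln)[lin == "ochrophytes"]
    donor <- rownames(aln)[lin == "green_algae"]
    excl <- rownames(aln)[lin %in% c("red_algae", "glaucophytes")]
    if (length(focal) < 3L || !length(donor) || !length(excl)) next
    trimmed <- trim_columns(aln, cfg$column_gap_keep_fraction)
    calls <- find_unique_shared_residues(trimmed, focal, donor, excl,
                                         cfg$focal_residue_fraction)
    if (!nrow(calls)) next
    donor_sub <- stats::setNames(sub[match(donor, rownames(aln))], donor)
    for (i in seq_len(nrow(calls))) {
      col <- calls$column[i] + 1L
      status <- vapply(ref_green$tip.label, function(sc) {
        rows <- donor[donor_sub == sc]
        if (!length(rows)) return("gap")
        v <- trimmed[rows, col]
        if (any(v == calls$residue[i])) "match"
        else if (all(v == "-")) "gap" else "mismatch"
      }, "")
      obs <- infer_origin_node(status, ref_green, "observed")
      ear <- infer_origin_node(status, ref_green, "earliest",
                               observed_node = obs)
      synap_rows[[length(synap_rows) + 1L]] <- data.frame(
        hppg_id = hid, column = calls$column[i],
        residue = calls$residue[i],
        focal_share = calls$focal_share_fraction[i],
        origin_node_observed = obs, origin_node_earliest = ear,
        stringsAsFactors = FALSE)
    }
  }
  synap <- if (length(synap_rows)) do.call(rbind, synap_rows) else
    data.frame(hppg_id = character(), column = integer(),
               residue = character(), focal_share = numeric(),
               origin_node_observed = character(),
               origin_node_earliest = character(), stringsAsFactors = FALSE)
  note("synapomorphy", "n_shared_residues", nrow(synap))

  ## stage: chimera ----------------------------------------------------
  chim_rows <- list()
  outg_ids <- seqs$seq_id[lineage_of_subject[seqs$seq_id] %in%
                            c(taxonomy$outgroup_lineages, "glaucophytes")]
  queries <- seqs$seq_id[seqs$seq_id %in% unique(hits$query_id) &
                           is_ochrophyte(seqs$sub_category, taxonomy)]
  for (q in queries) {
    comp <- collect_components(q, hits, lineage_of_subject,
                               cfg$hit_evalue_max)
    comp <- comp[comp$subject_id %in% outg_ids, , drop = FALSE]
    if (!nrow(comp)) next
    fams <- group_component_families(comp, cfg$chimera_overlap_fraction)
    call <- detect_chimeras(q, fams, cfg$chimera_overlap_fraction,
                            cfg$chimera_top_n)
    chim_rows[[q]] <- data.frame(
      query_id = q, chimeric = call$chimeric,
      n_families = length(fams),
      ntd_origin = if (is.na(call$ntd_origin)) "" else call$ntd_origin,
      ctd_origin = if (is.na(call$ctd_origin)) "" else call$ctd_origin,
      stringsAsFactors = FALSE)
  }
  chimeras <- if (length(chim_rows)) do.call(rbind, chim_rows) else
    data.frame(query_id = character(), chimeric = logical(),
               n_families = integer(), ntd_origin = character(),
               ctd_origin = character(), stringsAsFactors = FALSE)
  rownames(chimeras) <- NULL
  chimeras <- chimeras[order(chimeras$query_id), , drop = FALSE]
  note("chimera", "n_chimeric", sum(chimeras$chimeric))

  ## stage: enrich -----------------------------------------------------
  ## a secondary gene-family dataset assembled without any targeting
  ## filter: consensus targeting per family vs similarity-based origin
  seed_cand_all <- seqs[seqs$seq_id %in% och_ids &
                          seqs$species_id %in% genome_species, ,
                        drop = FALSE]
  caps_all <- caps
  for (sid in setdiff(seed_cand_all$seq_id, names(caps_all)))
    caps_all[[sid]] <- compute_outgroup_cap(
      sid, hits, lineage_of_subject, taxonomy$outgroup_lineages)
  merged_all <- merge_seeds(seed_cand_all, hits, caps_all,
                            default_organism_precedence())
  fam_rows <- lapply(merged_all$seeds, function(sid) {
    h <- grow_hppg(sid, hits, caps_all[[sid]], seqs,
                   candidate_ids = och_ids, taxonomy = taxonomy)
    calls <- ifelse(
      targ$dual_call[match(h$member_ids, targ$seq_id)], "dual",
      ifelse(targ$plastid_call[match(h$member_ids, targ$seq_id)],
             "plastid", "none"))
    cons <- family_targeting_consensus(calls, "ochrophyte", cfg)
    qh <- hits_for_query(hits, sid)
    sub_lin <- lineage_of_subject[qh$subject_id]
    usable <- !(qh$subject_id %in% h$member_ids) &
      !(sub_lin %in% c("ochrophytes", taxonomy$cash_lineages)) &
      qh$evalue <= cfg$hit_evalue_max
    b <- blast_top_hit_origin(sub_lin[usable], cfg$consecutive_hits_min)
    data.frame(hppg_id = sid, family = .family_of_id(sid),
               origin = if (b$determined) b$origin else "unresolved",
               plastid = cons %in% c("plastid", "dual"),
               stringsAsFactors = FALSE)
  })
  fam_tab <- do.call(rbind, fam_rows)
  rownames(fam_tab) <- NULL
  fam_tab <- fam_tab[order(fam_tab$hppg_id), , drop = FALSE]
  enr <- targeting_enrichment(fam_tab, alpha = cfg$alpha)
  gene_origin <- stats::setNames(
    origins$combined_origin,
    origins$family)
  gene_origin <- gene_origin[gene_origin != "unresolved"]
  coexp <- NULL
  if (length(unique(gene_origin)) >= 2L &&
      min(table(gene_origin)) >= 2L) {
    coexp <- coexpression_by_origin(
      ds$expression[intersect(rownames(ds$expression),
                              names(gene_origin)), , drop = FALSE],
      gene_origin, alpha = cfg$alpha)
  }
  note("enrich", "n_origins_tested", nrow(enr))

  summary_df <- do.call(rbind, summary_rows)
  run <- list(config = config, params = params, cfg = cfg, dataset = ds,
              decontam = dec, targeting = targ, hppgs = hppgs,
              curated = curated, origins = origins, synapomorphies = synap,
              chimeras = chimeras, enrichment = enr, coexpression = coexp,
              family_table = fam_tab, summary = summary_df)
  class(run) <- "pipeline_run"
  if (!is.null(config$outdir)) write_pipeline_outputs(run, config$outdir)
  run
}

#' Write pipeline outputs to a run directory
#'
#' @param run a `pipeline_run`.
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_pipeline_outputs <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(run$summary, "summary.tsv")
  wt(run$origins, "origins.tsv")
  wt(run$chimeras, "chimeras.tsv")
  wt(run$synapomorphies, "synapomorphies.tsv")
  wt(run$enrichment, "targeting_enrichment.tsv")
  wt(run$family_table, "family_table.tsv")
  wt(data.frame(seq_id = sort(run$decontam$removed),
                stringsAsFactors = FALSE), "decontam_removed.tsv")
  hp <- do.call(rbind, lapply(run$curated, function(h) data.frame(
    hppg_id = h$hppg_id, seed_id = h$seed_id,
    n_members = length(h$member_ids),
    patterns = paste(h$patterns_passed, collapse = ","),
    status = h$status, stringsAsFactors = FALSE)))
  if (is.null(hp)) hp <- data.frame(hppg_id = character())
  wt(hp, "hppgs.tsv")
  manifest <- list(
    seed = run$config$seed,
    stages = run$summary$stage[!duplicated(run$summary$stage)],
    counts = stats::setNames(as.list(run$summary$value),
                             paste(run$summary$stage, run$summary$key,
                                   sep = ".")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}

#' Score a pipeline run against the generator's planted truth
#'
#' @param run a `pipeline_run` on a simulated dataset.
#' @return list of recovery metrics: origin recovery among determined
#'   combined calls, contradiction rate, contaminant removal and clean
#'   loss, fusion detection with correct segment origins, HPPG yield
#'   against conservation-surviving truth families.
#' @export
score_against_truth <- function(run) {
  truth <- run$dataset$truth
  fam_origin <- stats::setNames(run$dataset$families$origin,
                                run$dataset$families$family)
  det <- run$origins[run$origins$combined_origin != "unresolved", ,
                     drop = FALSE]
  origin_match <- if (nrow(det))
    mean(det$combined_origin == fam_origin[det$family]) else NA_real_
  contradiction <- if (nrow(det))
    mean(det$combined_origin != fam_origin[det$family]) else NA_real_
  contaminants <- truth$seq_id[truth$contaminant]
  clean <- truth$seq_id[!truth$contaminant]
  removed <- run$decontam$removed
  contaminant_removal <- if (length(contaminants))
    mean(contaminants %in% removed) else NA_real_
  clean_loss <- mean(clean %in% removed)
  fus <- truth[truth$is_fusion, , drop = FALSE]
  fusion_detect <- NA_real_
  if (nrow(fus)) {
    ok <- vapply(seq_len(nrow(fus)), function(i) {
      row <- run$chimeras[run$chimeras$query_id == fus$seq_id[i], ,
                          drop = FALSE]
      nrow(row) == 1L && row$chimeric &&
        row$ntd_origin == fus$ntd_origin[i] &&
        row$ctd_origin == fus$ctd_origin[i]
    }, TRUE)
    fusion_detect <- mean(ok)
  }
  list(origin_recovery = origin_match,
       origin_contradiction = contradiction,
       n_determined = nrow(det),
       contaminant_removal = contaminant_removal,
       n_contaminants = length(contaminants),
       clean_loss = clean_loss,
       n_clean = length(clean),
       fusion_detection = fusion_detect,
       n_fusions = nrow(fus),
       n_ancestral_hppgs = length(run$curated),
       n_truth_families = nrow(run$dataset$families))
}
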