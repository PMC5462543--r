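#' Floating outgroup cap for a seed sequence
#'
#' The cap is the expect value, bitscore and rank of the best (rank-1) hit
#' of the seed against the outgroup lineages. Orthologue admission requires
#' a strictly lower expect value than the cap (rank order breaks exact
#' zero-zero ties). A seed with no outgroup hit gets an open cap: every
#' candidate is admissible, and the cap is flagged.
#'
#' @param seed_id seed sequence id.
#' @param hits a [hit_table()] (the seed's search results).
#' @param lineage_of_subject named character vector mapping subject ids to
#'   lineages.
#' @param outgroup_lineages lineages counted as outgroup.
#' @return list of class `outgroup_cap`: `seed_id`, `evalue`, `bitscore`,
#'   `rank` (rank of the outgroup hit in the seed's full hit list), `open`.
#' @export
compute_outgroup_cap <- function(seed_id, hits, lineage_of_subject,
                                 outgroup_lineages =
                                   default_taxonomy()$outgroup_lineages) {
  h <- hits_for_query(hits, seed_id)
  og <- h[lineage_of_subject[h$subject_id] %in% outgroup_lineages, ,
          drop = FALSE]
  if (nrow(og) == 0L) {
    cap <- list(seed_id = seed_id, evalue = Inf, bitscore = -Inf,
                rank = Inf, open = TRUE)
  } else {
    cap <- list(seed_id = seed_id, evalue = og$evalue[1L],
                bitscore = og$bitscore[1L], rank = og$rank[1L],
                open = FALSE)
  }
  class(cap) <- "outgroup_cap"
  cap
}

# admissibility of one hit row under a floating cap
.admissible <- function(evalue, rank, cap) {
  if (cap$open) return(rep(TRUE, length(evalue)))
  evalue < cap$evalue | (evalue == 0 & cap$evalue == 0 & rank < cap$rank)
}

#' Merge redundant seed candidates under floating caps
#'
#' Two candidates merge when either matches the other with an expect value
#' strictly below the matcher's outgroup cap (exact zero-zero ties resolved
#' by hit-list rank). Merging is by transitive closure; from each cluster a
#' single seed is retained, chosen first by the organism precedence list
#' and then by the lowest expect value against the candidate's own outgroup
#' top hit.
#'
#' @param seed_candidates data.frame with `seq_id` and `species_id`.
#' @param hits a [hit_table()] over the candidates.
#' @param caps named list of [compute_outgroup_cap()] results (one per
#'   candidate).
#' @param organism_precedence character vector of species ids in order of
#'   preference; must have no duplicates.
#' @return list with `seeds` (retained seed ids) and `merge_map` (named
#'   character vector candidate -> retained seed).
#' @export
merge_seeds <- function(seed_candidates, hits, caps, organism_precedence) {
  if (anyDuplicated(organism_precedence))
    stop("organism precedence list contains duplicates (cyclic preference)")
  ids <- seed_candidates$seq_id
  missing <- setdiff(ids, names(caps))
  if (length(missing))
    stop("candidates without outgroup cap: ", paste(missing, collapse = ", "))
  h <- hits[hits$query_id %in% ids & hits$subject_id %in% ids, ,
            drop = FALSE]
  adm <- logical(nrow(h))
  for (q in unique(h$query_id)) {
    sel <- h$query_id == q
    adm[sel] <- .admissible(h$evalue[sel], h$rank[sel], caps[[q]])
  }
  edges <- h[adm, c("query_id", "subject_id"), drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  comp <- igraph::components(g)$membership
  prec_rank <- function(sp) {
    r <- match(sp, organism_precedence)
    ifelse(is.na(r), length(organism_precedence) + 1L, r)
  }
  own_cap_ev <- vapply(ids, function(i) caps[[i]]$evalue, 0)
  merge_map <- character(length(ids))
  names(merge_map) <- ids
  for (cl in unique(comp)) {
    members <- ids[comp[ids] == cl]
    sp <- seed_candidates$species_id[match(members, seed_candidates$seq_id)]
    ord <- order(prec_rank(sp), own_cap_ev[members], members)
    merge_map[members] <- members[ord[1L]]
  }
  list(seeds = sort(unique(unname(merge_map))), merge_map = merge_map)
}

#' Grow a homologous plastid-protein group from a seed
#'
#' Admits every library sequence matching the seed with an expect value
#' strictly below the seed's outgroup cap (zero-zero ties by rank), trims
#' each member N-terminally to its first methionine, and tallies presence
#' per ochrophyte sub-category. Members without any methionine are excluded
#' with a message.
#'
#' @param seed_id seed sequence id (always a member).
#' @param hits a [hit_table()] of the seed searched against the library.
#' @param cap the seed's [compute_outgroup_cap()].
#' @param sequences sequence data.frame covering seed and candidates.
#' @param candidate_ids ids eligible for membership (e.g. plastid-predicted
#'   ochrophyte sequences); defaults to every subject in the hit list.
#' @param taxonomy a [taxonomy_scheme()].
#' @return object of class `hppg`: list with `hppg_id`, `seed_id`,
#'   `member_ids`, `members` (trimmed sequence data.frame), `presence`
#'   (named integer over the 11 ochrophyte sub-categories),
#'   `patterns_passed` (empty until [evaluate_conservation()]), `status`.
#' @export
grow_hppg <- function(seed_id, hits, cap, sequences, candidate_ids = NULL,
                      taxonomy = default_taxonomy()) {
  h <- hits_for_query(hits, seed_id)
  if (is.null(candidate_ids)) candidate_ids <- unique(h$subject_id)
  h <- h[h$subject_id %in% setdiff(candidate_ids, seed_id), , drop = FALSE]
  admitted <- h$subject_id[.admissible(h$evalue, h$rank, cap)]
  member_ids <- unique(c(seed_id, admitted))
  members <- sequences[match(member_ids, sequences$seq_id), , drop = FALSE]
  if (anyNA(members$seq_id)) stop("members missing from sequence table")
  mpos <- regexpr("M", members$residues, fixed = TRUE)
  no_met <- mpos < 0L
  if (any(no_met)) {
    message("grow_hppg: excluding ", sum(no_met),
            " member(s) without methionine")
    members <- members[!no_met, , drop = FALSE]
    mpos <- mpos[!no_met]
    member_ids <- members$seq_id
  }
  members$residues <- substr(members$residues, mpos,
                             nchar(members$residues))
  obj <- list(hppg_id = seed_id, seed_id = seed_id,
              member_ids = member_ids, members = members,
              presence = hppg_presence(members$sub_category, taxonomy),
              patterns_passed = character(0), status = "candidate")
  class(obj) <- "hppg"
  obj
}

#' Presence counts over the eleven ochrophyte sub-categories
#' @param sub_categories member sub-categories.
#' @param taxonomy a [taxonomy_scheme()].
#' @return named integer vector over all 11 ochrophyte sub-categories.
#' @export
hppg_presence <- function(sub_categories, taxonomy = default_taxonomy()) {
  och <- unlist(taxonomy$ochrophyte_groups, use.names = FALSE)
  counts <- table(factor(sub_categories, levels = och))
  stats::setNames(as.integer(counts), och)
}

#' Conservation patterns over ochrophyte groups
#'
#' The three calibrated patterns: P1 = majority (>=2/3) of chrysista and
#' majority (>=3/5) of diatoms; P2 = majority of chrysista and majority
#' (>=2/3) of hypogyristea; P3 = at least one chrysistan sub-category and
#' majorities of both hypogyristea and diatoms. Fractions are inclusive and
#' evaluated on sub-categories with at least one member.
#'
#' @param config a [pipeline_config()].
#' @return named list of minimum fractions per group.
#' @export
conservation_patterns <- function(config = pipeline_config()) {
  list(
    P1 = c(chrysista = config$chrysista_majority, hypogyristea = 0,
           diatoms = config$diatom_majority),
    P2 = c(chrysista = config$chrysista_majority,
           hypogyristea = config$hypogyristea_majority, diatoms = 0),
    P3 = c(chrysista = 1e-9, hypogyristea = config$hypogyristea_majority,
           diatoms = config$diatom_majority)
  )
}

#' Evaluate conservation patterns for an HPPG
#'
#' @param hppg an `hppg` (or a bare presence vector).
#' @param patterns list as from [conservation_patterns()].
#' @param taxonomy a [taxonomy_scheme()].
#' @return the HPPG with `patterns_passed` filled and `status` promoted to
#'   `"conserved"` when at least one pattern passes (a bare presence vector
#'   yields just the pattern names).
#' @export
evaluate_conservation <- function(hppg, patterns = conservation_patterns(),
                                  taxonomy = default_taxonomy()) {
  presence <- if (inherits(hppg, "hppg")) hppg$presence else hppg
  fr <- vapply(taxonomy$ochrophyte_groups, function(subs) {
    mean(presence[subs] >= 1L)
  }, 0)
  passed <- names(patterns)[vapply(patterns, function(p) {
    all(fr[names(p)] >= p)
  }, TRUE)]
  if (!inherits(hppg, "hppg")) return(passed)
  hppg$patterns_passed <- passed
  if (length(passed) && hppg$status == "candidate")
    hppg$status <- "conserved"
  hppg
}

#' Rank candidate conservation patterns by control separation
#'
#' For each candidate pattern, counts how many positive and negative
#' control HPPGs pass it and computes a 2x2 chi-squared statistic
#' (pass/fail x positive/negative, no continuity correction). Patterns are
#' ranked by ascending p-value: the best pattern is the one separating the
#' controls most strongly.
#'
#' @param candidate_patterns named list of patterns (see
#'   [conservation_patterns()]).
#' @param positive_controls,negative_controls lists of `hppg` objects or
#'   presence vectors.
#' @param taxonomy a [taxonomy_scheme()].
#' @return data.frame ranked by p: `pattern`, `pos_pass`, `neg_pass`,
#'   `statistic`, `p`.
#' @export
select_conservation_patterns <- function(candidate_patterns,
                                         positive_controls,
                                         negative_controls,
                                         taxonomy = default_taxonomy()) {
  if (!length(positive_controls) || !length(negative_controls))
    stop("both control sets must be non-empty")
  pass_frac <- function(controls, pat) {
    vapply(controls, function(h) {
      pat %in% evaluate_conservation(
        if (inherits(h, "hppg")) h$presence else h,
        candidate_patterns, taxonomy)
    }, TRUE)
  }
  rows <- lapply(names(candidate_patterns), function(pn) {
    pp <- pass_frac(positive_controls, pn)
    np <- pass_frac(negative_controls, pn)
    tab <- rbind(c(sum(pp), sum(!pp)), c(sum(np), sum(!np)))
    if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
      stat <- 0; p <- 1
    } else {
      cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      stat <- unname(cs$statistic); p <- cs$p.value
    }
    data.frame(pattern = pn, pos_pass = sum(pp), neg_pass = sum(np),
               statistic = stat, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (all(out$pos_pass == 0L) || all(out$neg_pass == length(negative_controls)))
    warning("a control set fails (or passes) every candidate pattern")
  out[order(out$p, out$pattern), , drop = FALSE]
}

# first/last alignment column whose consensus-compatible fraction reaches
# `fraction`: a row agrees when its residue is identical to, or
# BLOSUM62-positive against, the column's consensus residue
.conserved_domain <- function(aln, fraction = 0.7) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B <- get("BLOSUM62", envir = environment())
  ok <- vapply(seq_len(ncol(aln)), function(j) {
    col <- aln[, j]
    res <- col[col != "-" & col != "X"]
    if (!length(res)) return(FALSE)
    cons <- names(sort(table(res), decreasing = TRUE))[1L]
    agree <- res == cons | (res %in% rownames(B) & B[cbind(res, cons)] > 0)
    (sum(agree) / nrow(aln)) > fraction
  }, TRUE)
  if (!any(ok)) return(c(NA_integer_, NA_integer_))
  c(min(which(ok)), max(which(ok)))
}

#' Curate an HPPG alignment
#'
#' Identifies the conserved domain of the alignment (first and last column
#' whose consensus-compatible fraction exceeds
#' `conserved_domain_fraction`), then removes members whose first aligned
#' residue starts more than `n_truncation_max` consensus positions after
#' the domain start (N-terminal truncation beyond a plausible targeting
#' sequence) or whose last aligned residue precedes the domain end
#' (premature termination). Conservation is re-evaluated afterwards; the
#' HPPG is eliminated when no pattern passes.
#'
#' @param hppg an `hppg`.
#' @param alignment character matrix covering at least all members.
#' @param config a [pipeline_config()].
#' @param patterns conservation patterns.
#' @param taxonomy a [taxonomy_scheme()].
#' @return list with `hppg` (status `"curated"`, or `NULL` if eliminated),
#'   `alignment` (member rows kept), `removed` (ids), `domain` (columns).
#' @export
curate_alignment <- function(hppg, alignment, config = pipeline_config(),
                             patterns = conservation_patterns(config),
                             taxonomy = default_taxonomy()) {
  missing <- setdiff(hppg$member_ids, rownames(alignment))
  if (length(missing))
    stop("alignment missing members: ", paste(missing, collapse = ", "))
  aln <- alignment[hppg$member_ids, , drop = FALSE]
  dom <- .conserved_domain(alignment, config$conserved_domain_fraction)
  if (anyNA(dom)) dom <- c(1L, ncol(alignment))
  # consensus positions: columns with non-gap fraction >= 0.5 in the full
  # alignment (the backbone a truncation is measured against)
  consensus_cols <- which(colMeans(alignment != "-") >= 0.5)
  removed <- character(0)
  for (id in rownames(aln)) {
    row <- aln[id, ]
    nz <- which(row != "-")
    if (!length(nz)) { removed <- c(removed, id); next }
    first <- nz[1L]; last <- nz[length(nz)]
    late <- sum(consensus_cols >= dom[1L] & consensus_cols < first)
    if (late > config$n_truncation_max || last < dom[2L])
      removed <- c(removed, id)
  }
  keep <- setdiff(rownames(aln), removed)
  hppg$member_ids <- keep
  hppg$members <- hppg$members[hppg$members$seq_id %in% keep, , drop = FALSE]
  hppg$presence <- hppg_presence(hppg$members$sub_category, taxonomy)
  hppg <- evaluate_conservation(hppg, patterns, taxonomy)
  if (!length(hppg$patterns_passed)) {
    return(list(hppg = NULL, alignment = NULL, removed = removed,
                domain = dom))
  }
  hppg$status <- "curated"
  list(hppg = hppg, alignment = aln[keep, , drop = FALSE],
       removed = removed, domain = dom)
}

#' Trim alignment columns by non-gap fraction
#'
#' Keeps columns whose fraction of non-gap residues is at least
#' `keep_fraction` (gap-threshold semantics; the boundary column is kept).
#'
#' @param alignment character matrix.
#' @param keep_fraction minimum non-gap fraction (default 0.5).
#' @return trimmed character matrix (row order preserved) with attribute
#'   `kept_columns` (original column indices).
#' @export
trim_columns <- function(alignment, keep_fraction = 0.5) {
  if (!nrow(alignment) || !ncol(alignment)) stop("alignment is empty")
  keep <- which(colMeans(alignment != "-") >= keep_fraction)
  if (!length(keep)) stop("alignment vanished: every column removed")
  out <- alignment[, keep, drop = FALSE]
  attr(out, "kept_columns") <- keep
  out
}

#' Check for a conserved ochrophyte clade in a gene tree
#'
#' Passes iff some clade (either side of any edge of the unrooted tree)
#' contains enough ochrophyte sub-categories to satisfy at least one
#' conservation pattern while its non-ochrophyte leaves (CASH lineages,
#' rhizarians and euglenids are ignored) all belong to a single one of the
#' five permitted interrupting groups (prokaryotes, red algae, green algae,
#' aplastidic stramenopiles, other eukaryotes).
#'
#' @param tree annotated `phylo` (see [annotate_tree()]).
#' @param patterns conservation patterns.
#' @param taxonomy a [taxonomy_scheme()].
#' @param config a [pipeline_config()].
#' @return list: `pass`, `reason`, `offending_lineages` (for the best
#'   failing clade), `clade_tips` (leaves of the passing clade, if any).
#' @export
check_ochrophyte_clade <- function(tree, patterns = conservation_patterns(),
                                   taxonomy = default_taxonomy(),
                                   config = pipeline_config()) {
  info <- attr(tree, "leaf_info")
  if (is.null(info)) { tree <- annotate_tree(tree, taxonomy)
    info <- attr(tree, "leaf_info") }
  if (length(tree$tip.label) < 4L)
    return(list(pass = FALSE, reason = "uninformative",
                offending_lineages = character(0), clade_tips = NULL))
  ignored <- c(taxonomy$cash_lineages, "euglenids", "chlorarachniophytes")
  ntip <- length(tree$tip.label)
  sides <- list()
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2L]
    tips <- if (child <= ntip) tree$tip.label[child] else
      ape::extract.clade(tree, child)$tip.label
    sides[[length(sides) + 1L]] <- tips
    sides[[length(sides) + 1L]] <- setdiff(tree$tip.label, tips)
  }
  sides <- unique(sides)
  best_off <- character(0)
  for (tips in sides) {
    sub <- info$sub_category[match(tips, info$label)]
    lin <- info$lineage[match(tips, info$label)]
    och <- sub[lin == "ochrophytes"]
    if (!length(och)) next
    pres <- hppg_presence(och, taxonomy)
    if (!length(evaluate_conservation(pres, patterns, taxonomy))) next
    foreign <- unique(lin[!(lin %in% c("ochrophytes", ignored))])
    if (length(foreign) <= 1L)
      return(list(pass = TRUE, reason = "ok",
                  offending_lineages = character(0), clade_tips = tips))
    if (!length(best_off) || length(foreign) < length(best_off))
      best_off <- foreign
  }
  list(pass = FALSE, reason = "no qualifying clade",
       offending_lineages = best_off, clade_tips = NULL)
}

#' @export
print.hppg <- function(x, ...) {
  cat("hppg", x$hppg_id, "- seed", x$seed_id, "-", length(x$member_ids),
      "members, status", x$status, "\n")
  cat("  patterns passed:",
      if (length(x$patterns_passed)) paste(x$patterns_passed, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}
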