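#' Screen a gene tree for strictly vertical inheritance
#'
#' An HPPG is excluded from synapomorphic-residue analysis when any watched
#' lineage forms two or more clades, where a clade is a monophyletic group
#' containing more than one sequence of the lineage and separated from the
#' next such group by at least two sequences from outside the lineage.
#' Configured allowances are honoured: lineages listed in `allow_nested`
#' may contain nested sequences of the named lineages without breaking
#' their monophyly, and leaves of the `ignore` lineages never enter the
#' assessment (defaults follow the green-gene dataset rules: green algae
#' may be paraphyletic to cryptomonads, haptophytes and ochrophytes;
#' ochrophytes to cryptomonads and haptophytes; chlorarachniophyte,
#' euglenid and alveolate leaves are ignored).
#'
#' @param tree annotated `phylo`.
#' @param watched lineages screened for multiple clades.
#' @param allow_nested named list: lineage -> lineages allowed nested
#'   inside it.
#' @param ignore lineages whose leaves are set aside entirely.
#' @param taxonomy a [taxonomy_scheme()].
#' @return list: `include` (logical), `offending_lineages`.
#' @export
screen_vertical_inheritance <- function(
    tree,
    watched = c("ochrophytes", "cryptomonads", "haptophytes", "red_algae",
                "green_algae"),
    allow_nested = list(
      green_algae = c("cryptomonads", "haptophytes", "ochrophytes"),
      ochrophytes = c("cryptomonads", "haptophytes")),
    ignore = c("chlorarachniophytes", "euglenids", "other_alveolates",
               "dinotoms"),
    taxonomy = default_taxonomy()) {
  if (is.null(attr(tree, "leaf_info"))) tree <- annotate_tree(tree, taxonomy)
  info <- attr(tree, "leaf_info")
  drop <- info$label[info$lineage %in% ignore]
  work <- tree
  if (length(drop) && length(drop) < length(tree$tip.label)) {
    work <- ape::drop.tip(tree, drop)
    work <- annotate_tree(work, taxonomy)
  }
  winfo <- attr(work, "leaf_info")
  offenders <- character(0)
  for (lin in watched) {
    inside <- c(lin, allow_nested[[lin]])
    lin_tips <- winfo$label[winfo$lineage == lin]
    if (length(lin_tips) < 2L) next
    # cluster lineage leaves: maximal clades whose leaves are all from the
    # lineage or its allowed nested lineages
    ntip <- length(work$tip.label)
    member <- winfo$label[winfo$lineage %in% inside]
    clusters <- list()
    assigned <- character(0)
    # examine clades from largest to smallest
    clades <- lapply((ntip + 1L):(ntip + work$Nnode), function(nd)
      ape::extract.clade(work, nd)$tip.label)
    clades <- c(clades, as.list(work$tip.label))
    clades <- clades[order(-lengths(clades))]
    for (tips in clades) {
      if (any(tips %in% assigned)) next
      if (!all(tips %in% member)) next
      if (!any(tips %in% lin_tips)) next
      clusters[[length(clusters) + 1L]] <- intersect(tips, lin_tips)
      assigned <- c(assigned, tips)
    }
    multi <- clusters[lengths(clusters) > 1L]
    if (length(multi) >= 2L) {
      # genuine separation: >=2 outside sequences within the spanning clade
      sep <- FALSE
      for (a in seq_along(multi)) for (b in seq_along(multi)) {
        if (a >= b) next
        span <- ape::extract.clade(
          work, ape::getMRCA(work, c(multi[[a]], multi[[b]])))$tip.label
        outside <- setdiff(span, member)
        if (length(outside) >= 2L) sep <- TRUE
      }
      if (sep) offenders <- c(offenders, lin)
    }
  }
  list(include = !length(offenders), offending_lineages = offenders)
}

#' Validate one member sequence by composite similarity checks
#'
#' Two-stage screen: (1) globally, the first three hits must come from the
#' query's own lineage (ochrophyte queries are tested against their own
#' group: chrysista, hypogyristea or diatoms); (2) within the alignment,
#' the first non-self hit must come from a different sub-category of the
#' same lineage, with the published exceptions: glaucophyte queries may hit
#' cyanobacteria, red or green algae (usually a single glaucophyte per
#' alignment); green queries may hit ochrophytes, cryptomonads or
#' haptophytes provided their best green hit has a lower expect value than
#' their best red or glaucophyte hit; ochrophyte queries may hit any other
#' ochrophyte sub-category (and cryptomonads/haptophytes under the same
#' expect-value proviso); when no other sub-category of the query's lineage
#' exists in the alignment, a same-sub-category top hit is accepted.
#'
#' @param query_sub_category query sub-category.
#' @param global_hit_sub_categories sub-categories of the global search
#'   hits, rank order.
#' @param aln_hits data.frame of within-alignment hits in rank order with
#'   columns `sub_category` and `evalue` (self-hits removed).
#' @param aln_sub_categories sub-categories present in the alignment.
#' @param taxonomy a [taxonomy_scheme()].
#' @return list: `keep` (logical), `reason`.
#' @export
validate_member_sequence <- function(query_sub_category,
                                     global_hit_sub_categories,
                                     aln_hits, aln_sub_categories,
                                     taxonomy = default_taxonomy()) {
  q_lin <- lineage_of(query_sub_category, taxonomy,
                      ochrophyte_as_group = TRUE)
  g_lin <- lineage_of(global_hit_sub_categories, taxonomy,
                      ochrophyte_as_group = TRUE)
  if (length(g_lin) < 3L || any(g_lin[1:3] != q_lin))
    return(list(keep = FALSE, reason = "global lineage"))
  if (!nrow(aln_hits))
    return(list(keep = FALSE, reason = "no alignment hits"))
  lin_plain <- lineage_of(query_sub_category, taxonomy)
  a_sub <- aln_hits$sub_category
  a_lin <- lineage_of(a_sub, taxonomy)
  top_sub <- a_sub[1L]; top_lin <- a_lin[1L]
  same_lineage_other <- top_lin == lin_plain && top_sub != query_sub_category
  if (same_lineage_other) return(list(keep = TRUE, reason = "ok"))
  best_ev <- function(lins) {
    sel <- a_lin %in% lins
    if (any(sel)) min(aln_hits$evalue[sel]) else Inf
  }
  if (lin_plain == "glaucophytes" &&
      top_lin %in% c("prokaryotes", "red_algae", "green_algae"))
    return(list(keep = TRUE, reason = "glaucophyte allowance"))
  if (lin_plain == "green_algae" &&
      top_lin %in% c("ochrophytes", "cryptomonads", "haptophytes")) {
    if (best_ev("green_algae") < best_ev(c("red_algae", "glaucophytes")))
      return(list(keep = TRUE, reason = "green paraphyly allowance"))
    return(list(keep = FALSE, reason = "green support too weak"))
  }
  if (lin_plain == "ochrophytes") {
    if (top_lin == "ochrophytes" && top_sub != query_sub_category)
      return(list(keep = TRUE, reason = "ochrophyte cross-group allowance"))
    if (top_lin %in% c("cryptomonads", "haptophytes")) {
      if (best_ev("ochrophytes") <
          best_ev(c("green_algae", "red_algae", "glaucophytes")))
        return(list(keep = TRUE, reason = "ochrophyte paraphyly allowance"))
      return(list(keep = FALSE, reason = "ochrophyte support too weak"))
    }
  }
  other_subs <- setdiff(aln_sub_categories[
    lineage_of(aln_sub_categories, taxonomy) == lin_plain],
    query_sub_category)
  if (!length(other_subs) && top_sub == query_sub_category)
    return(list(keep = TRUE, reason = "same-sub-category fallback"))
  list(keep = FALSE, reason = "alignment top hit")
}

#' Uniquely shared residues between a focal and a donor lineage set
#'
#' A trimmed-alignment column qualifies when (a) some residue is held by at
#' least `focal_fraction` (default 2/3) of the ungapped focal sequences,
#' (b) at least one donor sequence holds the same residue, (c) no exclusion
#' sequence holds it, and (d) at least one exclusion sequence is ungapped
#' at that column. Columns where the focal set is entirely gapped are
#' skipped.
#'
#' @param alignment character matrix (one sequence per sub-category).
#' @param focal_ids,donor_ids,exclusion_ids row names of the three sets.
#' @param focal_fraction minimum share among ungapped focal sequences.
#' @return data.frame of calls: `column` (0-based), `residue`,
#'   `focal_share_fraction`, `donor_sub_categories` (comma-joined donor
#'   rows holding the residue).
#' @export
find_unique_shared_residues <- function(alignment, focal_ids, donor_ids,
                                        exclusion_ids,
                                        focal_fraction = 2 / 3) {
  stopifnot(all(c(focal_ids, donor_ids, exclusion_ids) %in%
                  rownames(alignment)))
  rows <- list()
  for (j in seq_len(ncol(alignment))) {
    f <- alignment[focal_ids, j]
    fu <- f[f != "-"]
    if (!length(fu)) next
    tab <- sort(table(fu), decreasing = TRUE)
    r <- names(tab)[1L]
    share <- tab[[1L]] / length(fu)
    if (share < focal_fraction) next
    d <- alignment[donor_ids, j]
    if (!any(d == r)) next
    e <- alignment[exclusion_ids, j]
    if (any(e == r)) next
    if (!any(e != "-")) next
    rows[[length(rows) + 1L]] <- data.frame(
      column = j - 1L, residue = r, focal_share_fraction = share,
      donor_sub_categories = paste(donor_ids[d == r], collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(column = integer(), residue = character(),
                      focal_share_fraction = numeric(),
                      donor_sub_categories = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Infer the origin node of a uniquely shared residue
#'
#' Places a residue on a reference topology whose leaves are donor
#' sub-categories. The candidate origin is the most recent common ancestor
#' of the leaves carrying the residue (`observed` mode) or of the carrying
#' and gapped leaves (`earliest` mode: gaps count as matches); the
#' candidate stands only if its clade holds more matching than
#' non-matching-or-gapped leaves. When the candidate clade fails the
#' majority rule (scattered matches), the call falls back to the
#' qualifying clade carrying the most matching leaves — for a single
#' carrier, its sub-category leaf. The earliest node is constrained to be
#' ancestor-or-equal of the observed node.
#'
#' @param status named character vector over the reference leaves:
#'   `"match"`, `"mismatch"` or `"gap"`.
#' @param reference_topology rooted `phylo` with labelled internal nodes.
#' @param mode `"observed"` or `"earliest"`.
#' @param observed_node when `mode = "earliest"`, the node label of the
#'   observed call (enforces the ancestor-or-equal invariant).
#' @return node label (internal node label, or leaf name).
#' @export
infer_origin_node <- function(status, reference_topology,
                              mode = c("observed", "earliest"),
                              observed_node = NULL) {
  mode <- match.arg(mode)
  tr <- reference_topology
  ntip <- length(tr$tip.label)
  if (is.null(tr$node.label) || !any(nzchar(tr$node.label)))
    tr$node.label <- paste0("node", seq_len(tr$Nnode))
  stopifnot(all(tr$tip.label %in% names(status)))
  node_tips <- function(nd) {
    if (nd <= ntip) tr$tip.label[nd] else ape::extract.clade(tr, nd)$tip.label
  }
  label_of <- function(nd) {
    if (nd <= ntip) tr$tip.label[nd] else tr$node.label[nd - ntip]
  }
  counted_match <- function(s) s == "match" | (mode == "earliest" & s == "gap")
  qualifies <- function(nd) {
    s <- status[node_tips(nd)]
    sum(counted_match(s)) > sum(!counted_match(s))
  }
  carriers <- tr$tip.label[counted_match(status[tr$tip.label])]
  # in earliest mode an all-gap leaf set can only widen, never define, the
  # call: require at least one genuine match
  if (!any(status[tr$tip.label] == "match")) return(NA_character_)
  cand <- if (length(carriers) == 1L) match(carriers, tr$tip.label) else
    ape::getMRCA(tr, carriers)
  node <- NULL
  if (qualifies(cand)) {
    node <- cand
  } else {
    # scattered carriers: best qualifying clade by number of matching
    # leaves, ties towards the smaller clade, then tree order
    nodes <- c(seq_len(ntip), (ntip + 1L):(ntip + tr$Nnode))
    ok <- nodes[vapply(nodes, qualifies, TRUE)]
    ok <- ok[vapply(ok, function(nd)
      any(node_tips(nd) %in% carriers), TRUE)]
    if (!length(ok)) return(NA_character_)
    nmatch <- vapply(ok, function(nd)
      sum(counted_match(status[node_tips(nd)])), 0L)
    sizes <- vapply(ok, function(nd) length(node_tips(nd)), 0L)
    node <- ok[order(-nmatch, sizes, ok)][1L]
  }
  if (mode == "earliest" && !is.null(observed_node)) {
    all_labels <- c(tr$tip.label, tr$node.label)
    obs_nd <- match(observed_node, all_labels)
    if (!is.na(obs_nd)) {
      anc <- obs_nd; nd <- obs_nd
      repeat {
        up <- tr$edge[tr$edge[, 2L] == nd, 1L]
        if (!length(up)) break
        anc <- c(anc, up); nd <- up
      }
      if (!(node %in% anc)) node <- obs_nd
    }
  }
  label_of(node)
}

#' Flag amino acids with lineage-biased composition
#'
#' For every amino acid, a 2x2 chi-squared test (that residue vs all
#' others, lineage A vs lineage B) over all ungapped alignment positions;
#' residues with `p <= alpha` are flagged and replaced by gaps in all
#' sequences of the filtered alignment. Degenerate tables (zero margins)
#' are skipped.
#'
#' @param alignment character matrix.
#' @param ids_a,ids_b row names of the two lineages compared.
#' @param alpha significance threshold.
#' @return list: `flagged` (amino acids), `tests` (per-residue data.frame),
#'   `alignment` (filtered).
#' @export
composition_bias_filter <- function(alignment, ids_a, ids_b, alpha = 0.05) {
  stopifnot(length(ids_a) >= 1L, length(ids_b) >= 1L)
  a <- as.vector(alignment[ids_a, , drop = FALSE])
  b <- as.vector(alignment[ids_b, , drop = FALSE])
  a <- a[a != "-" & a != "X"]; b <- b[b != "-" & b != "X"]
  aas <- sort(unique(c(a, b)))
  rows <- lapply(aas, function(r) {
    tab <- rbind(c(sum(a == r), sum(a != r)), c(sum(b == r), sum(b != r)))
    if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
      return(data.frame(residue = r, statistic = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    data.frame(residue = r, statistic = unname(cs$statistic),
               p = cs$p.value, stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, rows)
  flagged <- tests$residue[!is.na(tests$p) & tests$p <= alpha]
  filt <- alignment
  filt[filt %in% flagged] <- "-"
  list(flagged = flagged, tests = tests, alignment = filt)
}

#' Count residues uniquely shared with each partner lineage
#'
#' On a concatenated alignment with lineage annotations, a column counts
#' for partner lineage L when the focal rule holds (`strict`: the same
#' residue in every focal sequence; `majority`: in at least
#' `majority_count` focal sequences) and that residue occurs in at least
#' one sequence of L and in no other partner lineage.
#'
#' @param alignment character matrix.
#' @param focal_ids focal rows.
#' @param partner_ids named list: partner lineage -> row names.
#' @param mode `"strict"` or `"majority"`.
#' @param majority_count focal count threshold for `"majority"` mode
#'   (default: more than half of the focal rows).
#' @return named integer vector of counts per partner lineage.
#' @export
count_shared_residues_concatenated <- function(alignment, focal_ids,
                                               partner_ids,
                                               mode = c("strict", "majority"),
                                               majority_count = NULL) {
  mode <- match.arg(mode)
  if (is.null(majority_count))
    majority_count <- ceiling(length(focal_ids) / 2)
  counts <- stats::setNames(integer(length(partner_ids)), names(partner_ids))
  for (j in seq_len(ncol(alignment))) {
    f <- alignment[focal_ids, j]
    if (mode == "strict") {
      if (any(f == "-") || length(unique(f)) != 1L) next
      r <- f[1L]
    } else {
      fu <- f[f != "-"]
      if (!length(fu)) next
      tab <- sort(table(fu), decreasing = TRUE)
      if (tab[[1L]] < majority_count) next
      r <- names(tab)[1L]
    }
    has <- vapply(partner_ids, function(ids)
      any(alignment[ids, j] == r), TRUE)
    if (sum(has) == 1L) counts[which(has)] <- counts[which(has)] + 1L
  }
  counts
}
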