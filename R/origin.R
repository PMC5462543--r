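#' Similarity-based origin by the consecutive-top-hit rule
#'
#' The origin is the lineage of the rank-1 hit; it is reported as
#' determined only when the first `min_consecutive` (default 3) or more
#' hits all resolve within that lineage. Self-hits, hits to members of the
#' same HPPG and hits to the query's own species are expected to have been
#' removed upstream.
#'
#' @param hit_lineages character vector of hit lineages in rank order.
#' @param min_consecutive minimum run length for a determined call.
#' @return list: `origin` (lineage or `"ambiguous"`), `consecutive`,
#'   `determined`.
#' @export
blast_top_hit_origin <- function(hit_lineages, min_consecutive = 3L) {
  hit_lineages <- unname(hit_lineages[!is.na(hit_lineages)])
  if (!length(hit_lineages))
    return(list(origin = "ambiguous", consecutive = 0L, determined = FALSE))
  first <- hit_lineages[1L]
  run <- which(hit_lineages != first)
  consecutive <- if (length(run)) run[1L] - 1L else length(hit_lineages)
  determined <- consecutive >= min_consecutive
  list(origin = if (determined) first else first,
       consecutive = as.integer(consecutive), determined = determined)
}

# root an unrooted annotated tree on the edge whose far side (relative to
# the focal leaves) is most phylogenetically complex: most distinct
# lineages, then most sub-categories, then most leaves, then smallest leaf
# label.  The focal stem edge itself is never a candidate (its near side
# holds nothing but the focal clade, which would leave no sister group).
.root_by_complexity <- function(tree, focal_tips, taxonomy) {
  info <- attr(tree, "leaf_info")
  ntip <- length(tree$tip.label)
  n_nonfocal <- ntip - sum(tree$tip.label %in% focal_tips)
  best <- NULL
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2L]
    tips <- if (child <= ntip) tree$tip.label[child] else
      ape::extract.clade(tree, child)$tip.label
    for (side in list(tips, setdiff(tree$tip.label, tips))) {
      if (!length(side) || length(side) == ntip) next
      if (any(focal_tips %in% side)) next
      if (length(side) >= n_nonfocal) next
      i <- match(side, info$label)
      key <- list(nlin = length(unique(info$lineage[i])),
                  nsub = length(unique(info$sub_category[i])),
                  nleaf = length(side), first = min(side), side = side)
      if (is.null(best) ||
          key$nlin > best$nlin ||
          (key$nlin == best$nlin && key$nsub > best$nsub) ||
          (key$nlin == best$nlin && key$nsub == best$nsub &&
             key$nleaf > best$nleaf) ||
          (key$nlin == best$nlin && key$nsub == best$nsub &&
             key$nleaf == best$nleaf && key$first < best$first))
        best <- key
    }
  }
  if (is.null(best)) return(NULL)
  rooted <- ape::root(tree, outgroup = best$side, resolve.root = TRUE)
  attr(rooted, "leaf_info") <- info
  rooted
}

#' Gene-tree origin by the constrained sister-group rule
#'
#' Roots the tree on the most phylogenetically complex side away from the
#' focal clade, requires the focal lineage to be monophyletic (CASH,
#' rhizarian and euglenid leaves are set aside before the test), and
#' reports an origin only when the focal clade has exactly one sister
#' group consisting of at least two sequences from at least two different
#' sub-categories of a single lineage.
#'
#' @param tree annotated `phylo`.
#' @param focal_lineage lineage of the focal clade (default
#'   `"ochrophytes"`).
#' @param taxonomy a [taxonomy_scheme()].
#' @return list: `origin` (lineage or `"undetermined"`), `sister`
#'   (sub-categories in the sister group), `monophyletic`.
#' @export
tree_sister_origin <- function(tree, focal_lineage = "ochrophytes",
                               taxonomy = default_taxonomy()) {
  if (is.null(attr(tree, "leaf_info"))) tree <- annotate_tree(tree, taxonomy)
  info <- attr(tree, "leaf_info")
  ignored <- c(taxonomy$cash_lineages, "euglenids", "chlorarachniophytes")
  drop <- info$label[info$lineage %in% ignored]
  if (length(drop)) {
    tree <- ape::drop.tip(tree, drop)
    if (is.null(tree))
      return(list(origin = "undetermined", sister = character(0),
                  monophyletic = FALSE))
    tree <- annotate_tree(tree, taxonomy)
    info <- attr(tree, "leaf_info")
  }
  focal_tips <- info$label[info$lineage == focal_lineage]
  if (!length(focal_tips)) stop("focal clade absent from tree")
  if (length(focal_tips) == length(tree$tip.label))
    return(list(origin = "undetermined", sister = character(0),
                monophyletic = TRUE))
  rooted <- .root_by_complexity(tree, focal_tips, taxonomy)
  if (is.null(rooted))
    return(list(origin = "undetermined", sister = character(0),
                monophyletic = FALSE))
  if (!ape::is.monophyletic(rooted, focal_tips))
    return(list(origin = "undetermined", sister = character(0),
                monophyletic = FALSE))
  mrca <- ape::getMRCA(rooted, focal_tips)
  if (is.null(mrca))
    mrca <- match(focal_tips[1L], rooted$tip.label)
  parent <- rooted$edge[rooted$edge[, 2L] == mrca, 1L]
  if (!length(parent))
    return(list(origin = "undetermined", sister = character(0),
                monophyletic = TRUE))
  siblings <- rooted$edge[rooted$edge[, 1L] == parent, 2L]
  siblings <- setdiff(siblings, mrca)
  if (length(siblings) != 1L)
    return(list(origin = "undetermined", sister = character(0),
                monophyletic = TRUE))
  ntip <- length(rooted$tip.label)
  sis_tips <- if (siblings <= ntip) rooted$tip.label[siblings] else
    ape::extract.clade(rooted, siblings)$tip.label
  i <- match(sis_tips, info$label)
  lin <- unique(info$lineage[i])
  sub <- unique(info$sub_category[i])
  ok <- length(sis_tips) >= 2L && length(sub) >= 2L && length(lin) == 1L
  list(origin = if (ok) lin else "undetermined", sister = sub,
       monophyletic = TRUE)
}

#' Combine similarity and tree origin calls
#'
#' Agreement between a determined consecutive-top-hit call and a
#' determined sister-group call yields a high-confidence combined origin.
#' Any disagreement or undetermined component leaves the HPPG unresolved
#' at low confidence, annotated with the tree origin when available and
#' the similarity origin otherwise.
#'
#' @param blast_call result of [blast_top_hit_origin()].
#' @param tree_call result of [tree_sister_origin()].
#' @param hppg_id optional identifier carried through.
#' @return list of class `origin_call`: `hppg_id`, `blast_origin`,
#'   `blast_consecutive`, `tree_origin`, `sister_sub_categories`,
#'   `combined_origin` (lineage or `"unresolved"`), `annotation`,
#'   `confidence`.
#' @export
combine_origins <- function(blast_call, tree_call, hppg_id = NA_character_) {
  b_det <- isTRUE(blast_call$determined)
  t_det <- !identical(tree_call$origin, "undetermined")
  agree <- b_det && t_det && identical(blast_call$origin, tree_call$origin)
  combined <- if (agree) blast_call$origin else "unresolved"
  annotation <- if (agree) blast_call$origin else if (t_det)
    tree_call$origin else if (b_det) blast_call$origin else NA_character_
  out <- list(
    hppg_id = hppg_id,
    blast_origin = if (b_det) blast_call$origin else "ambiguous",
    blast_consecutive = blast_call$consecutive,
    tree_origin = if (t_det) tree_call$origin else "undetermined",
    sister_sub_categories = tree_call$sister,
    combined_origin = combined,
    annotation = annotation,
    confidence = if (agree) "high" else "low"
  )
  class(out) <- "origin_call"
  out
}

#' Next-deepest evolutionary affinity
#'
#' For hit lists: strips the leading run of primary-origin hits and applies
#' the consecutive-top-hit rule to the remaining suffix. For trees:
#' evaluates the sister group of the clade formed by the focal clade plus
#' its primary sister, under the same constraints as
#' [tree_sister_origin()].
#'
#' @param x character vector of hit lineages in rank order, or an annotated
#'   `phylo`.
#' @param primary_origin the already-assigned primary origin lineage.
#' @param focal_lineage focal lineage for the tree mode.
#' @param taxonomy a [taxonomy_scheme()].
#' @param min_consecutive rule threshold.
#' @return list as from [blast_top_hit_origin()] /
#'   [tree_sister_origin()]; origin `"not determined"` when no deeper
#'   group resolves.
#' @export
deeper_affinity <- function(x, primary_origin,
                            focal_lineage = "ochrophytes",
                            taxonomy = default_taxonomy(),
                            min_consecutive = 3L) {
  if (is.character(x)) {
    run <- which(x != primary_origin)
    if (!length(run))
      return(list(origin = "not determined", consecutive = 0L,
                  determined = FALSE))
    suffix <- x[run[1L]:length(x)]
    call <- blast_top_hit_origin(suffix, min_consecutive)
    if (!call$determined) call$origin <- call$origin
    return(call)
  }
  tree <- x
  if (is.null(attr(tree, "leaf_info"))) tree <- annotate_tree(tree, taxonomy)
  info <- attr(tree, "leaf_info")
  # treat focal + primary-origin leaves as one extended focal clade
  ext <- unique(c(focal_lineage, primary_origin))
  tmp <- info
  tmp$lineage[tmp$lineage %in% ext] <- focal_lineage
  attr(tree, "leaf_info") <- tmp
  res <- tree_sister_origin(tree, focal_lineage, taxonomy)
  if (identical(res$origin, "undetermined")) res$origin <- "not determined"
  res
}

#' Annotate the tree position of a CASH lineage
#'
#' Places the sequences of one CASH lineage relative to the ochrophyte
#' clade into one of eight categories: internal to the diatoms,
#' hypogyristea or chrysista, internal at an ambiguous position, or
#' external as the immediate sister to all ochrophytes, within the red
#' algae, within the green algae, or at any other external position. The
#' position is only recorded when the lineage forms exactly one clade in
#' the tree, that clade holds at least `min_sub_categories` of its
#' sub-categories (lineages with several sampled sub-categories) and at
#' least one predicted plastid-targeted sequence (plastid-bearing CASH
#' lineages).
#'
#' @param tree annotated `phylo`.
#' @param cash_lineage lineage to place (e.g. `"haptophytes"`).
#' @param targeting_calls named logical: plastid-targeted status per leaf
#'   of the CASH lineage.
#' @param taxonomy a [taxonomy_scheme()].
#' @param min_sub_categories minimum distinct sub-categories required
#'   (default 2 for alveolates, cryptomonads and haptophytes; use 1 for
#'   dinotoms).
#' @param require_plastid whether at least one leaf must be
#'   plastid-targeted.
#' @return list: `category` (one of the eight, or `"not recorded"`) and
#'   `reason`.
#' @export
annotate_cash_position <- function(tree, cash_lineage, targeting_calls,
                                   taxonomy = default_taxonomy(),
                                   min_sub_categories = 2L,
                                   require_plastid = TRUE) {
  if (is.null(attr(tree, "leaf_info"))) tree <- annotate_tree(tree, taxonomy)
  info <- attr(tree, "leaf_info")
  cash_tips <- info$label[info$lineage == cash_lineage]
  if (!length(cash_tips))
    return(list(category = "not recorded", reason = "lineage absent"))
  och_tips <- info$label[info$lineage == "ochrophytes"]
  rooted <- .root_by_complexity(tree, unique(c(och_tips, cash_tips)),
                                taxonomy)
  if (is.null(rooted))
    return(list(category = "not recorded", reason = "unrootable"))
  info <- attr(rooted, "leaf_info")
  if (!ape::is.monophyletic(rooted, cash_tips) && length(cash_tips) > 1L)
    return(list(category = "not recorded",
                reason = "multiple evolutionarily distinct groups"))
  sub <- unique(info$sub_category[match(cash_tips, info$label)])
  if (length(sub) < min_sub_categories)
    return(list(category = "not recorded",
                reason = "too few sub-categories"))
  if (require_plastid &&
      !any(targeting_calls[cash_tips] %in% TRUE))
    return(list(category = "not recorded",
                reason = "no plastid-targeted sequence"))
  ntip <- length(rooted$tip.label)
  node <- if (length(cash_tips) == 1L) match(cash_tips, rooted$tip.label)
  else ape::getMRCA(rooted, cash_tips)
  parent <- rooted$edge[rooted$edge[, 2L] == node, 1L]
  if (!length(parent))
    return(list(category = "not recorded", reason = "clade spans root"))
  sibs <- setdiff(rooted$edge[rooted$edge[, 1L] == parent, 2L], node)
  sis_tips <- unlist(lapply(sibs, function(s) {
    if (s <= ntip) rooted$tip.label[s] else
      ape::extract.clade(rooted, s)$tip.label
  }))
  sis_lin <- info$lineage[match(sis_tips, info$label)]
  sis_sub <- info$sub_category[match(sis_tips, info$label)]
  if (all(sis_lin == "ochrophytes")) {
    groups <- unique(ochrophyte_group_of(sis_sub, taxonomy))
    # nested inside the ochrophyte clade?
    inside <- !all(och_tips %in% sis_tips)
    category <- if (length(groups) == 1L)
      paste0("internal:", groups) else "internal:ambiguous"
    if (!inside && length(groups) > 1L &&
        setequal(sis_tips, och_tips)) category <- "external:immediate-sister"
    return(list(category = category, reason = "ok"))
  }
  if (setequal(intersect(sis_tips, och_tips), och_tips) &&
      all(sis_lin %in% c("ochrophytes", taxonomy$cash_lineages)))
    return(list(category = "external:immediate-sister", reason = "ok"))
  if (all(sis_lin == "red_algae"))
    return(list(category = "external:within-red", reason = "ok"))
  if (all(sis_lin == "green_algae"))
    return(list(category = "external:within-green", reason = "ok"))
  list(category = "external:other", reason = "ok")
}

#' Top-hit origin against a reduced library
#'
#' Removes hits from the excluded lineage (normally the query's own) and
#' applies the consecutive-top-hit rule to the remainder. Ochrophyte
#' sub-categories are treated as their three groups for this analysis.
#'
#' @param hit_sub_categories character vector of hit sub-categories in rank
#'   order.
#' @param excluded_lineage lineage to exclude (group-level granularity).
#' @param taxonomy a [taxonomy_scheme()].
#' @param min_consecutive rule threshold.
#' @return list as from [blast_top_hit_origin()].
#' @export
reduced_library_top_hit <- function(hit_sub_categories, excluded_lineage,
                                    taxonomy = default_taxonomy(),
                                    min_consecutive = 3L) {
  lin <- lineage_of(hit_sub_categories, taxonomy, ochrophyte_as_group = TRUE)
  keep <- !is.na(lin) & lin != excluded_lineage
  blast_top_hit_origin(lin[keep], min_consecutive)
}
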