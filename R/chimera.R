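#' Collect homology components of one query protein
#'
#' One component per hit retained at the expect-value cutoff (inclusive at
#' the boundary): its query interval, bitscore and subject lineage.
#'
#' @param query_id query protein id.
#' @param hits a [hit_table()].
#' @param lineage_of_subject named character vector subject id -> lineage.
#' @param evalue_max inclusive expect-value cutoff (default 1e-5).
#' @return data.frame of components (`subject_id`, `qstart`, `qend`,
#'   `bitscore`, `lineage`); empty when nothing passes.
#' @export
collect_components <- function(query_id, hits, lineage_of_subject,
                               evalue_max = 1e-5) {
  h <- hits_for_query(hits, query_id)
  h <- h[h$evalue <= evalue_max, , drop = FALSE]
  data.frame(subject_id = h$subject_id, qstart = h$qstart, qend = h$qend,
             bitscore = h$bitscore,
             lineage = unname(lineage_of_subject[h$subject_id]),
             stringsAsFactors = FALSE)
}

.overlap_len <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2))

#' Group components into component families
#'
#' Two components belong to the same family when they overlap by more than
#' `overlap_fraction` (default 70%) of the length of each (transitive
#' closure). Families are then merged when one family's representative
#' span (the union span of its members on the query) is covered by more
#' than the same fraction of its length by another family's span; merging
#' iterates to a fixed point. The result is invariant under permutation of
#' the component order.
#'
#' @param components data.frame from [collect_components()].
#' @param overlap_fraction mutual-overlap threshold.
#' @return list of `component_family` objects: `members` (component rows),
#'   `span` (`c(start, end)` union span), `family_id`.
#' @export
group_component_families <- function(components, overlap_fraction = 0.7) {
  n <- nrow(components)
  if (!n) return(list())
  # stage 1: pairwise mutual-overlap rule, transitive closure
  if (n == 1L) {
    comp <- 1L
  } else {
    pairs <- utils::combn(n, 2L)
    s <- components$qstart; e <- components$qend
    ov <- .overlap_len(s[pairs[1L, ]], e[pairs[1L, ]],
                       s[pairs[2L, ]], e[pairs[2L, ]])
    l1 <- e[pairs[1L, ]] - s[pairs[1L, ]]
    l2 <- e[pairs[2L, ]] - s[pairs[2L, ]]
    linked <- ov > overlap_fraction * l1 & ov > overlap_fraction * l2
    g <- igraph::graph_from_data_frame(
      data.frame(from = pairs[1L, linked], to = pairs[2L, linked]),
      directed = FALSE, vertices = data.frame(name = seq_len(n)))
    comp <- igraph::components(g)$membership[as.character(seq_len(n))]
  }
  fams <- lapply(sort(unique(comp)), function(cl) {
    rows <- components[comp == cl, , drop = FALSE]
    list(members = rows, span = c(min(rows$qstart), max(rows$qend)))
  })
  # stage 2: family-level inclusion merge.  All families linked by the
  # >70% span-inclusion rule in the current round are merged
  # simultaneously (connected components), then spans are recomputed and
  # the round repeats until stable -- this makes the result independent of
  # the component input order.
  repeat {
    k <- length(fams)
    if (k < 2L) break
    spans <- t(vapply(fams, function(f) f$span, c(0, 0)))
    linked <- matrix(FALSE, k, k)
    for (x in seq_len(k - 1L)) for (y in (x + 1L):k) {
      ov <- .overlap_len(spans[x, 1L], spans[x, 2L],
                         spans[y, 1L], spans[y, 2L])
      lx <- spans[x, 2L] - spans[x, 1L]
      ly <- spans[y, 2L] - spans[y, 1L]
      if ((lx > 0 && ov > overlap_fraction * lx) ||
          (ly > 0 && ov > overlap_fraction * ly))
        linked[x, y] <- linked[y, x] <- TRUE
    }
    if (!any(linked)) break
    g2 <- igraph::graph_from_adjacency_matrix(linked, mode = "undirected")
    cl <- igraph::components(g2)$membership
    fams <- lapply(sort(unique(cl)), function(ci) {
      members <- do.call(rbind, lapply(fams[cl == ci], `[[`, "members"))
      list(members = members,
           span = c(min(members$qstart), max(members$qend)))
    })
  }
  # canonical order: by span start, then span end
  ord <- order(vapply(fams, function(f) f$span[1L], 0),
               vapply(fams, function(f) f$span[2L], 0))
  fams <- fams[ord]
  for (i in seq_along(fams)) {
    fams[[i]]$members <-
      fams[[i]]$members[order(-fams[[i]]$members$bitscore,
                              fams[[i]]$members$subject_id), , drop = FALSE]
    rownames(fams[[i]]$members) <- NULL
    fams[[i]]$family_id <- i
    class(fams[[i]]) <- "component_family"
  }
  fams
}

#' Assign an evolutionary origin to a component family
#'
#' The up-to-three best members by bitscore (ties by subject id) must agree
#' on one lineage; families with fewer than three members require
#' unanimity among what exists. Otherwise the family is `"unassigned"`.
#'
#' @param family a `component_family`.
#' @param top_n number of best members examined (default 3).
#' @return lineage name or `"unassigned"`.
#' @export
assign_family_origin <- function(family, top_n = 3L) {
  m <- family$members
  if (!nrow(m)) stop("empty component family")
  top <- utils::head(m[order(-m$bitscore, m$subject_id), ], top_n)
  lins <- unique(top$lineage)
  if (length(lins) == 1L && !is.na(lins)) lins else "unassigned"
}

#' Detect a chimeric protein from its component families
#'
#' A protein is chimeric when it carries at least two origin-assigned
#' component families of different lineages whose representative spans do
#' not satisfy the mutual >70% overlap rule. Domain labels (NTD/CTD) are
#' assigned by ascending span midpoint.
#'
#' @param query_id protein id.
#' @param families list from [group_component_families()].
#' @param overlap_fraction mutual-overlap threshold.
#' @param top_n for [assign_family_origin()].
#' @return list: `query_id`, `chimeric`, `domains` (data.frame of span and
#'   origin ordered N- to C-terminal), `ntd_origin`, `ctd_origin`.
#' @export
detect_chimeras <- function(query_id, families, overlap_fraction = 0.7,
                            top_n = 3L) {
  if (!length(families))
    return(list(query_id = query_id, chimeric = FALSE,
                domains = NULL, ntd_origin = NA_character_,
                ctd_origin = NA_character_))
  origin <- vapply(families, assign_family_origin, "", top_n = top_n)
  spans <- t(vapply(families, function(f) f$span, c(0, 0)))
  assigned <- which(origin != "unassigned")
  chimeric <- FALSE
  if (length(assigned) >= 2L) {
    for (a in assigned) for (b in assigned) {
      if (a >= b || origin[a] == origin[b]) next
      ov <- .overlap_len(spans[a, 1L], spans[a, 2L],
                         spans[b, 1L], spans[b, 2L])
      la <- spans[a, 2L] - spans[a, 1L]
      lb <- spans[b, 2L] - spans[b, 1L]
      mutual <- ov > overlap_fraction * la && ov > overlap_fraction * lb
      if (!mutual) chimeric <- TRUE
    }
  }
  mid <- rowMeans(spans)
  ord <- order(mid)
  domains <- data.frame(start = spans[ord, 1L], end = spans[ord, 2L],
                        origin = origin[ord], stringsAsFactors = FALSE)
  dom_assigned <- domains[domains$origin != "unassigned", , drop = FALSE]
  list(query_id = query_id, chimeric = chimeric, domains = domains,
       ntd_origin = if (chimeric) dom_assigned$origin[1L] else NA_character_,
       ctd_origin = if (chimeric)
         dom_assigned$origin[nrow(dom_assigned)] else NA_character_)
}
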