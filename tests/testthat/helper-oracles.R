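# Independent brute-force oracles used across the suite.  These are written
# naively on purpose and never call the implementation paths they check.

# -- Smith-Waterman local alignment with affine gaps (triple-loop DP) -----
oracle_sw_score <- function(a, b, open = 11, ext = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B <- get("BLOSUM62", envir = environment())
  x <- strsplit(a, "")[[1L]]
  y <- strsplit(b, "")[[1L]]
  n <- length(x); m <- length(y)
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)
  F_ <- matrix(-Inf, n + 1L, m + 1L)
  best <- 0
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      E[i, j] <- max(H[i, j - 1L] - open - ext, E[i, j - 1L] - ext)
      F_[i, j] <- max(H[i - 1L, j] - open - ext, F_[i - 1L, j] - ext)
      H[i, j] <- max(0, H[i - 1L, j - 1L] + B[x[i - 1L], y[j - 1L]],
                     E[i, j], F_[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# -- transitive closure of an admissibility relation (boolean powers) -----
oracle_closure_clusters <- function(adjacency) {
  n <- nrow(adjacency)
  reach <- (adjacency | t(adjacency)) | diag(TRUE, n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  # canonical cluster labels: index of first member
  apply(reach, 1L, function(r) min(which(r)))
}

# -- exhaustive per-column uniquely-shared-residue scan -------------------
oracle_unique_shared <- function(aln, focal, donor, excl, frac = 2 / 3) {
  hits <- list()
  for (j in seq_len(ncol(aln))) {
    f <- aln[focal, j]
    fu <- f[f != "-"]
    if (length(fu) == 0L) next
    cand <- unique(fu)
    found <- NULL
    best <- 0
    for (r in cand) {
      share <- sum(fu == r) / length(fu)
      if (share > best) { best <- share; found <- r }
    }
    if (best < frac) next
    r <- found
    if (!any(aln[donor, j] == r)) next
    e <- aln[excl, j]
    if (any(e == r)) next
    if (all(e == "-")) next
    hits[[length(hits) + 1L]] <- c(col = j - 1L, res = r)
  }
  hits
}

# -- naive two-stage chimera component grouping ---------------------------
oracle_group_components <- function(comp, frac = 0.7) {
  n <- nrow(comp)
  if (!n) return(list())
  ov <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2))
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j || lab[i] == lab[j]) next
      o <- ov(comp$qstart[i], comp$qend[i], comp$qstart[j], comp$qend[j])
      li <- comp$qend[i] - comp$qstart[i]
      lj <- comp$qend[j] - comp$qstart[j]
      if (o > frac * li && o > frac * lj) {
        lab[lab == lab[j]] <- lab[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  fams <- lapply(unique(lab), function(l) {
    rows <- which(lab == l)
    list(rows = rows, span = c(min(comp$qstart[rows]),
                               max(comp$qend[rows])))
  })
  # round-based inclusion merging: naive pairwise scan to find all linked
  # families, naive label propagation, rebuild, repeat until stable
  repeat {
    k <- length(fams)
    if (k < 2L) break
    flab <- seq_len(k)
    any_link <- FALSE
    repeat {
      moved <- FALSE
      for (x in seq_len(k)) for (y in seq_len(k)) {
        if (x == y || flab[x] == flab[y]) next
        sx <- fams[[x]]$span; sy <- fams[[y]]$span
        o <- ov(sx[1L], sx[2L], sy[1L], sy[2L])
        lx <- sx[2L] - sx[1L]; ly <- sy[2L] - sy[1L]
        if ((lx > 0 && o > frac * lx) || (ly > 0 && o > frac * ly)) {
          flab[flab == flab[y]] <- flab[x]
          moved <- TRUE; any_link <- TRUE
        }
      }
      if (!moved) break
    }
    if (!any_link) break
    fams <- lapply(unique(flab), function(l) {
      rows <- unlist(lapply(fams[flab == l], `[[`, "rows"))
      list(rows = rows,
           span = c(min(comp$qstart[rows]), max(comp$qend[rows])))
    })
  }
  fams
}

# canonical signature of a component-family partition: sorted member sets
family_signature <- function(fams, key_fun) {
  sigs <- vapply(fams, key_fun, "")
  sort(sigs)
}

# -- small sequence fixture helpers --------------------------------------
make_records <- function(ids, seqs, subcats = NULL, species = NULL) {
  if (is.null(subcats)) subcats <- rep("pennates", length(ids))
  if (is.null(species)) species <- paste0("sp_", subcats)
  data.frame(seq_id = ids, sub_category = subcats, species_id = species,
             library_id = species, residues = seqs, stringsAsFactors = FALSE)
}

random_protein <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               n, replace = TRUE), collapse = "")
}
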