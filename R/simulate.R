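#' Parameters for the synthetic dataset generator
#'
#' Defaults describe the study conditions the pipeline is validated under:
#' thirty protein families with planted donor origins (red-algal majority,
#' substantial green-algal minority, smaller aplastidic-stramenopile and
#' prokaryotic contributions), plastid-targeting fractions biased towards
#' the endosymbiotic donors, 30-50 residue N-terminal presequences with a
#' hydrophobic signal region and an ASAFAP-type motif, a 3% cross-library
#' contamination rate, six planted domain-fusion proteins, and expression
#' modules whose block correlation is independent of evolutionary origin.
#'
#' @param seed integer seed; fully determines every output.
#' @param families_per_origin named integer vector of family counts per
#'   donor lineage.
#' @param plastid_fraction_per_origin named probability vector that a family
#'   of each origin is plastid-targeted.
#' @param dual_fraction fraction of plastid-targeted families that are also
#'   mitochondrially targeted (dual).
#' @param mito_fraction fraction of non-plastid families with mitochondrial
#'   presequences.
#' @param substitution_rate_per_branch multiplier on reference branch
#'   lengths (expected substitutions per site per unit branch length).
#' @param indel_rate per-branch probability of one deletion event (1-6
#'   residues); indels are realised as deletions in a fixed ancestral
#'   column frame so that true alignments are exact.
#' @param contamination_rate probability that a transcriptome contig is
#'   copied verbatim into a foreign transcriptome library.
#' @param fragment_rate probability that a transcriptome contig is an
#'   assembly fragment missing 55-90 N-terminal residues of the mature
#'   protein (exercises alignment curation).
#' @param fusion_count number of chimeric fusion proteins planted.
#' @param presequence_length_range presequence length bounds (residues).
#' @param expression_block_correlation within-module correlation of the
#'   synthetic expression profiles, in `[-1, 1]`.
#' @param mature_length length of the ancestral mature protein.
#' @param n_conditions number of expression conditions.
#' @param include_haptophytes include haptophyte plastid-targeted members
#'   (grafted as sister to the pelagophyte/dictyochophyte clade, the planted
#'   serial-endosymbiosis signal).
#' @return list of class `simulation_params`.
#' @export
simulation_params <- function(seed = 1L,
                              families_per_origin = c(
                                red_algae = 12L, green_algae = 8L,
                                aplastidic_stramenopiles = 5L,
                                prokaryotes = 5L),
                              plastid_fraction_per_origin = c(
                                red_algae = 0.8, green_algae = 0.7,
                                aplastidic_stramenopiles = 0.35,
                                prokaryotes = 0.35),
                              dual_fraction = 0.15,
                              mito_fraction = 0.25,
                              substitution_rate_per_branch = 1,
                              indel_rate = 0.03,
                              contamination_rate = 0.015,
                              fragment_rate = 0.06,
                              fusion_count = 6L,
                              presequence_length_range = c(30L, 50L),
                              expression_block_correlation = 0.5,
                              mature_length = 240L,
                              n_conditions = 40L,
                              include_haptophytes = TRUE) {
  p <- as.list(environment())
  if (all(p$families_per_origin == 0L)) stop("empty design")
  probs <- c(p$plastid_fraction_per_origin, p$dual_fraction, p$mito_fraction,
             p$contamination_rate, p$fragment_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(p$families_per_origin < 0)) stop("family counts must be >= 0")
  if (abs(p$expression_block_correlation) > 1)
    stop("expression_block_correlation must lie in [-1, 1]")
  if (p$seed != round(p$seed)) stop("seed must be an integer")
  class(p) <- "simulation_params"
  p
}

#' Species table for the default simulated corpus
#'
#' One species per sub-category. Five ochrophyte sub-categories carry
#' complete genome libraries (seed-eligible); the remaining ochrophyte and
#' haptophyte sub-categories are transcriptome libraries (subject to
#' decontamination); donor/outgroup sub-categories form the reference
#' library (the uniref-like outgroup search space).
#'
#' @param taxonomy a [taxonomy_scheme()].
#' @return data.frame of `sub_category`, `species_id`, `library_id`,
#'   `library_type`.
#' @export
default_species_table <- function(taxonomy = default_taxonomy()) {
  genome_subcats <- c("pennates", "thalassiosirales", "pesc_clade",
                      "pelagophytes", "px_clade")
  ochro <- unlist(taxonomy$ochrophyte_groups, use.names = FALSE)
  hapto <- names(taxonomy$sub_categories)[
    taxonomy$sub_categories == "haptophytes"]
  outg <- names(taxonomy$sub_categories)[
    taxonomy$sub_categories %in% taxonomy$outgroup_lineages |
      taxonomy$sub_categories == "glaucophytes"]
  sub <- c(ochro, hapto, outg)
  type <- c(ifelse(ochro %in% genome_subcats, "genome", "transcriptome"),
            rep("transcriptome", length(hapto)),
            rep("reference", length(outg)))
  spp <- paste0("sp_", sub)
  data.frame(sub_category = sub, species_id = spp, library_id = spp,
             library_type = type, stringsAsFactors = FALSE)
}

#' Organism precedence for seed retention in the default corpus
#'
#' Genome species first (diatoms, then other groups), mirroring the rule
#' that the retained seed is chosen by a fixed organism preference list.
#' @return character vector of species ids.
#' @export
default_organism_precedence <- function() {
  paste0("sp_", c("pennates", "thalassiosirales", "pesc_clade",
                  "pelagophytes", "px_clade"))
}

#' Reference green-lineage topology
#'
#' Small rooted reference topology used to place the origin node of
#' residues uniquely shared with green algae.
#' @return `phylo` with labelled internal nodes.
#' @export
reference_green_topology <- function() {
  ape::read.tree(text = paste0(
    "((core_chlorophytes,prasinophytes)chlorophyta,streptophytes)",
    "green_algae;"))
}

#' Reference ochrophyte topology
#'
#' Rooted reference topology of the eleven ochrophyte sub-categories used
#' to place origin nodes of residues shared between haptophytes and
#' ochrophyte lineages.
#' @return `phylo` with labelled internal nodes.
#' @export
reference_ochrophyte_topology <- function() {
  ape::read.tree(text = paste0(
    "((px_clade,raphidophytes,pesc_clade)chrysista,",
    "(((pelagophytes,dictyochophytes)pelagophyte_dictyochophyte,",
    "bolidophytes)hypogyristea,",
    "(corethron,radial_centrics,thalassiosirales,polar_centrics,pennates)",
    "diatoms)hypogyristea_diatoms)ochrophytes;"))
}

# Gene-tree scaffold for a family of a given donor origin.  The ochrophyte
# clade is grafted as sister to the donor lineage's crown so that the
# family's deepest ochrophyte split lies inside the donor clade; other
# outgroup lineages attach at greater depth.
.family_tree_newick <- function(origin, include_haptophytes) {
  hypo <- if (include_haptophytes) {
    paste0("(((pelagophytes:0.05,dictyochophytes:0.05):0.03,",
           "(pavlovophytes:0.05,prymnesiales:0.05,isochrysidales:0.05)",
           ":0.06):0.02,bolidophytes:0.08):0.05")
  } else {
    "(pelagophytes:0.07,dictyochophytes:0.07,bolidophytes:0.08):0.05"
  }
  och <- paste0(
    "((px_clade:0.09,raphidophytes:0.09,pesc_clade:0.09):0.05,(", hypo,
    ",(corethron:0.08,radial_centrics:0.07,thalassiosirales:0.07,",
    "polar_centrics:0.07,pennates:0.07):0.05):0.04)")
  crowns <- c(
    red_algae = "(cyanidiales:0.14,florideophytes:0.12,porphyridiophytes:0.12)",
    green_algae = "(core_chlorophytes:0.12,prasinophytes:0.12,streptophytes:0.14)",
    aplastidic_stramenopiles =
      "(oomycetes:0.12,labyrinthulomycetes:0.13,slopalinids:0.13)",
    prokaryotes = "(cyanobacteria:0.13,actinobacteria:0.13,proteobacteria:0.13)",
    other_eukaryotes = "(opisthokonts:0.15,amoebozoa:0.15)",
    glaucophytes = "glaucophytes_sc"
  )
  if (!origin %in% names(crowns))
    stop("unsupported donor origin: ", origin)
  ingroup <- paste0("(", och, ":0.20,", crowns[[origin]], ":0.06):0.25")
  rest <- crowns[setdiff(names(crowns), c(origin, "glaucophytes"))]
  rest <- paste0(rest, ":", ifelse(names(rest) == "prokaryotes", 0.45, 0.25))
  paste0("(", paste(c(ingroup, rest), collapse = ","), ");")
}

.AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
         "F", "P", "S", "T", "W", "Y", "V")

# sample() that never falls into the length-1 integer trap
.resample <- function(x, size = 1L) x[sample.int(length(x), size)]

# Evolve a character-vector sequence along one branch (substitutions and
# at most one deletion), in the ancestral column frame.
.evolve_branch <- function(seq, brlen, rate, indel_rate) {
  alive <- which(seq != "-")
  if (!length(alive)) return(seq)
  nsub <- stats::rpois(1L, brlen * rate * length(alive))
  if (nsub > 0L) {
    pos <- sample(alive, min(nsub, length(alive)))
    for (p in pos) {
      seq[p] <- sample(setdiff(.AA, seq[p]), 1L)
    }
  }
  if (stats::runif(1L) < indel_rate && length(alive) > 12L) {
    len <- sample(1:6, 1L)
    start <- sample(seq_len(length(alive) - len), 1L)
    seq[alive[start:(start + len - 1L)]] <- "-"
  }
  seq
}

# Tip sequences for one family: evolve the ancestral mature sequence down
# the (pruned) gene tree.  Returns a character matrix in ancestral columns.
.evolve_family <- function(tree, ancestral, rate, indel_rate) {
  ntip <- length(tree$tip.label)
  seqs <- vector("list", ntip + tree$Nnode)
  root <- ntip + 1L
  seqs[[root]] <- ancestral
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1L]; b <- edges[k, 2L]
    bl <- tree$edge.length[which(tree$edge[, 1L] == a &
                                   tree$edge[, 2L] == b)][1L]
    seqs[[b]] <- .evolve_branch(seqs[[a]], bl, rate, indel_rate)
  }
  m <- do.call(rbind, seqs[seq_len(ntip)])
  rownames(m) <- tree$tip.label
  m
}

.HYDRO <- c("A", "L", "V", "F", "I", "W")

# Presequence grammar: M + hydrophobic signal + ASAFAP motif (+ internal M
# and an arginine-rich stretch for dual targeting) + transit region.
.make_presequence <- function(type, len_range) {
  len <- sample(len_range[1L]:len_range[2L], 1L)
  if (type == "mito") {
    body <- sample(c("R", "L", "S", "A", "K", "T", "G"), len - 1L,
                   replace = TRUE, prob = c(0.32, 0.14, 0.14, 0.14, 0.08,
                                            0.09, 0.09))
    return(paste(c("M", body), collapse = ""))
  }
  signal <- sample(.HYDRO, sample(10:14, 1L), replace = TRUE)
  head <- c("M", signal, strsplit("ASAFAP", "")[[1L]])
  core <- character(0)
  if (type == "plastid_dual") {
    # internal start codon followed by a strongly basic core, so that the
    # alternative N-terminus reads as a mitochondrial presequence
    head <- c(head, "M")
    core <- sample(c("R", "K", "S", "L"), 12L, replace = TRUE,
                   prob = c(0.6, 0.1, 0.15, 0.15))
  }
  remain <- len - length(head) - length(core)
  transit_pool <- if (type == "plastid_dual") {
    list(chars = c("R", "S", "T", "A", "G", "N", "P"),
         prob = c(0.35, 0.15, 0.12, 0.12, 0.1, 0.08, 0.08))
  } else {
    list(chars = c("S", "T", "A", "G", "N", "P", "K"),
         prob = c(0.22, 0.18, 0.18, 0.14, 0.1, 0.08, 0.1))
  }
  transit <- sample(transit_pool$chars, max(remain, 4L), replace = TRUE,
                    prob = transit_pool$prob)
  paste(c(head, core, transit), collapse = "")
}

#' Block-correlated expression profiles independent of any labelling
#'
#' Genes are assigned to co-expression modules at random; within a module
#' profiles share a latent factor with correlation `rho`. Because module
#' membership is random, the correlation structure is independent of any
#' gene annotation (such as evolutionary origin) — the null model used to
#' check the coexpression statistics.
#'
#' @param n_genes,n_conditions matrix dimensions.
#' @param rho within-module correlation in `[0, 1]`.
#' @param block_size genes per module.
#' @param gene_names optional row names.
#' @return numeric matrix genes x conditions.
#' @export
simulate_expression <- function(n_genes, n_conditions = 40L, rho = 0.5,
                                block_size = 6L, gene_names = NULL) {
  block <- sample(rep(seq_len(ceiling(n_genes / block_size)),
                      length.out = n_genes))
  f <- matrix(stats::rnorm(max(block) * n_conditions), nrow = max(block))
  eps <- matrix(stats::rnorm(n_genes * n_conditions), nrow = n_genes)
  expr <- sqrt(rho) * f[block, , drop = FALSE] + sqrt(1 - rho) * eps
  rownames(expr) <- if (is.null(gene_names))
    sprintf("g%03d", seq_len(n_genes)) else gene_names
  colnames(expr) <- sprintf("cond%02d", seq_len(n_conditions))
  expr
}

#' Generate a synthetic plastid-proteome dataset with planted truth
#'
#' Simulates protein families of known donor origin evolved along
#' origin-specific gene trees, adds targeting presequences, plants chimeric
#' fusion proteins and cross-library contamination, scores all
#' within-family similarities with the deterministic local-alignment
#' scorer, and emits an origin-independent block-correlated expression
#' matrix. The same seed reproduces every output exactly.
#'
#' @param params a [simulation_params()] object.
#' @param outdir optional directory; when given, all outputs are written as
#'   plain-text files (FASTA per library, hit TSV, alignments, Newick
#'   trees, expression and truth tables).
#' @param taxonomy a [taxonomy_scheme()].
#' @return list with elements `sequences` (data.frame over all libraries),
#'   `hits` (a [hit_table()]), `alignments` (named list of character
#'   matrices, mature region), `trees` (named list of `phylo`), `expression`
#'   (matrix), `truth` (data.frame), `families` (data.frame), `species`,
#'   `params`, `taxonomy`.
#' @export
simulate_dataset <- function(params = simulation_params(), outdir = NULL,
                             taxonomy = default_taxonomy()) {
  if (all(params$families_per_origin == 0L)) stop("empty design")
  set.seed(as.integer(params$seed))
  species <- default_species_table(taxonomy)
  fams <- data.frame(
    family = character(), origin = character(), targeting = character(),
    stringsAsFactors = FALSE)
  fid <- 0L
  for (org in names(params$families_per_origin)) {
    n <- params$families_per_origin[[org]]
    if (n == 0L) next
    for (i in seq_len(n)) {
      fid <- fid + 1L
      pl <- stats::runif(1L) < params$plastid_fraction_per_origin[[org]]
      targ <- if (pl) {
        if (stats::runif(1L) < params$dual_fraction) "dual" else "plastid"
      } else {
        if (stats::runif(1L) < params$mito_fraction) "mitochondrial" else
          "none"
      }
      fams <- rbind(fams, data.frame(
        family = sprintf("fam%02d", fid), origin = org, targeting = targ,
        stringsAsFactors = FALSE))
    }
  }
  sp_of <- stats::setNames(species$species_id, species$sub_category)
  type_of <- stats::setNames(species$library_type, species$sub_category)

  seq_rows <- list()
  truth_rows <- list()
  alignments <- list()
  trees <- list()
  hit_blocks <- list()

  for (i in seq_len(nrow(fams))) {
    fam <- fams$family[i]; org <- fams$origin[i]; targ <- fams$targeting[i]
    plastid_family <- targ %in% c("plastid", "dual")
    tr <- ape::read.tree(text = .family_tree_newick(
      org, params$include_haptophytes && plastid_family))
    keepers <- tr$tip.label
    lin <- lineage_of(keepers, taxonomy)
    keep_p <- ifelse(lin == "ochrophytes", 0.92,
                     ifelse(lin == "haptophytes", 0.85,
                            ifelse(lin == org, 1, 0.7)))
    keep <- stats::runif(length(keepers)) < keep_p
    # ensure enough ochrophytes for a meaningful family
    if (sum(keep & lin == "ochrophytes") < 6L)
      keep[lin == "ochrophytes"] <- TRUE
    tr <- ape::keep.tip(tr, keepers[keep])
    anc <- c("M", sample(.AA, params$mature_length - 1L, replace = TRUE))
    tips <- .evolve_family(tr, anc, params$substitution_rate_per_branch,
                           params$indel_rate)
    subcats <- rownames(tips)
    ids <- paste0(subcats, "|", sp_of[subcats], "|", fam)
    rownames(tips) <- ids
    tr$tip.label <- ids
    alignments[[fam]] <- tips
    trees[[fam]] <- tr
    for (j in seq_along(ids)) {
      sc <- subcats[j]
      mature <- paste(tips[j, tips[j, ] != "-"], collapse = "")
      is_och <- is_ochrophyte(sc, taxonomy)
      is_hap <- lineage_of(sc, taxonomy) == "haptophytes"
      seq_targ <- if ((is_och || is_hap) && targ != "none") targ else "none"
      pre <- ""
      if (seq_targ %in% c("plastid", "dual")) {
        pre <- .make_presequence(
          if (seq_targ == "dual") "plastid_dual" else "plastid",
          params$presequence_length_range)
      } else if (seq_targ == "mitochondrial") {
        pre <- .make_presequence("mito", params$presequence_length_range)
      }
      fragment <- FALSE
      if (type_of[sc] == "transcriptome" &&
          stats::runif(1L) < params$fragment_rate) {
        fragment <- TRUE
        cut <- sample(55:90, 1L)
        keep_cols <- which(tips[j, ] != "-")
        if (length(keep_cols) > cut + 40L) {
          drop_cols <- keep_cols[seq_len(cut)]
          tips[j, drop_cols] <- "-"
          alignments[[fam]][j, drop_cols] <- "-"
          mature <- paste(tips[j, tips[j, ] != "-"], collapse = "")
        } else fragment <- FALSE
      }
      seq_rows[[length(seq_rows) + 1L]] <- data.frame(
        seq_id = ids[j], sub_category = sc, species_id = sp_of[sc],
        library_id = sp_of[sc], residues = paste0(pre, mature),
        stringsAsFactors = FALSE)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        seq_id = ids[j], family = fam, origin = org, targeting = seq_targ,
        fragment = fragment, contaminant = FALSE,
        source_library = NA_character_, is_fusion = FALSE,
        breakpoint = NA_integer_, ntd_origin = NA_character_,
        ctd_origin = NA_character_, stringsAsFactors = FALSE)
    }
  }
  sequences <- do.call(rbind, seq_rows)
  truth <- do.call(rbind, truth_rows)

  # planted chimeric fusion proteins, hosted in a transcriptome ochrophyte
  # species present in both parent families (built from that species' own
  # copies, so cross-library identities stay at between-species levels)
  fusion_specs <- list()
  if (params$fusion_count > 0L) {
    origins <- unique(fams$origin)
    host_pref <- c("raphidophytes", "corethron", "radial_centrics",
                   "polar_centrics", "bolidophytes", "dictyochophytes")
    if (length(origins) >= 2L && nrow(fams) >= 2L) {
      for (k in seq_len(params$fusion_count)) {
        pair <- c(.resample(fams$family[fams$origin == .resample(origins)]),
                  NA)
        o1 <- fams$origin[fams$family == pair[1L]]
        cand <- fams$family[fams$origin != o1]
        pair[2L] <- .resample(cand)
        o2 <- fams$origin[fams$family == pair[2L]]
        subcat_of_rows <- function(f) sub("\\|.*$", "", rownames(
          alignments[[f]]))
        shared <- intersect(subcat_of_rows(pair[1L]),
                            subcat_of_rows(pair[2L]))
        host <- c(intersect(host_pref, shared), shared)[1L]
        if (is.na(host)) next
        host_row <- function(f) {
          m <- alignments[[f]]
          r <- grep(paste0("^", host, "\\|"), rownames(m))[1L]
          paste(m[r, m[r, ] != "-"], collapse = "")
        }
        matA <- host_row(pair[1L]); matB <- host_row(pair[2L])
        pre <- .make_presequence("plastid", params$presequence_length_range)
        fus_id <- paste0(host, "|", sp_of[host], "|fusion",
                         sprintf("%02d", k))
        fus_seq <- paste0(pre, matA, matB)
        sequences <- rbind(sequences, data.frame(
          seq_id = fus_id, sub_category = host,
          species_id = sp_of[host], library_id = sp_of[host],
          residues = fus_seq, stringsAsFactors = FALSE))
        truth <- rbind(truth, data.frame(
          seq_id = fus_id, family = paste0("fusion", sprintf("%02d", k)),
          origin = NA_character_, targeting = "plastid", fragment = FALSE,
          contaminant = FALSE, source_library = NA_character_,
          is_fusion = TRUE, breakpoint = nchar(pre) + nchar(matA),
          ntd_origin = o1, ctd_origin = o2, stringsAsFactors = FALSE))
        fusion_specs[[length(fusion_specs) + 1L]] <-
          list(id = fus_id, fams = pair)
      }
    }
  }

  # cross-library contamination: verbatim copies into foreign transcriptome
  # libraries, relabelled as the destination species
  tlibs <- species[species$library_type == "transcriptome", ]
  cand <- which(sequences$library_id %in% tlibs$library_id &
                  !truth$is_fusion)
  contam <- cand[stats::runif(length(cand)) < params$contamination_rate]
  for (ci in contam) {
    src <- sequences[ci, ]
    dest <- tlibs[tlibs$library_id != src$library_id &
                    tlibs$library_id %in% sequences$library_id, ]
    if (!nrow(dest)) next
    d <- dest[sample(nrow(dest), 1L), ]
    new_id <- paste0(d$sub_category, "|", d$species_id, "|",
                     sub("^.*\\|", "", src$seq_id), "_c")
    sequences <- rbind(sequences, data.frame(
      seq_id = new_id, sub_category = d$sub_category,
      species_id = d$species_id, library_id = d$library_id,
      residues = src$residues, stringsAsFactors = FALSE))
    fam <- truth$family[truth$seq_id == src$seq_id]
    truth <- rbind(truth, data.frame(
      seq_id = new_id, family = fam,
      origin = truth$origin[truth$seq_id == src$seq_id],
      targeting = truth$targeting[truth$seq_id == src$seq_id],
      fragment = FALSE, contaminant = TRUE,
      source_library = src$library_id, is_fusion = FALSE,
      breakpoint = NA_integer_, ntd_origin = NA_character_,
      ctd_origin = NA_character_, stringsAsFactors = FALSE))
    m <- alignments[[fam]]
    src_row <- m[src$seq_id, , drop = FALSE]
    rownames(src_row) <- new_id
    alignments[[fam]] <- rbind(m, src_row)
  }
  rownames(sequences) <- NULL
  rownames(truth) <- NULL

  # within-family similarity hits (cross-family similarity is negligible by
  # construction and omitted)
  for (fam in names(alignments)) {
    members <- sequences[sequences$seq_id %in% rownames(alignments[[fam]]), ]
    if (nrow(members) >= 2L)
      hit_blocks[[fam]] <- compute_similarity_scores(members)
  }
  for (fs in fusion_specs) {
    pool <- sequences[sequences$seq_id %in%
                        c(fs$id,
                          rownames(alignments[[fs$fams[1L]]]),
                          rownames(alignments[[fs$fams[2L]]])), ]
    h <- compute_similarity_scores(pool)
    hit_blocks[[fs$id]] <- h[h$query_id == fs$id | h$subject_id == fs$id, ]
  }
  hits <- hit_table(do.call(rbind, lapply(hit_blocks, as.data.frame)))

  # origin-independent block-correlated expression profiles (one gene per
  # family, model-species copy)
  expr <- simulate_expression(nrow(fams), params$n_conditions,
                              abs(params$expression_block_correlation),
                              gene_names = fams$family)

  out <- list(sequences = sequences, hits = hits, alignments = alignments,
              trees = trees, expression = expr, truth = truth,
              families = fams, species = species, params = params,
              taxonomy = taxonomy)
  if (!is.null(outdir)) write_dataset(out, outdir)
  out
}

#' Write a simulated dataset to plain-text files
#'
#' @param dataset result of [simulate_dataset()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_dataset <- function(dataset, outdir) {
  dir.create(file.path(outdir, "libraries"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(outdir, "alignments"), showWarnings = FALSE)
  dir.create(file.path(outdir, "trees"), showWarnings = FALSE)
  for (lib in sort(unique(dataset$sequences$library_id))) {
    recs <- dataset$sequences[dataset$sequences$library_id == lib, ]
    recs <- recs[order(recs$seq_id), ]
    write_fasta(recs, file.path(outdir, "libraries", paste0(lib, ".fasta")))
  }
  write_hit_table(dataset$hits, file.path(outdir, "hits.tsv"))
  for (fam in sort(names(dataset$alignments))) {
    write_alignment(dataset$alignments[[fam]],
                    file.path(outdir, "alignments", paste0(fam, ".fasta")))
    ape::write.tree(dataset$trees[[fam]],
                    file.path(outdir, "trees", paste0(fam, ".nwk")))
  }
  utils::write.table(
    data.frame(family = rownames(dataset$expression),
               round(dataset$expression, 6), check.names = FALSE),
    file.path(outdir, "expression.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(dataset$truth, file.path(outdir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$species, file.path(outdir, "species.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
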