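#' Read protein sequences from FASTA
#'
#' Headers follow the `subcategory|species|seqid` dialect; the full header is
#' retained as the unique sequence identifier. Residues are upper-cased and
#' terminal `*` stop symbols stripped. Records with empty bodies are dropped
#' with a warning.
#'
#' @param path FASTA file.
#' @param library_id library label attached to every record; defaults to the
#'   species field of each header.
#' @param taxonomy a [taxonomy_scheme()]; headers with unknown sub-categories
#'   raise an error naming the offending line.
#' @return data.frame with columns `seq_id`, `sub_category`, `species_id`,
#'   `library_id`, `residues`.
#' @export
read_fasta <- function(path, library_id = NULL,
                       taxonomy = default_taxonomy()) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readAAStringSet(path)
  headers <- names(set)
  parts <- strsplit(headers, "|", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("malformed FASTA header (expected 'subcategory|species|seqid') in ",
         path, " at record ", bad[1L], ": ", headers[bad[1L]])
  sub <- vapply(parts, `[[`, "", 1L)
  spp <- vapply(parts, `[[`, "", 2L)
  unknown <- setdiff(unique(sub), names(taxonomy$sub_categories))
  if (length(unknown))
    stop("unknown sub-categories in ", path, ": ",
         paste(unknown, collapse = ", "))
  res <- toupper(as.character(set))
  res <- gsub("\\*+$", "", gsub("^\\*+", "", res))
  empty <- !nzchar(res)
  if (any(empty)) {
    warning(sum(empty), " empty record(s) dropped from ", path)
  }
  out <- data.frame(
    seq_id = headers, sub_category = sub, species_id = spp,
    library_id = if (is.null(library_id)) spp else library_id,
    residues = unname(res), stringsAsFactors = FALSE
  )
  out[!empty, , drop = FALSE]
}

#' Write protein sequences to FASTA
#'
#' Inverse of [read_fasta()]: the `seq_id` column (already in the
#' `subcategory|species|seqid` dialect) becomes the header.
#'
#' @param records data.frame as returned by [read_fasta()].
#' @param path output file.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$seq_id[i]), con)
    s <- records$residues[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a ranked similarity hit table
#'
#' Parses a 12-column BLAST `outfmt 6`-style TSV (`qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore`) with
#' 1-based inclusive coordinates, converting to the package's 0-based
#' half-open convention. Per-query hit lists are sorted by ascending expect
#' value, ties broken by descending bitscore then subject id, and ranked
#' from 1. Duplicate (query, subject, interval) rows keep the best-bitscore
#' row.
#'
#' @param path TSV file (no header row).
#' @return A `hit_table` data.frame; see [hit_table()].
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "numeric",
                                         "integer", "integer", "integer",
                                         "character", "character", "character",
                                         "character", "character", "numeric"))
  names(df) <- c("query_id", "subject_id", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                 "bitscore")
  for (col in c("qstart", "qend", "sstart", "send", "evalue")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v))
      stop("non-numeric value in column '", col, "' of ", path, " at row ",
           which(is.na(v))[1L])
    df[[col]] <- v
  }
  hit_table(data.frame(
    query_id = df$query_id, subject_id = df$subject_id,
    pident = df$pident,
    qstart = as.integer(df$qstart - 1L), qend = as.integer(df$qend),
    sstart = as.integer(df$sstart - 1L), send = as.integer(df$send),
    evalue = df$evalue, bitscore = df$bitscore, stringsAsFactors = FALSE
  ))
}

#' Construct a ranked hit table
#'
#' Normalises a data.frame of pairwise similarity hits (0-based half-open
#' intervals) into the canonical `hit_table`: duplicates collapsed to the
#' best-bitscore row, per-query sorting by (evalue ascending, bitscore
#' descending, subject id ascending), 1-based consecutive ranks.
#'
#' @param hits data.frame with columns `query_id`, `subject_id`, `pident`,
#'   `qstart`, `qend`, `sstart`, `send`, `evalue`, `bitscore`.
#' @return data.frame of class `hit_table` with an added `rank` column.
#' @export
hit_table <- function(hits) {
  need <- c("query_id", "subject_id", "pident", "qstart", "qend",
            "sstart", "send", "evalue", "bitscore")
  miss <- setdiff(need, names(hits))
  if (length(miss)) stop("hit table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(hits$evalue < 0)) stop("negative expect values in hit table")
  key <- paste(hits$query_id, hits$subject_id, hits$qstart, hits$qend,
               hits$sstart, hits$send, sep = "\r")
  if (anyDuplicated(key)) {
    ord <- order(key, -hits$bitscore)
    hits <- hits[ord, , drop = FALSE]
    keep <- !duplicated(key[ord])
    message("hit_table: collapsed ", sum(!keep), " duplicate row(s), ",
            "keeping best bitscore")
    hits <- hits[keep, , drop = FALSE]
  }
  ord <- order(hits$query_id, hits$evalue, -hits$bitscore, hits$subject_id,
               method = "radix")
  hits <- hits[ord, , drop = FALSE]
  hits$rank <- stats::ave(seq_len(nrow(hits)), hits$query_id,
                          FUN = seq_along)
  rownames(hits) <- NULL
  class(hits) <- c("hit_table", "data.frame")
  hits
}

#' Hits of one query, in rank order
#'
#' @param hits a `hit_table`.
#' @param query_id query identifier.
#' @return data.frame of this query's hits sorted by rank (possibly empty).
#' @export
hits_for_query <- function(hits, query_id) {
  out <- hits[hits$query_id == query_id, , drop = FALSE]
  out[order(out$rank), , drop = FALSE]
}

#' Write a hit table as BLAST outfmt-6-style TSV
#'
#' Converts intervals back to 1-based inclusive coordinates.
#'
#' @param hits a `hit_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  alen <- pmax(hits$qend - hits$qstart, hits$send - hits$sstart)
  out <- data.frame(
    hits$query_id, hits$subject_id, sprintf("%.2f", hits$pident),
    alen, 0L, 0L,
    hits$qstart + 1L, hits$qend, hits$sstart + 1L, hits$send,
    format(hits$evalue, digits = 3, scientific = TRUE, trim = TRUE),
    sprintf("%.1f", hits$bitscore)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene tree with lineage annotation
#'
#' Reads a Newick tree (support values allowed, unrooted input supported)
#' and attaches sub-category and lineage annotations for every leaf. Leaf
#' labels must either be known sub-category names or full
#' `subcategory|species|seqid` sequence identifiers.
#'
#' @param path Newick file.
#' @param taxonomy a [taxonomy_scheme()].
#' @return An `ape` `phylo` with attribute `leaf_info`, a data.frame of
#'   `label`, `sub_category`, `lineage`.
#' @export
read_tree <- function(path, taxonomy = default_taxonomy()) {
  tr <- ape::read.tree(path)
  annotate_tree(tr, taxonomy)
}

#' Attach sub-category/lineage annotation to a tree
#'
#' @param tree an `ape` `phylo`.
#' @inheritParams read_tree
#' @return the tree with a `leaf_info` attribute.
#' @export
annotate_tree <- function(tree, taxonomy = default_taxonomy()) {
  labs <- tree$tip.label
  sub <- ifelse(grepl("|", labs, fixed = TRUE),
                vapply(strsplit(labs, "|", fixed = TRUE), `[[`, "", 1L),
                labs)
  unknown <- setdiff(unique(sub), names(taxonomy$sub_categories))
  if (length(unknown))
    stop("tree leaves with unknown sub-categories: ",
         paste(unknown, collapse = ", "))
  attr(tree, "leaf_info") <- data.frame(
    label = labs, sub_category = sub,
    lineage = lineage_of(sub, taxonomy), stringsAsFactors = FALSE
  )
  tree
}

#' Read an aligned FASTA file as a character matrix
#'
#' @param path aligned FASTA; `-` is the gap character.
#' @return character matrix (rows = sequences, columns = alignment columns)
#'   with sequence identifiers as row names.
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  w <- unique(Biostrings::width(set))
  if (length(w) != 1L)
    stop("unequal sequence lengths in alignment ", path)
  m <- do.call(rbind, strsplit(toupper(as.character(set)), ""))
  rownames(m) <- names(set)
  m
}

#' Write a character-matrix alignment as aligned FASTA
#'
#' @param aln character matrix with row names.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  recs <- data.frame(seq_id = rownames(aln),
                     residues = apply(aln, 1L, paste, collapse = ""),
                     stringsAsFactors = FALSE)
  write_fasta(recs, path)
}
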