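#' Deterministic all-against-all local similarity scoring
#'
#' A reproducible stand-in for a BLASTp search over a small sequence set.
#' Every unordered pair of distinct sequences is aligned locally (BLOSUM62,
#' affine gap costs; Biostrings' Smith-Waterman implementation) and pairs
#' with a positive raw score are emitted as hits in both directions.
#' Bitscores follow the Karlin-Altschul transformation
#' `(lambda * S - ln K) / ln 2` with fixed gapped-BLOSUM62 constants, and
#' expect values are `m * n * 2^(-bitscore)` where `m`, `n` are the query
#' and subject lengths. Percent identity is computed over the local
#' alignment length. Self-hits are excluded and sequences shorter than
#' three residues are skipped with a warning.
#'
#' @param records sequence data.frame as from [read_fasta()].
#' @param gap_opening,gap_extension affine gap costs (positive; defaults 11
#'   and 1, matching the bitscore constants).
#' @param lambda,K Karlin-Altschul constants for the scoring system.
#' @param min_score minimum raw alignment score for a hit to be emitted
#'   (default: anything positive).
#' @return A [hit_table()] obeying the ranking invariants.
#' @export
compute_similarity_scores <- function(records, gap_opening = 11,
                                      gap_extension = 1, lambda = 0.267,
                                      K = 0.041, min_score = 1e-9) {
  if (nrow(records) < 2L) stop("need at least two sequences")
  len <- nchar(records$residues)
  short <- len < 3L
  if (any(short)) {
    warning("skipping ", sum(short), " sequence(s) shorter than 3 residues")
    records <- records[!short, , drop = FALSE]
    len <- len[!short]
  }
  n <- nrow(records)
  if (n < 2L) stop("need at least two sequences of length >= 3")
  idx <- utils::combn(n, 2L)
  pat <- Biostrings::AAStringSet(records$residues[idx[1L, ]])
  subj <- Biostrings::AAStringSet(records$residues[idx[2L, ]])
  aln <- Biostrings::pairwiseAlignment(
    pat, subj, type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  sc <- Biostrings::score(aln)
  keep <- sc >= min_score
  if (!any(keep)) {
    empty <- data.frame(query_id = character(), subject_id = character(),
                        pident = numeric(), qstart = integer(),
                        qend = integer(), sstart = integer(),
                        send = integer(), evalue = numeric(),
                        bitscore = numeric(), stringsAsFactors = FALSE)
    return(hit_table(empty))
  }
  i <- idx[1L, keep]; j <- idx[2L, keep]
  sc <- sc[keep]
  nm <- Biostrings::nmatch(aln)[keep]
  alen <- Biostrings::nchar(aln)[keep]
  ps <- Biostrings::start(Biostrings::pattern(aln))[keep]
  pw <- Biostrings::width(Biostrings::pattern(aln))[keep]
  ss <- Biostrings::start(Biostrings::subject(aln))[keep]
  sw <- Biostrings::width(Biostrings::subject(aln))[keep]
  bits <- (lambda * sc - log(K)) / log(2)
  ev <- len[i] * len[j] * 2^(-bits)
  pid <- 100 * nm / alen
  both <- data.frame(
    query_id = c(records$seq_id[i], records$seq_id[j]),
    subject_id = c(records$seq_id[j], records$seq_id[i]),
    pident = c(pid, pid),
    qstart = c(ps - 1L, ss - 1L), qend = c(ps + pw - 1L, ss + sw - 1L),
    sstart = c(ss - 1L, ps - 1L), send = c(ss + sw - 1L, ps + pw - 1L),
    evalue = c(ev, ev), bitscore = c(bits, bits),
    stringsAsFactors = FALSE
  )
  hit_table(both)
}
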