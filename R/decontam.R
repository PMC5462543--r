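#' Cross-library best-hit identity distribution
#'
#' For every contig of either library that has at least one similarity hit
#' against the other library, records the percent identity of its best such
#' hit (rank order, i.e. lowest expect value first). Identities are
#' histogrammed at one percentage-point resolution over `[0, 100]`; 100%
#' identities fall in the top `[99, 100]` bin. Between two clean libraries
#' the distribution is unimodal around the average between-species
#' identity; cross-contamination adds a second peak at ~100%.
#'
#' @param library_a,library_b library identifiers.
#' @param hits a [hit_table()] whose sequence ids carry library information.
#' @param library_of named character vector mapping seq_id to library_id.
#' @return list of class `identity_distribution` with `counts` (length 100,
#'   bins `[0,1), ..., [98,99), [99,100]`), `best` (named numeric of per-
#'   contig best cross-library identities), `pair`, and `no_evidence` flag.
#' @export
pairwise_identity_distribution <- function(library_a, library_b, hits,
                                           library_of) {
  ql <- library_of[hits$query_id]
  sl <- library_of[hits$subject_id]
  cross <- (ql == library_a & sl == library_b) |
    (ql == library_b & sl == library_a)
  h <- hits[which(cross), , drop = FALSE]
  if (nrow(h) == 0L) {
    out <- list(counts = integer(100L), best = stats::setNames(numeric(0),
                                                               character(0)),
                pair = c(library_a, library_b), no_evidence = TRUE)
    class(out) <- "identity_distribution"
    return(out)
  }
  h <- h[order(h$query_id, h$rank), ]
  first <- !duplicated(h$query_id)
  best <- stats::setNames(h$pident[first], h$query_id[first])
  bins <- pmin(floor(best), 99) + 1L
  counts <- tabulate(bins, nbins = 100L)
  out <- list(counts = counts, best = best,
              pair = c(library_a, library_b), no_evidence = FALSE)
  class(out) <- "identity_distribution"
  out
}

# centred moving average with shrinking windows at the edges
.smooth_counts <- function(x, window) {
  if (window <= 1L) return(as.numeric(x))
  half <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, 0)
}

#' Contamination threshold from an identity distribution
#'
#' Smooths the histogram with a centred moving average and looks for two
#' modes: a contamination peak whose position lies in the top `[99, 100]`
#' region and the clean mode immediately below it. The threshold
#' is the identity of the minimum bin strictly between the two peak
#' positions (ties broken towards the lowest identity). Returns `NA` when
#' the distribution is empty or effectively unimodal.
#'
#' @param dist an `identity_distribution` (or a bare counts vector of
#'   length 100).
#' @param window moving-average window in bins (default 3).
#' @return threshold percent identity (lower bin edge) or `NA_real_`.
#' @export
find_contamination_threshold <- function(dist, window = 3L) {
  counts <- if (inherits(dist, "identity_distribution")) dist$counts else
    dist
  if (length(counts) != 100L) stop("expected 100 histogram bins")
  if (sum(counts) == 0L) return(NA_real_)
  s <- .smooth_counts(counts, window)
  n <- length(s)
  # local maxima with plateau handling: a run of equal smoothed values
  # flanked by strictly smaller neighbours (or the array ends)
  peaks <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && s[j + 1L] == s[i]) j <- j + 1L
    left_ok <- i == 1L || s[i - 1L] < s[i]
    right_ok <- j == n || s[j + 1L] < s[i]
    if (left_ok && right_ok && s[i] > 0) peaks <- c(peaks, i)
    i <- j + 1L
  }
  if (length(peaks) < 2L) return(NA_real_)
  upper <- peaks[peaks >= 100L]     # bin 100 covers [99, 100]
  if (!length(upper)) return(NA_real_)
  upper <- max(upper)
  lower <- peaks[peaks < upper]
  if (!length(lower)) return(NA_real_)
  lower <- max(lower)   # the clean mode adjacent to the contamination peak
  if (upper - lower < 2L) return(NA_real_)
  valley <- (lower + 1L):(upper - 1L)
  thr_bin <- valley[which.min(s[valley])]   # ties -> lowest identity
  as.numeric(thr_bin - 1L)                  # lower edge of the bin
}

#' Remove cross-library contaminants
#'
#' Computes (or accepts) per-library-pair contamination thresholds and
#' removes every contig whose best cross-library identity exceeds the
#' threshold of any pair it is involved in. Pairs without a threshold
#' (unimodal distributions, no evidence) pass through unchanged.
#'
#' @param sequences sequence data.frame (with `seq_id`, `library_id`).
#' @param hits a [hit_table()] over those sequences.
#' @param libraries library ids to screen (default: all transcriptome-style
#'   libraries present in `sequences`); pairs are formed within this set.
#' @param thresholds optional precomputed data.frame (`library_a`,
#'   `library_b`, `threshold`); computed from the data when `NULL`.
#' @param window smoothing window for [find_contamination_threshold()].
#' @return list with `sequences` (filtered), `removed` (seq ids), `report`
#'   (per-library removed counts and fractions) and `thresholds`.
#' @export
remove_cross_contaminants <- function(sequences, hits,
                                      libraries = NULL, thresholds = NULL,
                                      window = 3L) {
  library_of <- stats::setNames(sequences$library_id, sequences$seq_id)
  if (is.null(libraries)) libraries <- sort(unique(sequences$library_id))
  removed <- character(0)
  thr_rows <- list()
  if (length(libraries) >= 2L) {
    prs <- utils::combn(sort(libraries), 2L)
    for (k in seq_len(ncol(prs))) {
      a <- prs[1L, k]; b <- prs[2L, k]
      if (!is.null(thresholds)) {
        row <- thresholds[(thresholds$library_a == a &
                             thresholds$library_b == b) |
                            (thresholds$library_a == b &
                               thresholds$library_b == a), ]
        thr <- if (nrow(row)) row$threshold[1L] else NA_real_
        if (!is.na(thr)) {
          d <- pairwise_identity_distribution(a, b, hits, library_of)
        } else d <- NULL
      } else {
        d <- pairwise_identity_distribution(a, b, hits, library_of)
        thr <- find_contamination_threshold(d, window)
      }
      thr_rows[[k]] <- data.frame(library_a = a, library_b = b,
                                  threshold = thr, stringsAsFactors = FALSE)
      if (!is.na(thr) && !is.null(d)) {
        bad <- names(d$best)[d$best > thr]
        removed <- union(removed, bad)
      }
    }
  }
  thr_df <- if (length(thr_rows)) do.call(rbind, thr_rows) else
    data.frame(library_a = character(), library_b = character(),
               threshold = numeric(), stringsAsFactors = FALSE)
  keep <- !(sequences$seq_id %in% removed)
  report <- do.call(rbind, lapply(libraries, function(l) {
    in_lib <- sequences$library_id == l
    data.frame(library_id = l, n = sum(in_lib),
               removed = sum(in_lib & !keep),
               fraction = if (sum(in_lib)) sum(in_lib & !keep) / sum(in_lib)
               else 0, stringsAsFactors = FALSE)
  }))
  list(sequences = sequences[keep, , drop = FALSE], removed = removed,
       report = report, thresholds = thr_df)
}
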