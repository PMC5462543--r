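#' Built-in plastid-targeting prediction
#'
#' Rule-based predictor for the synthetic presequence grammar: a sequence
#' is called plastid-targeted when an N-terminal hydrophobic signal region
#' is followed by an ASAFAP-type motif within the first
#' `max(presequence_length_range)` residues. The plastid score is the
#' hydrophobic fraction of the signal window preceding the motif (0 when no
#' motif is found). External predictor output can be supplied instead via
#' [read_predictions()].
#'
#' @param records sequence data.frame (see [read_fasta()]).
#' @param motif regular expression of the targeting motif.
#' @param search_window number of N-terminal residues searched.
#' @param min_hydrophobic_fraction minimum hydrophobic fraction of the
#'   region between the initiator methionine and the motif.
#' @return data.frame with `seq_id`, `plastid_call`, `plastid_score`.
#' @export
predict_plastid <- function(records, motif = "[AG]SAFAP",
                            search_window = 50L,
                            min_hydrophobic_fraction = 0.6) {
  hydro <- c("A", "L", "V", "F", "I", "W", "M", "C")
  one <- function(s) {
    if (!nzchar(s)) return(c(0, 0))
    head <- substr(s, 1L, search_window)
    m <- regexpr(motif, head)
    if (m < 0L) return(c(0, 0))
    sig <- strsplit(substr(s, 2L, m - 1L), "")[[1L]]
    if (length(sig) < 6L) return(c(0, 0))
    frac <- mean(sig %in% hydro)
    c(as.numeric(frac >= min_hydrophobic_fraction), frac)
  }
  res <- t(vapply(records$residues, one, c(0, 0), USE.NAMES = FALSE))
  data.frame(seq_id = records$seq_id, plastid_call = res[, 1L] > 0,
             plastid_score = res[, 2L], stringsAsFactors = FALSE)
}

#' Read external targeting predictions
#'
#' Adapter for external predictor output supplied as TSV with columns
#' `seq_id`, `tool_name`, `call`, `score`. Sequences absent from the file
#' are treated as not predicted (and reported via a message).
#'
#' @param path TSV file with a header row.
#' @param seq_ids sequence ids expected; missing ones are filled with
#'   `call = FALSE`, `score = 0`.
#' @return data.frame of `seq_id`, `tool_name`, `call`, `score`.
#' @export
read_predictions <- function(path, seq_ids = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("seq_id", "tool_name", "call", "score")
  if (!all(need %in% names(df)))
    stop("prediction TSV must have columns: ", paste(need, collapse = ", "))
  df$call <- as.logical(df$call)
  if (!is.null(seq_ids)) {
    missing <- setdiff(seq_ids, df$seq_id)
    if (length(missing)) {
      message(length(missing),
              " sequence(s) without external prediction; treated as ",
              "not predicted")
      df <- rbind(df, data.frame(seq_id = missing,
                                 tool_name = df$tool_name[1L],
                                 call = FALSE, score = 0,
                                 stringsAsFactors = FALSE))
    }
  }
  df
}

#' Built-in mitochondrial targeting scorer
#'
#' Scores an N-terminus in `[0, 1]` by the arginine content of its first 30
#' residues (`(n_R - 2) / 6`, clamped), emulating the behaviour of a
#' mitochondrial presequence predictor on the synthetic grammar, where
#' mitochondrial and dual-targeting presequences are arginine-rich.
#'
#' @param nterm character string (an N-terminal sequence).
#' @return numeric score in `[0, 1]`.
#' @export
mito_score_builtin <- function(nterm) {
  head <- strsplit(substr(nterm, 1L, 30L), "")[[1L]]
  nr <- sum(head == "R")
  min(1, max(0, (nr - 2) / 6))
}

#' Dual-targeting screen
#'
#' Scores the full-length N-terminus and, when a methionine exists at
#' precursor positions 2-31 (1-based), the truncated N-terminus starting at
#' the first such methionine (alternative translation initiation). The dual
#' call is positive iff the sequence is plastid-targeted and the maximum
#' available mitochondrial score reaches the cutoff (default 0.35).
#'
#' @param records sequence data.frame.
#' @param mito_scorer function mapping an N-terminal string to `[0, 1]`.
#' @param plastid external or built-in plastid predictions
#'   (default: [predict_plastid()] on `records`).
#' @param config a [pipeline_config()] (uses `mito_score_cutoff` and
#'   `downstream_met_window`).
#' @return data.frame with `seq_id`, `plastid_call`, `plastid_score`,
#'   `mito_score_full`, `mito_score_downstream` (NA when no downstream
#'   methionine), `dual_call`.
#' @export
screen_dual_targeting <- function(records, mito_scorer = mito_score_builtin,
                                  plastid = NULL,
                                  config = pipeline_config()) {
  if (is.null(plastid)) plastid <- predict_plastid(records)
  plastid <- plastid[match(records$seq_id, plastid$seq_id), ]
  w <- config$downstream_met_window
  full <- vapply(records$residues, function(s) mito_scorer(s), 0,
                 USE.NAMES = FALSE)
  down <- vapply(records$residues, function(s) {
    tail_ <- substr(s, 2L, w + 1L)
    m <- regexpr("M", tail_, fixed = TRUE)
    if (m < 0L) return(NA_real_)
    mito_scorer(substr(s, m + 1L, nchar(s)))
  }, 0, USE.NAMES = FALSE)
  best <- pmax(full, down, na.rm = TRUE)
  data.frame(
    seq_id = records$seq_id,
    plastid_call = plastid$plastid_call,
    plastid_score = plastid$plastid_score,
    mito_score_full = full, mito_score_downstream = down,
    dual_call = plastid$plastid_call & best >= config$mito_score_cutoff,
    stringsAsFactors = FALSE
  )
}

#' Consensus targeting call for a gene family
#'
#' For ochrophyte families a localisation is the consensus iff it is the
#' plurality call and is held by at least 2/3 of the members; for
#' three-member haptophyte families only the 2/3 rule applies. Otherwise
#' the family is `"unassigned"`.
#'
#' @param calls character vector of per-member localisation calls (e.g.
#'   `"plastid"`, `"mitochondrial"`, `"dual"`, `"none"`).
#' @param family_size_class `"ochrophyte"` (plurality + 2/3) or
#'   `"haptophyte"` (2/3 only).
#' @param config a [pipeline_config()].
#' @return single consensus call, or `"unassigned"`.
#' @export
family_targeting_consensus <- function(calls,
                                       family_size_class = c("ochrophyte",
                                                             "haptophyte"),
                                       config = pipeline_config()) {
  family_size_class <- match.arg(family_size_class)
  if (!length(calls)) stop("need at least one prediction")
  tab <- sort(table(calls), decreasing = TRUE)
  frac <- tab[1L] / length(calls)
  if (frac < config$family_consensus_fraction) return("unassigned")
  if (family_size_class == "ochrophyte") {
    # plurality must be unique
    if (length(tab) > 1L && tab[2L] == tab[1L]) return("unassigned")
  }
  names(tab)[1L]
}
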