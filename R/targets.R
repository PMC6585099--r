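#' Consensus vote over miRNA-target prediction tables
#'
#' Retains a (miRNA, transcript) pair when it appears in at least
#' `min_votes` distinct prediction sources (default 8 of the classical 12
#' databases). Each table is deduplicated before voting, so a source
#' contributes at most one vote per pair.
#'
#' @param tables Named list of data frames, each with columns `mirna_id` and
#'   `transcript_id`; names are the source names and must be unique.
#' @param min_votes Minimum number of agreeing sources (default 8).
#' @return Data frame of class `consensus_targets` with columns `mirna_id`,
#'   `transcript_id`, `votes` (only pairs with votes >= `min_votes`), sorted
#'   by miRNA then transcript.
#' @export
consensus_targets <- function(tables, min_votes = 8) {
  if (!length(names(tables)) || any(names(tables) == "") ||
      anyDuplicated(names(tables))) {
    stop_("prediction tables must carry unique, non-empty source names")
  }
  if (length(tables) < min_votes) {
    stop_("need at least min_votes = ", min_votes, " tables; have ",
          length(tables))
  }
  pair_keys <- lapply(tables, function(tab) {
    if (!all(c("mirna_id", "transcript_id") %in% names(tab))) {
      stop_("each table needs columns mirna_id and transcript_id")
    }
    unique(paste(tab$mirna_id, tab$transcript_id, sep = "\r"))
  })
  votes <- table(unlist(pair_keys, use.names = FALSE))
  keep <- votes[votes >= min_votes]
  parts <- strsplit(names(keep), "\r", fixed = TRUE)
  out <- data.frame(
    mirna_id = vapply(parts, `[`, "", 1),
    transcript_id = vapply(parts, `[`, "", 2),
    votes = as.integer(keep),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$mirna_id, out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("consensus_targets", "data.frame")
  out
}

#' Count consensus targets per miRNA
#'
#' @param ct A `consensus_targets` data frame.
#' @return List with `per_mirna` (named integer vector of transcript counts
#'   per miRNA) and `union_count` (number of distinct transcripts across all
#'   miRNAs).
#' @export
count_targets_per_mirna <- function(ct) {
  if (nrow(ct) == 0) {
    return(list(per_mirna = stats::setNames(integer(0), character(0)),
                union_count = 0L))
  }
  per <- vapply(split(ct$transcript_id, ct$mirna_id),
                function(tx) length(unique(tx)), integer(1))
  list(per_mirna = per, union_count = length(unique(ct$transcript_id)))
}

#' Read per-source prediction tables from a directory
#'
#' Each `*.tsv` file in `dir` is one source (file name without extension =
#' source name) with columns `mirna_id` and `transcript_id`.
#'
#' @param dir Directory of TSV files.
#' @return Named list of data frames for \code{\link{consensus_targets}}.
#' @export
read_prediction_tables <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  if (!length(files)) stop_("no .tsv prediction tables in ", dir)
  tabs <- lapply(files, utils::read.delim, stringsAsFactors = FALSE)
  names(tabs) <- sub("\\.tsv$", "", basename(files))
  tabs
}
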