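#' @include utils.R
NULL

.asQualityReads <- function(reads) {
  if (is(reads, "QualityScaledDNAStringSet")) return(reads)
  stopf("reads must be a QualityScaledDNAStringSet")
}

#' Positional deduplication of reads
#'
#' Reads are considered duplicates when bases 5 to 55 (1-based, inclusive; a
#' 51-nt key) are identical; identical keys are grouped transitively and one
#' uniformly random member of each group is kept (seeded). Reads shorter than
#' 55 nt are keyed on their sequence from base 5 to their end, a conservative
#' grouping that never indexes past the read. Output order is stable by the
#' first occurrence of each group.
#'
#' @param reads a `QualityScaledDNAStringSet` from one library.
#' @param seed integer seed for the survivor choice.
#' @return list with `reads` (the survivors) and `report` (input count,
#'   duplicates removed).
#' @examples
#' r <- Biostrings::QualityScaledDNAStringSet(
#'   Biostrings::DNAStringSet(c(a = strrep("ACGT", 20), b = strrep("ACGT", 20))),
#'   Biostrings::PhredQuality(c(a = strrep("I", 80), b = strrep("I", 80))))
#' deduplicateReads(r, seed = 1)$report
#' @export
deduplicateReads <- function(reads, seed = 1L) {
  reads <- .asQualityReads(reads)
  n <- length(reads)
  if (n == 0L)
    return(list(reads = reads,
                report = c(input = 0L, duplicates_removed = 0L)))
  s <- as.character(reads)
  key <- substr(s, 5L, pmin(55L, nchar(s)))
  groups <- split(seq_len(n), key)
  keep <- withSeed(seed, vapply(groups, function(idx) {
    if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
  }, integer(1)))
  first <- vapply(groups, `[`, integer(1), 1L)
  keep <- keep[order(first)]
  list(reads = reads[keep],
       report = c(input = n, duplicates_removed = n - length(keep)))
}

#' Trim low-quality 3' tails
#'
#' Removes, from each read, the 3' suffix maximizing
#' \eqn{\sum_i (t - q_i)} over the suffix (the standard BWA-style rule) with
#' Phred threshold `threshold`; when no suffix scores positively the read is
#' unchanged. Qualities are trimmed in lockstep. Reads trimmed to length zero
#' are retained as empty reads (dropped later by [filterByLength()]).
#'
#' @param reads a `QualityScaledDNAStringSet`.
#' @param threshold Phred threshold (default 10).
#' @return Trimmed `QualityScaledDNAStringSet`.
#' @export
trimQualityTails <- function(reads, threshold = 10L) {
  reads <- .asQualityReads(reads)
  if (length(reads) == 0L) return(reads)
  ql <- as.list(as(Biostrings::quality(reads), "IntegerList"))
  newLen <- cpp_quality_trim(ql, as.integer(threshold))
  subseq(reads, start = 1L, width = newLen)
}

#' Trim adapter contamination
#'
#' Scans each read for the best ungapped local match (+1 match / -3 mismatch,
#' both strands of every adapter) and, when the best score reaches
#' `minMatch` (default 16, the weak-match analog of VecScreen's terminal
#' threshold), truncates the read at the match start if the match lies in the
#' 3' half, or masks the matched span with N otherwise.
#'
#' @param reads a `QualityScaledDNAStringSet`.
#' @param adapters character vector of adapter sequences.
#' @param minMatch minimum ungapped match score to act on.
#' @return list with `reads` and `report` (`reads_adapter_trimmed` count).
#' @export
trimAdapters <- function(reads, adapters, minMatch = 16L) {
  reads <- .asQualityReads(reads)
  if (length(adapters) == 0L) stopf("adapters must be non-empty")
  if (length(reads) == 0L)
    return(list(reads = reads, report = c(reads_adapter_trimmed = 0L)))
  both <- c(adapters, revCompChar(adapters))
  hits <- cpp_adapter_scan(as.character(reads), both, 1L, -3L)
  act <- hits[, 1] >= minMatch & width(reads) > 0L
  if (!any(act))
    return(list(reads = reads, report = c(reads_adapter_trimmed = 0L)))
  s <- as.character(reads)
  q <- as.character(Biostrings::quality(reads))
  len <- nchar(s)
  mid <- (hits[, 2] + hits[, 3]) / 2
  for (i in which(act)) {
    if (mid[i] > len[i] / 2) {        # 3' half: truncate at match start
      s[i] <- substr(s[i], 1L, hits[i, 2] - 1L)
      q[i] <- substr(q[i], 1L, hits[i, 2] - 1L)
    } else {                          # 5'/interior: mask span with N
      substr(s[i], hits[i, 2], hits[i, 3]) <-
        strrep("N", hits[i, 3] - hits[i, 2] + 1L)
    }
  }
  out <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(s, names(reads))),
    Biostrings::PhredQuality(setNames(q, names(reads))))
  list(reads = out, report = c(reads_adapter_trimmed = sum(act)))
}

#' Drop short reads
#'
#' @param reads a `QualityScaledDNAStringSet`.
#' @param minLen minimum retained length (inclusive; default 50 nt).
#' @return list with `reads` and `report` (`reads_dropped_short`).
#' @export
filterByLength <- function(reads, minLen = 50L) {
  reads <- .asQualityReads(reads)
  keep <- width(reads) >= minLen
  list(reads = reads[keep],
       report = c(reads_dropped_short = sum(!keep)))
}

#' Clean one library of raw reads
#'
#' Applies, in order: positional deduplication (bases 5-55), Phred quality
#' tail trimming, adapter trimming and length filtering, and assembles a
#' cleaning report whose counts reconcile
#' (`input - duplicates_removed - reads_dropped_short = output`).
#'
#' @param reads a `QualityScaledDNAStringSet` for one library.
#' @param adapters adapter sequences to trim.
#' @param phred quality-trim threshold.
#' @param minLen length-filter threshold.
#' @param minMatch adapter match threshold.
#' @param seed seed for the dedup survivor choice.
#' @return list with `reads` (cleaned) and `report` (named counts).
#' @export
cleanReads <- function(reads, adapters = NULL, phred = 10L, minLen = 50L,
                       minMatch = 16L, seed = 1L) {
  dd <- deduplicateReads(reads, seed = seed)
  basesBefore <- sum(width(dd$reads))
  qt <- trimQualityTails(dd$reads, threshold = phred)
  basesTrimmed <- basesBefore - sum(width(qt))
  if (!is.null(adapters) && length(adapters)) {
    ad <- trimAdapters(qt, adapters, minMatch = minMatch)
  } else {
    ad <- list(reads = qt, report = c(reads_adapter_trimmed = 0L))
  }
  lf <- filterByLength(ad$reads, minLen = minLen)
  report <- c(dd$report, bases_trimmed_quality = basesTrimmed,
              ad$report, lf$report,
              output = length(lf$reads))
  stopifnot(report[["input"]] - report[["duplicates_removed"]] -
              report[["reads_dropped_short"]] == report[["output"]])
  list(reads = lf$reads, report = report)
}
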