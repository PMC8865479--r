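#' @include triage.R
NULL

#' Merge non-overlapping contigs from the same genome
#'
#' Contigs whose best viral hits target the same subject protein with
#' non-overlapping, order-consistent subject spans are joined in subject
#' order with a spacer of 10 N; contigs hit in the negative frame are
#' reverse-complemented first so the merged sequence is collinear with the
#' subject. Groups with conflicting orientations are left unmerged with a
#' warning.
#'
#' @param contigs named `DNAStringSet`.
#' @param hits hit table from [translatedSearch()] for these contigs.
#' @param spacer number of N characters between joined contigs.
#' @return `DNAStringSet` of merged plus untouched contigs; merged entries
#'   carry a `merged_from` metadata column.
#' @export
mergeContigs <- function(contigs, hits, spacer = 10L) {
  best <- bestHits(hits)
  best <- best[best$query %in% names(contigs), , drop = FALSE]
  merged <- character(); mergedFrom <- list()
  consumed <- character()
  for (subj in unique(best$subject)) {
    g <- best[best$subject == subj, , drop = FALSE]
    if (nrow(g) < 2L) next
    g <- g[order(g$sstart), , drop = FALSE]
    if (any(g$send[-nrow(g)] > g$sstart[-1L])) next  # overlapping spans
    if (length(unique(sign(g$frame))) > 1L) {
      warning("conflicting orientations for subject ", subj, "; not merged")
      next
    }
    pieces <- vapply(seq_len(nrow(g)), function(i) {
      s <- as.character(contigs[[g$query[i]]])
      if (g$frame[i] < 0) revCompChar(s) else s
    }, character(1))
    id <- paste(g$query, collapse = "+")
    merged[id] <- paste(pieces, collapse = strrep("N", spacer))
    mergedFrom[[id]] <- g$query
    consumed <- c(consumed, g$query)
  }
  keep <- setdiff(names(contigs), consumed)
  out <- c(Biostrings::DNAStringSet(merged),
           Biostrings::DNAStringSet(as.character(contigs[keep])))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    merged_from = IRanges::CharacterList(
      c(mergedFrom, as.list(keep))))
  out
}

#' Map reads to reference sequences
#'
#' Exact `minSeed`-mer anchors (several per read, both strands) followed by
#' ungapped evaluation at the anchored offset: a read maps when at least
#' `minFraction` of its bases align to the reference at `minIdentity` or
#' better. Each read is counted once, for its best-matching reference (ties
#' go to the earlier reference).
#'
#' @param reads named `DNAStringSet`/character.
#' @param references named `DNAStringSet`/character.
#' @param minSeed exact seed length (default 31).
#' @param minFraction minimum aligned fraction of the read (default 0.9).
#' @param minIdentity minimum identity over the aligned span (default 0.95).
#' @return list: `counts` (mapped reads per reference), `coverage` (per-base
#'   integer vectors), `assignments` (read, reference, span, strand,
#'   identity).
#' @export
mapReads <- function(reads, references, minSeed = 31L, minFraction = 0.9,
                     minIdentity = 0.95) {
  refs <- namedChars(references, "ref")
  rds <- namedChars(reads, "read")
  refLen <- nchar(refs)
  refInt <- lapply(refs, utf8ToInt)
  idx <- new.env(hash = TRUE, parent = emptyenv())
  for (r in seq_along(refs)) {
    n <- refLen[r] - minSeed + 1L
    if (n < 1L) next
    km <- substring(refs[r], seq_len(n), minSeed:refLen[r])
    for (i in seq_len(n)) {
      key <- km[i]
      idx[[key]] <- c(idx[[key]], r, i)
    }
  }
  counts <- setNames(integer(length(refs)), names(refs))
  covAdd <- lapply(refLen, function(L) integer(L + 1L))
  asg <- list()
  rcs <- revCompChar(rds)
  for (k in seq_along(rds)) {
    len <- nchar(rds[k])
    if (len < minSeed) next
    offs <- unique(c(seq(1L, len - minSeed + 1L, by = minSeed),
                     len - minSeed + 1L))
    bestScore <- -1L; bestRec <- NULL
    for (strand in c("+", "-")) {
      s <- if (strand == "+") rds[k] else rcs[k]
      sv <- NULL
      cand <- integer()
      for (o in offs) {
        h <- idx[[substr(s, o, o + minSeed - 1L)]]
        if (is.null(h)) next
        hr <- h[c(TRUE, FALSE)]; hi <- h[c(FALSE, TRUE)]
        cand <- c(cand, rbind(hr, hi - o + 1L))
      }
      if (!length(cand)) next
      cm <- matrix(cand, nrow = 2L)
      cm <- cm[, !duplicated(paste(cm[1L, ], cm[2L, ])), drop = FALSE]
      if (is.null(sv)) sv <- utf8ToInt(s)
      for (cidx in seq_len(ncol(cm))) {
        r <- cm[1L, cidx]; refStart <- cm[2L, cidx]
        rs <- max(1L, refStart)
        re <- min(refLen[r], refStart + len - 1L)
        nAln <- re - rs + 1L
        if (nAln < minFraction * len) next
        readFrom <- rs - refStart + 1L
        mts <- sum(refInt[[r]][rs:re] == sv[readFrom:(readFrom + nAln - 1L)])
        if (mts / nAln < minIdentity) next
        if (mts > bestScore) {
          bestScore <- mts
          bestRec <- list(r = r, rs = rs, re = re, strand = strand,
                          identity = mts / nAln)
        }
      }
    }
    if (!is.null(bestRec)) {
      r <- bestRec$r
      counts[r] <- counts[r] + 1L
      covAdd[[r]][bestRec$rs] <- covAdd[[r]][bestRec$rs] + 1L
      covAdd[[r]][bestRec$re + 1L] <- covAdd[[r]][bestRec$re + 1L] - 1L
      asg[[length(asg) + 1L]] <- data.frame(
        read = names(rds)[k], reference = names(refs)[r],
        ref_start = bestRec$rs, ref_end = bestRec$re,
        strand = bestRec$strand, identity = bestRec$identity,
        stringsAsFactors = FALSE)
    }
  }
  coverage <- lapply(seq_along(refs), function(r)
    cumsum(covAdd[[r]])[seq_len(refLen[r])])
  names(coverage) <- names(refs)
  list(counts = counts, coverage = coverage,
       assignments = if (length(asg)) do.call(rbind, asg) else
         data.frame(read = character(), reference = character(),
                    ref_start = integer(), ref_end = integer(),
                    strand = character(), identity = numeric(),
                    stringsAsFactors = FALSE))
}

# ORFs of one sequence; see predictOrfs() for the contract.
.orfsOne <- function(s, contigId, minSize, unit) {
  L <- nchar(s)
  res <- list()
  counter <- 0L
  for (strand in c("+", "-")) {
    src <- if (strand == "+") s else revCompChar(s)
    for (f in 1:3) {
      w <- L - f + 1L
      w <- w - (w %% 3L)
      if (w < 3L) next
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(substr(src, f, f + w - 1L)),
        if.fuzzy.codon = "X", no.init.codon = TRUE))
      ch <- strsplit(aa, "")[[1]]
      stops <- which(ch == "*")
      bounds <- c(0L, stops, length(ch) + 1L)
      for (b in seq_len(length(bounds) - 1L)) {
        s0 <- bounds[b] + 1L
        s1 <- bounds[b + 1L] - 1L
        if (s1 < s0) next
        hasStop <- bounds[b + 1L] <= length(ch)
        seg <- ch[s0:s1]
        mpos <- which(seg == "M")
        if (!length(mpos)) next
        a0 <- s0 + mpos[1L] - 1L
        nAA <- s1 - a0 + 1L
        ntLen <- if (hasStop) 3L * (nAA + 1L) else 3L * nAA
        okLen <- if (unit == "nt") ntLen >= minSize else nAA >= minSize
        if (!okLen) next
        startSrc <- (f - 1L) + 3L * (a0 - 1L)       # 0-based on src strand
        endSrc <- startSrc + ntLen
        if (strand == "+") {
          st <- startSrc; en <- endSrc
        } else {
          st <- L - endSrc; en <- L - startSrc
        }
        counter <- counter + 1L
        res[[counter]] <- data.frame(
          id = sprintf("%s_orf%03d", contigId, counter), contig_id = contigId,
          frame = if (strand == "+") f else -f, start = st, end = en,
          strand = strand, aa_sequence = paste(ch[a0:s1], collapse = ""),
          has_start = TRUE, has_stop = hasStop, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res)) do.call(rbind, res) else NULL
}

#' Predict ORFs in all six frames
#'
#' Reports, per stop-delimited frame segment, the maximal ORF starting at the
#' first ATG (so nested ORFs sharing a stop are suppressed) with nucleotide
#' length of at least `minSize` - the length including the stop codon, the
#' common gene-predictor convention; set `unit = "aa"` to threshold on the
#' amino-acid count instead. ORFs running into a contig edge without a stop
#' are reported with `has_stop = FALSE`. Start codons are restricted to ATG,
#' the genetic code is standard.
#'
#' @param contigs named `DNAStringSet`/character (one or many sequences).
#' @param minSize minimum size (nt including stop codon, or aa when
#'   `unit = "aa"`); default 300 nt.
#' @param unit `"nt"` (default) or `"aa"`.
#' @return data.frame: id, contig_id, frame, start, end (0-based half-open on
#'   the forward strand), strand, aa_sequence (stop excluded), has_start,
#'   has_stop.
#' @export
predictOrfs <- function(contigs, minSize = 300L, unit = c("nt", "aa")) {
  unit <- match.arg(unit)
  ss <- as.character(contigs)
  if (is.null(names(ss))) names(ss) <- sprintf("contig%04d", seq_along(ss))
  out <- lapply(seq_along(ss), function(i)
    .orfsOne(ss[i], names(ss)[i], minSize, unit))
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out)) do.call(rbind, c(out, make.row.names = FALSE)) else
    data.frame(id = character(), contig_id = character(), frame = integer(),
               start = integer(), end = integer(), strand = character(),
               aa_sequence = character(), has_start = logical(),
               has_stop = logical(), stringsAsFactors = FALSE)
}

#' Call hallmark genes on predicted ORFs
#'
#' Each ORF is scanned against all hallmark profiles; the best profile whose
#' score reaches its calibrated threshold yields the call. An ORF is a
#' complete hallmark CDS when it has both start and stop codons and the
#' profile is covered at 0.9 or better (the coverage guard keeps fragments
#' from being called complete).
#'
#' @param orfs data.frame from [predictOrfs()].
#' @param profiles hallmark profile list.
#' @param minOverlap minimum profile columns in a scanning window.
#' @param minCoverage minimum profile coverage for a call (complete CDSs
#'   additionally require 0.9).
#' @return data.frame: orf_id, contig_id, hallmark, profile_score,
#'   per_column, profile_coverage, complete_cds.
#' @export
callHallmarks <- function(orfs, profiles, minOverlap = 30L,
                          minCoverage = 0.5) {
  res <- list()
  for (i in seq_len(nrow(orfs))) {
    best <- NULL; bestPc <- -Inf
    for (pf in profiles) {
      sc <- pssmScan(orfs$aa_sequence[i], pf$matrix, minOverlap)
      if (is.finite(sc$perColumn) && sc$perColumn >= pf$threshold &&
          sc$coverage >= minCoverage && sc$perColumn > bestPc) {
        bestPc <- sc$perColumn
        best <- data.frame(
          orf_id = orfs$id[i], contig_id = orfs$contig_id[i],
          hallmark = pf$name, profile_score = sc$score,
          per_column = sc$perColumn, profile_coverage = sc$coverage,
          complete_cds = orfs$has_start[i] && orfs$has_stop[i] &&
            sc$coverage >= 0.9,
          stringsAsFactors = FALSE)
      }
    }
    if (!is.null(best)) res[[length(res) + 1L]] <- best
  }
  if (length(res)) do.call(rbind, res) else
    data.frame(orf_id = character(), contig_id = character(),
               hallmark = character(), profile_score = numeric(),
               per_column = numeric(), profile_coverage = numeric(),
               complete_cds = logical(), stringsAsFactors = FALSE)
}
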