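#' @include utils.R
NULL

# Verify a candidate suffix-prefix overlap of y (starting at position p of x).
# Returns c(score, oEff, contain) or NULL when it fails the thresholds.
.overlapScore <- function(xv, yv, p, minOverlap, minIdentity) {
  nx <- length(xv); ny <- length(yv)
  o <- nx - p + 1L
  oEff <- min(o, ny)
  if (oEff < minOverlap) return(NULL)
  m <- sum(xv[p:(p + oEff - 1L)] == yv[seq_len(oEff)])
  if (m / oEff < minIdentity) return(NULL)
  c(score = m, oEff = oEff, contain = as.integer(o >= ny))
}

.kmersOf <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character())
  substring(s, seq_len(n - k + 1L), k:n)
}

# register both strands of sequence i (current version) in the k-mer index;
# reverse-strand entries carry a negated sequence id
.indexAdd <- function(state, i) {
  ver <- state$version[i]
  km <- .kmersOf(state$char[[i]], state$seedLen)
  for (p in seq_along(km)) {
    key <- km[p]
    state$index[[key]] <- c(state$index[[key]], i, p, ver)
  }
  km <- .kmersOf(state$rc[[i]], state$seedLen)
  for (p in seq_along(km)) {
    key <- km[p]
    state$index[[key]] <- c(state$index[[key]], -i, p, ver)
  }
}

# all current (signed seq, pos) occurrences of a k-mer
.indexGet <- function(state, key) {
  v <- state$index[[key]]
  if (is.null(v)) return(NULL)
  m <- matrix(v, nrow = 3L)
  ai <- abs(m[1L, ])
  ok <- state$active[ai] & state$version[ai] == m[3L, ]
  if (!any(ok)) return(NULL)
  m[, ok, drop = FALSE]
}

.leftSeq <- function(state, si) {
  if (si > 0) state$seqs[[si]] else state$rcseqs[[-si]]
}

# candidate rows with `right` (given orientation) extending some left contig
# (either strand of the left, so head-to-head joins are found too)
.candRight <- function(state, right, minOverlap, minIdentity) {
  rows <- list()
  for (orient in 1:2) {
    y <- if (orient == 1L) state$seqs[[right]] else state$rcseqs[[right]]
    if (length(y) < max(state$seedLen, minOverlap)) next
    seed <- if (orient == 1L) state$seedF[right] else state$seedR[right]
    hit <- .indexGet(state, seed)
    if (is.null(hit)) next
    for (ci in seq_len(ncol(hit))) {
      si <- hit[1L, ci]; p <- hit[2L, ci]
      li <- abs(si)
      if (li == right) next
      sc <- .overlapScore(.leftSeq(state, si), y, p, minOverlap, minIdentity)
      if (!is.null(sc))
        rows[[length(rows) + 1L]] <- c(left = li,
                                       lorient = if (si > 0) 1L else 2L,
                                       right = right, orient = orient,
                                       p = p, sc,
                                       verL = state$version[li],
                                       verR = state$version[right])
    }
  }
  rows
}

# candidate rows with `left` (either strand) extended by any other active
# sequence: probe every active right's seeds against a throwaway index
.candLeft <- function(state, left, minOverlap, minIdentity) {
  local <- new.env(hash = TRUE, parent = emptyenv())
  km <- .kmersOf(state$char[[left]], state$seedLen)
  for (p in seq_along(km)) local[[km[p]]] <- c(local[[km[p]]], p)
  kmr <- .kmersOf(state$rc[[left]], state$seedLen)
  for (p in seq_along(kmr)) local[[kmr[p]]] <- c(local[[kmr[p]]], -p)
  rows <- list()
  for (right in which(state$active)) {
    if (right == left) next
    for (orient in 1:2) {
      y <- if (orient == 1L) state$seqs[[right]] else state$rcseqs[[right]]
      if (length(y) < max(state$seedLen, minOverlap)) next
      seed <- if (orient == 1L) state$seedF[right] else state$seedR[right]
      ps <- local[[seed]]
      if (is.null(ps)) next
      for (sp in ps) {
        lor <- if (sp > 0) 1L else 2L
        x <- if (sp > 0) state$seqs[[left]] else state$rcseqs[[left]]
        sc <- .overlapScore(x, y, abs(sp), minOverlap, minIdentity)
        if (!is.null(sc))
          rows[[length(rows) + 1L]] <- c(left = left, lorient = lor,
                                         right = right, orient = orient,
                                         p = abs(sp), sc,
                                         verL = state$version[left],
                                         verR = state$version[right])
      }
    }
  }
  rows
}

#' Greedy overlap-layout assembly of one library
#'
#' Repeatedly merges the pair of sequences (in either orientation) with the
#' highest-scoring suffix-prefix overlap of at least `minOverlap` nt at
#' `minIdentity` or better, until no qualifying merge remains; unmerged reads
#' become singlets. The overlap score is the number of matching bases; ties
#' are broken lexicographically by the ids of the joined sequences, so the
#' result is deterministic for a given input. Mismatches within an overlap
#' keep the left (extending) sequence's base. Candidate overlaps are anchored
#' on an exact `seedLen`-mer of the right sequence's prefix (hashed against
#' all suffixes), and full containments are merged as well.
#'
#' @param reads a named `DNAStringSet` (or `QualityScaledDNAStringSet`) of
#'   cleaned reads from one library.
#' @param minOverlap minimum overlap length (nt).
#' @param minIdentity minimum overlap identity.
#' @param seedLen exact seed anchoring candidate overlaps.
#' @param library library label stored on the contigs.
#' @return `DNAStringSet` of contigs with `mcols()` columns `library`,
#'   `members` (a `CharacterList` of read ids), `is_singlet` and
#'   `chimera_flag`.
#' @export
greedyAssemble <- function(reads, minOverlap = 35L, minIdentity = 0.98,
                           seedLen = 12L, library = NA_character_) {
  chars <- namedChars(reads, "r")
  n <- length(chars)
  if (n == 0L) {
    out <- Biostrings::DNAStringSet()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      library = character(), members = IRanges::CharacterList(),
      is_singlet = logical(), chimera_flag = logical())
    return(out)
  }
  state <- new.env(parent = emptyenv())
  state$seedLen <- as.integer(seedLen)
  state$char <- as.list(unname(chars))
  state$seqs <- lapply(state$char, utf8ToInt)
  state$rc <- as.list(revCompChar(unname(chars)))
  state$rcseqs <- lapply(state$rc, utf8ToInt)
  state$seedF <- vapply(state$char, substr, character(1), 1L, seedLen)
  state$seedR <- vapply(state$rc, substr, character(1), 1L, seedLen)
  state$active <- rep(TRUE, n)
  state$version <- rep(1L, n)
  state$members <- lapply(names(chars), function(x) x)
  state$label <- names(chars)
  state$index <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) .indexAdd(state, i)

  rows <- list()
  for (j in seq_len(n))
    rows <- c(rows, .candRight(state, j, minOverlap, minIdentity))
  tab <- if (length(rows)) do.call(rbind, rows) else NULL

  repeat {
    if (is.null(tab) || nrow(tab) == 0L) break
    ok <- state$active[tab[, "left"]] & state$active[tab[, "right"]] &
      state$version[tab[, "left"]] == tab[, "verL"] &
      state$version[tab[, "right"]] == tab[, "verR"] &
      tab[, "left"] != tab[, "right"]
    tab <- tab[ok, , drop = FALSE]
    if (nrow(tab) == 0L) break
    lab1 <- pmin(state$label[tab[, "left"]], state$label[tab[, "right"]])
    lab2 <- pmax(state$label[tab[, "left"]], state$label[tab[, "right"]])
    ord <- order(-tab[, "score"], lab1, lab2, tab[, "lorient"],
                 tab[, "orient"])
    b <- tab[ord[1L], ]
    li <- b[["left"]]; ri <- b[["right"]]
    x <- if (b[["lorient"]] == 1L) state$char[[li]] else state$rc[[li]]
    y <- if (b[["orient"]] == 1L) state$char[[ri]] else state$rc[[ri]]
    merged <- if (b[["contain"]] == 1L) x else
      paste0(x, substr(y, b[["oEff"]] + 1L, nchar(y)))
    # the merged contig replaces the left slot; versions invalidate old rows
    state$active[ri] <- FALSE
    state$version[li] <- state$version[li] + 1L
    state$char[[li]] <- merged
    state$seqs[[li]] <- utf8ToInt(merged)
    state$rc[[li]] <- revCompChar(merged)
    state$rcseqs[[li]] <- utf8ToInt(state$rc[[li]])
    state$seedF[li] <- substr(merged, 1L, seedLen)
    state$seedR[li] <- substr(state$rc[[li]], 1L, seedLen)
    state$members[[li]] <- c(state$members[[li]], state$members[[ri]])
    state$label[li] <- min(state$label[li], state$label[ri])
    .indexAdd(state, li)
    newRows <- c(.candRight(state, li, minOverlap, minIdentity),
                 .candLeft(state, li, minOverlap, minIdentity))
    if (length(newRows)) tab <- rbind(tab, do.call(rbind, newRows))
  }
  act <- which(state$active)
  seqs <- unlist(state$char[act])
  members <- state$members[act]
  out <- Biostrings::DNAStringSet(setNames(
    seqs, sprintf("%s_ctg%04d", ifelse(is.na(library), "lib", library),
                  seq_along(act))))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    library = library,
    members = IRanges::CharacterList(members),
    is_singlet = lengths(members) == 1L,
    chimera_flag = FALSE)
  out
}

#' Flag putative chimeric contigs
#'
#' A contig is flagged when the best hit of its 5' half and the best hit of
#' its 3' half (hit halves decided by the midpoint of the hit's nucleotide
#' span on the contig) come from different families, their query spans do not
#' overlap, and both E-values are below `eCutoff`.
#'
#' @param contigs `DNAStringSet` from [greedyAssemble()].
#' @param hits hit table from [translatedSearch()] for these contigs (must
#'   carry `qnt_start`/`qnt_end` nucleotide spans and `family`).
#' @param eCutoff E-value bound both half-hits must meet.
#' @return `contigs` with the `chimera_flag` metadata column updated.
#' @export
flagChimeras <- function(contigs, hits, eCutoff = 1e-5) {
  mc <- S4Vectors::mcols(contigs)
  flags <- logical(length(contigs))
  if (nrow(hits)) {
    hits <- hits[hits$evalue < eCutoff, , drop = FALSE]
    for (i in seq_along(contigs)) {
      h <- hits[hits$query == names(contigs)[i], , drop = FALSE]
      if (nrow(h) < 2L) next
      half <- width(contigs)[i] / 2
      m <- (h$qnt_start + h$qnt_end) / 2
      h5 <- h[m < half, , drop = FALSE]
      h3 <- h[m >= half, , drop = FALSE]
      if (!nrow(h5) || !nrow(h3)) next
      b5 <- h5[which.max(h5$bitscore), ]
      b3 <- h3[which.max(h3$bitscore), ]
      flags[i] <- !identical(b5$family, b3$family) &&
        (b5$qnt_end <= b3$qnt_start || b3$qnt_end <= b5$qnt_start)
    }
  }
  mc$chimera_flag <- flags
  S4Vectors::mcols(contigs) <- mc
  contigs
}
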