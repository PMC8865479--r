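#' @include utils.R AllClasses.R
NULL

#' Six-frame translation
#'
#' Translates a DNA sequence in frames +1..+3 (forward strand) and -1..-3
#' (reverse complement) under the standard genetic code; stop codons are
#' rendered `*`, fuzzy codons (any N) as `X`. Trailing partial codons are
#' dropped.
#'
#' @param seq a single DNA string (character or `DNAString`).
#' @return Named character vector of 6 amino-acid strings
#'   (`+1, +2, +3, -1, -2, -3`).
#' @examples
#' sixFrameTranslate("ATGGCC")[["+1"]]  # "MA"
#' @export
sixFrameTranslate <- function(seq) {
  fr <- .translateFrames(Biostrings::DNAStringSet(as.character(seq)))
  out <- vapply(fr$aa, `[`, character(1), 1L)
  names(out) <- fr$frameNames
  out
}

# Vectorized frame translation of a DNAStringSet; returns the 6 per-frame
# AAStringSets plus labels.
.translateFrames <- function(x) {
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  rc <- Biostrings::reverseComplement(x)
  aa <- lapply(frames, function(f) {
    src <- if (f > 0) x else rc
    off <- abs(f)
    w <- pmax(Biostrings::width(src) - off + 1L, 0L)
    w <- w - (w %% 3L)
    s <- Biostrings::subseq(src, start = pmin(off, Biostrings::width(src) + 1L),
                            width = w)
    Biostrings::translate(s, if.fuzzy.codon = "X", no.init.codon = TRUE)
  })
  list(aa = lapply(aa, as.character), frames = frames,
       frameNames = sprintf("%+d", frames))
}

# aa-frame span -> nucleotide span on the forward strand (0-based half-open)
.frameToNt <- function(frame, qstart, qend, L) {
  off <- abs(frame) - 1L
  nt0 <- off + 3L * qstart
  nt1 <- off + 3L * qend
  s <- ifelse(frame > 0, nt0, L - nt1)
  e <- ifelse(frame > 0, nt1, L - nt0)
  cbind(start = s, end = e)
}

#' Translated (or protein) homology search with Karlin-Altschul E-values
#'
#' Six-frame translates each query (unless `protein = TRUE`) and searches it
#' against a protein database with a seeded local aligner: exact 3-mer words
#' expanded to a BLOSUM62 neighbourhood at score `wordThreshold`, two-hit
#' diagonal triggering, ungapped X-drop extension, and full affine-gap
#' Smith-Waterman (open `gapOpen`, extend `gapExt`) on surviving pairs. Raw
#' scores `S` are converted to bits `S' = (lambda S - ln K)/ln 2` with the
#' gapped BLOSUM62 constants `lambda = 0.267`, `K = 0.041`, and
#' `E = m n 2^(-S')` with `m` the query frame length (aa) and `n` the total
#' database residues. Hits with `E < eCutoff` are reported, best hit per
#' query first.
#'
#' @param queries named `DNAStringSet`/character (or `AAStringSet` when
#'   `protein = TRUE`).
#' @param db `AAStringSet`, optionally with lineage metadata in `mcols()`.
#' @param eCutoff E-value cutoff (default 1e-5).
#' @param protein if TRUE, queries are proteins searched in frame 0.
#' @param wordThreshold,twoHitWindow,xDrop,ungappedTrigger seeding heuristics.
#' @param gapOpen,gapExt affine gap penalties.
#' @param minRawScore minimum raw score retained before E-value filtering.
#' @return data.frame of hits: query, subject, identity, length, mismatches,
#'   gaps, qstart, qend, sstart, send (0-based half-open, aa coordinates),
#'   evalue, bitscore, frame, db_role, raw_score, family, species and the
#'   nucleotide span `qnt_start`/`qnt_end` for translated queries.
#' @export
translatedSearch <- function(queries, db, eCutoff = 1e-5, protein = FALSE,
                             wordThreshold = 11L, twoHitWindow = 40L,
                             xDrop = 18L, ungappedTrigger = 38L,
                             gapOpen = 11L, gapExt = 1L, minRawScore = 25L) {
  if (length(db) == 0L || length(queries) == 0L) return(.emptyHits())
  qnames <- names(queries)
  if (is.null(qnames)) qnames <- sprintf("q%06d", seq_along(queries))
  if (protein) {
    frameStrings <- as.character(queries)
    frameOf <- rep(0L, length(queries))
    queryOf <- qnames
    qLen <- nchar(frameStrings)
    ntLen <- rep(NA_integer_, length(queries))
  } else {
    x <- Biostrings::DNAStringSet(as.character(queries))
    fr <- .translateFrames(x)
    frameStrings <- unlist(fr$aa, use.names = FALSE)
    frameOf <- rep(fr$frames, each = length(x))
    queryOf <- rep(qnames, times = 6L)
    qLen <- nchar(frameStrings)
    ntLen <- rep(Biostrings::width(x), times = 6L)
  }
  keep <- qLen >= 3L
  raw <- cpp_protein_search(frameStrings[keep], as.character(db),
                            blosumMatrix(), aaAlphabet(),
                            as.integer(wordThreshold),
                            as.integer(twoHitWindow), as.integer(xDrop),
                            as.integer(ungappedTrigger), as.integer(gapOpen),
                            as.integer(gapExt), as.integer(minRawScore))
  if (nrow(raw) == 0L) return(.emptyHits())
  fidx <- which(keep)[raw$query]
  m <- qLen[fidx]
  n <- sum(nchar(as.character(db)))
  bits <- bitScore(raw$raw_score)
  ev <- eValue(bits, m, n)
  mc <- S4Vectors::mcols(db)
  getmc <- function(col, default = NA_character_) {
    if (!is.null(mc) && col %in% colnames(mc)) as.character(mc[[col]])[raw$subject]
    else rep(default, nrow(raw))
  }
  hits <- data.frame(
    query = queryOf[fidx], subject = names(db)[raw$subject],
    identity = raw$nident / raw$length, length = raw$length,
    mismatches = raw$mismatches, gaps = raw$gaps,
    qstart = raw$qstart, qend = raw$qend,
    sstart = raw$sstart, send = raw$send,
    evalue = ev, bitscore = bits, frame = frameOf[fidx],
    db_role = getmc("db_role"), raw_score = raw$raw_score,
    family = getmc("family"), species = getmc("species"),
    stringsAsFactors = FALSE)
  if (!protein) {
    nt <- .frameToNt(hits$frame, hits$qstart, hits$qend, ntLen[fidx])
    hits$qnt_start <- nt[, "start"]
    hits$qnt_end <- nt[, "end"]
  } else {
    hits$qnt_start <- NA_integer_
    hits$qnt_end <- NA_integer_
  }
  hits <- hits[hits$evalue < eCutoff, , drop = FALSE]
  hits <- hits[order(hits$query, -hits$bitscore, -hits$identity,
                     hits$subject), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

.emptyHits <- function() {
  data.frame(query = character(), subject = character(), identity = numeric(),
             length = integer(), mismatches = integer(), gaps = integer(),
             qstart = integer(), qend = integer(), sstart = integer(),
             send = integer(), evalue = numeric(), bitscore = numeric(),
             frame = integer(), db_role = character(), raw_score = numeric(),
             family = character(), species = character(),
             qnt_start = integer(), qnt_end = integer(),
             stringsAsFactors = FALSE)
}

#' Best hit per query
#'
#' Highest bit score wins; ties broken by higher identity, then
#' lexicographic subject id.
#'
#' @param hits a hit table from [translatedSearch()].
#' @return One row per query.
#' @export
bestHits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  hits <- hits[order(hits$query, -hits$bitscore, -hits$identity,
                     hits$subject), , drop = FALSE]
  hits[!duplicated(hits$query), , drop = FALSE]
}

#' Competitive filtering against the non-virus decoy database
#'
#' Queries holding candidate viral hits are searched against the NVNR
#' database; a query's viral assignment is discarded when its best NVNR bit
#' score strictly exceeds its best viral bit score (ties favour the viral
#' assignment). With `removeOnAnyHit = TRUE` any NVNR hit below the E-value
#' cutoff removes the query instead.
#'
#' @param viralHits hit table (viral database) from [translatedSearch()].
#' @param queries the query sequences (superset is fine; subset by name).
#' @param nvnrDb NVNR `AAStringSet`.
#' @param eCutoff E-value cutoff for the NVNR search.
#' @param removeOnAnyHit alternative removal rule (see above).
#' @param ... further arguments to [translatedSearch()].
#' @return list: `hits` (retained viral hits), `removed` (data.frame of
#'   removed queries with competing bit scores), `nvnrHits`.
#' @export
competitiveFilter <- function(viralHits, queries, nvnrDb, eCutoff = 1e-5,
                              removeOnAnyHit = FALSE, ...) {
  if (nrow(viralHits) == 0L)
    return(list(hits = viralHits,
                removed = data.frame(query = character(),
                                     viral_bit = numeric(),
                                     nvnr_bit = numeric()),
                nvnrHits = .emptyHits()))
  qids <- unique(viralHits$query)
  qsub <- queries[names(queries) %in% qids]
  nh <- translatedSearch(qsub, nvnrDb, eCutoff = eCutoff, ...)
  bestV <- tapply(viralHits$bitscore, viralHits$query, max)
  bestN <- if (nrow(nh)) tapply(nh$bitscore, nh$query, max) else numeric()
  nv <- bestN[match(qids, names(bestN))]
  vv <- as.numeric(bestV[qids])
  out <- if (removeOnAnyHit) !is.na(nv) else !is.na(nv) & nv > vv
  removed <- data.frame(query = qids[out], viral_bit = vv[out],
                        nvnr_bit = as.numeric(nv[out]),
                        stringsAsFactors = FALSE)
  list(hits = viralHits[!viralHits$query %in% removed$query, , drop = FALSE],
       removed = removed, nvnrHits = nh)
}

# Best-window PSSM score of one amino-acid string against a profile.
# Alignment offsets allow partial overlap of at least minOverlap columns;
# residues missing from the profile alphabet (X, *) score -2.
pssmScan <- function(aa, mat, minOverlap = 30L) {
  W <- nrow(mat)
  chars <- strsplit(aa, "")[[1]]
  La <- length(chars)
  if (La < minOverlap) return(list(score = -Inf, coverage = 0, shift = NA))
  ridx <- match(chars, colnames(mat))
  best <- -Inf; bestShift <- NA; bestCov <- 0; bestPc <- -Inf
  for (s in (minOverlap - W):(La - minOverlap)) {
    p <- max(1L, 1L - s):min(W, La - s)
    r <- ridx[p + s]
    v <- numeric(length(p))
    ok <- !is.na(r)
    v[ok] <- mat[cbind(p[ok], r[ok])]
    v[!ok] <- -2
    sc <- sum(v)
    pc <- sc / length(p)
    if (pc > bestPc) {
      bestPc <- pc; best <- sc; bestShift <- s; bestCov <- length(p) / W
    }
  }
  list(score = best, perColumn = bestPc, coverage = bestCov,
       shift = bestShift)
}

#' Profile (PSSM) fallback for remote viral homologs
#'
#' Scans every six-frame translation of queries without a surviving viral
#' hit against each hallmark position-specific score matrix. The best-scoring
#' profile at or above its calibrated threshold yields a hit; an approximate
#' E-value `n_windows * 2^(-score)` is attached for ranking only.
#'
#' @param queries named `DNAStringSet`/character of unassigned sequences.
#' @param profiles list of hallmark profiles (see [buildDatabases()]).
#' @param minOverlap minimum profile columns covered by a window.
#' @param minCoverage minimum fraction of the profile a reported window must
#'   cover (short partial windows are not comparable to the calibrated
#'   threshold).
#' @return data.frame: query, hallmark, frame, score, per_column, coverage,
#'   evalue, family, species, db_role (`"viral"`), route
#'   (`"profile_fallback"`).
#' @export
profileFallback <- function(queries, profiles, minOverlap = 30L,
                            minCoverage = 0.6) {
  out <- list()
  qnames <- names(queries)
  x <- Biostrings::DNAStringSet(as.character(queries))
  fr <- .translateFrames(x)
  for (qi in seq_along(x)) {
    best <- NULL; bestPc <- -Inf
    for (pf in profiles) {
      for (f in seq_along(fr$frames)) {
        aa <- fr$aa[[f]][qi]
        if (nchar(aa) < minOverlap) next
        sc <- pssmScan(aa, pf$matrix, minOverlap)
        if (is.finite(sc$perColumn) && sc$perColumn >= pf$threshold &&
            sc$coverage >= minCoverage && sc$perColumn > bestPc) {
          bestPc <- sc$perColumn
          nWin <- nchar(aa) + nrow(pf$matrix)
          best <- data.frame(
            query = qnames[qi], hallmark = pf$name, frame = fr$frames[f],
            score = sc$score, per_column = sc$perColumn,
            coverage = sc$coverage,
            evalue = nWin * 2^(-sc$score), family = pf$family,
            species = pf$species, db_role = "viral",
            route = "profile_fallback", stringsAsFactors = FALSE)
        }
      }
    }
    if (!is.null(best)) out[[length(out) + 1L]] <- best
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(query = character(), hallmark = character(), frame = integer(),
               score = numeric(), per_column = numeric(),
               coverage = numeric(), evalue = numeric(),
               family = character(), species = character(),
               db_role = character(), route = character(),
               stringsAsFactors = FALSE)
}

#' Full triage of contigs/singlets
#'
#' The discovery chain: translated search against the viral proteome,
#' competitive confirmation against the NVNR decoys, then (optionally, for
#' queries left unassigned) the hallmark-profile fallback. Returns one
#' taxonomy assignment per surviving query; `n_reads` carries the number of
#' reads each query represents (contig member reads, 1 for singlets).
#'
#' @param queries named `DNAStringSet` of contigs and/or singlet reads.
#' @param viralDb,nvnrDb protein databases ([buildDatabases()]).
#' @param profiles hallmark profiles, or NULL to skip the fallback.
#' @param libraryOf named character: query id -> library.
#' @param memberCounts named integer: query id -> reads represented
#'   (default 1).
#' @param eCutoff E-value cutoff used in both searches.
#' @param removeOnAnyHit see [competitiveFilter()].
#' @param ... passed to [translatedSearch()].
#' @return list: `assignments` (query, library, family, species, n_reads,
#'   route), `viralHits`, `retained`, `removed`, `fallback`.
#' @export
triageSequences <- function(queries, viralDb, nvnrDb, profiles = NULL,
                            libraryOf = NULL, memberCounts = NULL,
                            eCutoff = 1e-5, removeOnAnyHit = FALSE, ...) {
  qnames <- names(queries)
  if (is.null(qnames)) stopf("queries must be named")
  if (is.null(libraryOf))
    libraryOf <- setNames(rep(NA_character_, length(queries)), qnames)
  if (is.null(memberCounts))
    memberCounts <- setNames(rep(1L, length(queries)), qnames)
  vh <- translatedSearch(queries, viralDb, eCutoff = eCutoff, ...)
  cf <- competitiveFilter(vh, queries, nvnrDb, eCutoff = eCutoff,
                          removeOnAnyHit = removeOnAnyHit, ...)
  best <- bestHits(cf$hits)
  assignments <- if (nrow(best)) data.frame(
    query = best$query, library = unname(libraryOf[best$query]),
    family = best$family, species = best$species,
    n_reads = as.integer(memberCounts[best$query]),
    route = "primary_search", stringsAsFactors = FALSE) else
      data.frame(query = character(), library = character(),
                 family = character(), species = character(),
                 n_reads = integer(), route = character(),
                 stringsAsFactors = FALSE)
  fb <- NULL
  if (!is.null(profiles)) {
    un <- setdiff(qnames, c(assignments$query, cf$removed$query))
    if (length(un)) {
      fb <- profileFallback(queries[un], profiles)
      if (nrow(fb))
        assignments <- rbind(assignments, data.frame(
          query = fb$query, library = unname(libraryOf[fb$query]),
          family = fb$family, species = fb$species,
          n_reads = as.integer(memberCounts[fb$query]),
          route = "profile_fallback", stringsAsFactors = FALSE))
    }
  }
  list(assignments = assignments, viralHits = vh, retained = cf$hits,
       removed = cf$removed, fallback = fb)
}

#' Tabulate taxonomy assignments into an abundance matrix
#'
#' `cell(library, taxon)` sums `n_reads` over assignments carrying that
#' lineage; optionally row-normalized to fractions.
#'
#' @param assignments data.frame from [triageSequences()].
#' @param lineage lineage table; any assigned taxon absent from it is an
#'   error.
#' @param level `"family"` or `"species"` columns.
#' @param libraries optional library set fixing the row order (zero rows
#'   allowed).
#' @param normalize return row fractions instead of counts.
#' @return An [AbundanceMatrix-class].
#' @export
tabulateAssignments <- function(assignments, lineage,
                                level = c("family", "species"),
                                libraries = NULL, normalize = FALSE) {
  level <- match.arg(level)
  taxa <- assignments[[level]]
  unknown <- setdiff(taxa, lineage[[level]])
  if (length(unknown))
    stopf("taxa not in the lineage table: %s", paste(unknown, collapse = ", "))
  if (is.null(libraries)) libraries <- sort(unique(assignments$library))
  taxaLevels <- sort(unique(taxa))
  m <- matrix(0L, nrow = length(libraries), ncol = length(taxaLevels),
              dimnames = list(libraries, taxaLevels))
  if (nrow(assignments)) {
    agg <- tapply(assignments$n_reads,
                  list(factor(assignments$library, levels = libraries),
                       factor(taxa, levels = taxaLevels)), sum)
    agg[is.na(agg)] <- 0
    m[] <- as.integer(agg)
  }
  am <- AbundanceMatrix(m, level = level)
  if (normalize) normalizeAbundance(am) else am
}
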