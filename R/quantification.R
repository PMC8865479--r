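#' @include triage.R annotation.R
NULL

#' Select phage-classified sequences
#'
#' Ids whose surviving taxonomy assignment falls under bacteriophage taxa
#' (families flagged as phage in the lineage table: the tailed-phage families
#' and Microviridae, plus phage-flagged profile placeholders).
#'
#' @param assignments data.frame from [triageSequences()].
#' @param lineage lineage table with the `phage` flag.
#' @return Character vector of query ids.
#' @export
selectPhageSequences <- function(assignments, lineage) {
  phageFams <- unique(lineage$family[lineage$phage])
  unique(assignments$query[assignments$family %in% phageFams])
}

#' Annotate ORFs against a protein catalogue
#'
#' Protein-protein (frame 0) search of predicted ORFs against the ARG or
#' functional-gene database; the best hit per ORF below the E-value cutoff is
#' reported with the catalogue metadata (drug class and resistance mechanism,
#' or pathway category) attached.
#'
#' @param orfs data.frame from [predictOrfs()].
#' @param db `AAStringSet` catalogue with metadata in `mcols()`.
#' @param eCutoff E-value cutoff (default 1e-5).
#' @param ... passed to [translatedSearch()].
#' @return data.frame: orf_id, contig_id, gene, evalue, bitscore, identity
#'   plus available metadata columns.
#' @export
annotateGenes <- function(orfs, db, eCutoff = 1e-5, ...) {
  if (nrow(orfs) == 0L || length(db) == 0L)
    return(data.frame(orf_id = character(), contig_id = character(),
                      gene = character(), evalue = numeric(),
                      bitscore = numeric(), identity = numeric(),
                      stringsAsFactors = FALSE))
  aa <- Biostrings::AAStringSet(setNames(orfs$aa_sequence, orfs$id))
  hits <- translatedSearch(aa, db, eCutoff = eCutoff, protein = TRUE, ...)
  best <- bestHits(hits)
  if (nrow(best) == 0L)
    return(data.frame(orf_id = character(), contig_id = character(),
                      gene = character(), evalue = numeric(),
                      bitscore = numeric(), identity = numeric(),
                      stringsAsFactors = FALSE))
  out <- data.frame(orf_id = best$query,
                    contig_id = orfs$contig_id[match(best$query, orfs$id)],
                    gene = best$subject, evalue = best$evalue,
                    bitscore = best$bitscore, identity = best$identity,
                    stringsAsFactors = FALSE)
  mc <- S4Vectors::mcols(db)
  for (col in setdiff(colnames(mc), "db_role"))
    out[[col]] <- as.character(mc[[col]])[match(out$gene, names(db))]
  out
}

#' Quantify annotated genes by read mapping
#'
#' Maps each library's raw reads onto the annotated ORF sequences (each read
#' counted once, best ORF) and normalizes read hits per library `N` and
#' coding length `L`: `ppm = hits * 1e6 / N` and
#' `fpkm = hits * 1e9 / (L * N)`. `N` is the raw (pre-cleaning) library read
#' count.
#'
#' @param geneCalls data.frame from [annotateGenes()].
#' @param orfSeqs named character/`DNAStringSet` of ORF nucleotide sequences
#'   (names = orf ids).
#' @param readsByLibrary named list of raw reads per library.
#' @param librarySizes named numeric of raw read counts per library
#'   (default: lengths of `readsByLibrary`).
#' @param mapCounts optional precomputed per-library mapped-read counts
#'   (named list: library -> named integer vector over ORF ids), e.g. from
#'   one [mapReads()] pass over a larger ORF set; when given, reads are not
#'   re-mapped here.
#' @param ... passed to [mapReads()].
#' @return data.frame (one row per gene x library): gene, library,
#'   read_hits, ppm, fpkm plus the catalogue metadata carried by `geneCalls`.
#' @export
quantifyGenes <- function(geneCalls, orfSeqs, readsByLibrary,
                          librarySizes = NULL, mapCounts = NULL, ...) {
  if (is.null(librarySizes))
    librarySizes <- vapply(readsByLibrary, length, numeric(1))
  if (any(librarySizes == 0)) stopf("library size N must be positive")
  orfSeqs <- orfSeqs[names(orfSeqs) %in% geneCalls$orf_id]
  if (length(orfSeqs) == 0L || nrow(geneCalls) == 0L)
    return(data.frame(gene = character(), library = character(),
                      read_hits = integer(), ppm = numeric(),
                      fpkm = numeric(), stringsAsFactors = FALSE))
  metaCols <- setdiff(colnames(geneCalls),
                      c("orf_id", "contig_id", "evalue", "bitscore",
                        "identity"))
  out <- list()
  for (lib in names(readsByLibrary)) {
    hits <- if (!is.null(mapCounts))
      setNames(as.integer(mapCounts[[lib]][names(orfSeqs)]), names(orfSeqs))
    else mapReads(readsByLibrary[[lib]], orfSeqs, ...)$counts
    hits[is.na(hits)] <- 0L
    N <- librarySizes[[lib]]
    L <- nchar(as.character(orfSeqs))
    perOrf <- data.frame(orf_id = names(orfSeqs), read_hits = as.integer(hits),
                         ppm = hits * 1e6 / N,
                         fpkm = hits * 1e9 / (L * N),
                         stringsAsFactors = FALSE)
    perOrf <- merge(perOrf, geneCalls[, c("orf_id", metaCols)], by = "orf_id")
    agg <- lapply(split(perOrf, perOrf$gene), function(g) {
      row <- g[1L, metaCols, drop = FALSE]
      cbind(data.frame(library = lib,
                       read_hits = sum(g$read_hits),
                       ppm = sum(g$ppm), fpkm = sum(g$fpkm),
                       stringsAsFactors = FALSE), row)
    })
    out[[lib]] <- do.call(rbind, c(agg, make.row.names = FALSE))
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  rownames(res) <- NULL
  res
}

#' Aggregate gene abundances by class
#'
#' Sums ppm per library over a grouping column (`drug_class`, `mechanism` or
#' `category`) and reports per-library proportions (normalized to 1).
#'
#' @param abundances data.frame from [quantifyGenes()].
#' @param by grouping column name.
#' @return data.frame: library, class, ppm, proportion.
#' @export
aggregateAbundance <- function(abundances,
                               by = c("drug_class", "mechanism", "category")) {
  by <- match.arg(by)
  if (!by %in% colnames(abundances)) stopf("no column '%s'", by)
  agg <- stats::aggregate(abundances$ppm,
                          list(library = abundances$library,
                               class = abundances[[by]]), sum)
  names(agg)[3L] <- "ppm"
  tot <- tapply(agg$ppm, agg$library, sum)
  agg$proportion <- ifelse(tot[agg$library] > 0,
                           agg$ppm / as.numeric(tot[agg$library]), 0)
  agg[order(agg$library, -agg$ppm), ]
}

#' Group-exclusive and core genes
#'
#' A gene is exclusive to a group when it is detected (`ppm > 0`) in at least
#' one of the group's libraries and in none outside; core genes are detected
#' in every library.
#'
#' @param abundances data.frame from [quantifyGenes()].
#' @param groupLabels named character: library -> group.
#' @return list: `exclusives` (genes per group) and `core`.
#' @export
exclusiveGenes <- function(abundances, groupLabels) {
  libs <- unique(abundances$library)
  pres <- tapply(abundances$ppm > 0, list(abundances$gene,
                                          abundances$library), any)
  pres[is.na(pres)] <- FALSE
  exclusives <- lapply(unique(groupLabels[libs]), function(g) {
    inG <- libs[groupLabels[libs] == g]
    outG <- setdiff(libs, inG)
    sel <- rowSums(pres[, inG, drop = FALSE]) > 0 &
      rowSums(pres[, outG, drop = FALSE]) == 0
    rownames(pres)[sel]
  })
  names(exclusives) <- unique(groupLabels[libs])
  core <- rownames(pres)[rowSums(pres[, libs, drop = FALSE]) == length(libs)]
  list(exclusives = exclusives, core = core)
}
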