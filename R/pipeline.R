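#' @include synthetic-data.R read-processing.R assembly.R triage.R
#' @include annotation.R ecology.R phylogenetics.R quantification.R io.R
NULL

# Assemble reads binned by (library, assigned species), capping each bin at
# `binCap` reads: a desk-scale subassembly that concentrates coverage where
# ORF reconstruction is needed.
.binnedAssembly <- function(reads, assignments, binCap = 200L,
                            minOverlap = 35L, minIdentity = 0.98) {
  contigs <- list()
  asg <- assignments[order(assignments$query), , drop = FALSE]
  bins <- split(asg$query, paste(asg$library, asg$species, sep = "::"))
  for (b in names(bins)) {
    ids <- bins[[b]]
    if (length(ids) > binCap) ids <- ids[seq_len(binCap)]
    lib <- sub("::.*$", "", b)
    sub <- reads[[lib]][names(reads[[lib]]) %in% ids]
    if (length(sub) < 2L) next
    ctg <- greedyAssemble(Biostrings::DNAStringSet(as.character(sub)),
                          minOverlap = minOverlap,
                          minIdentity = minIdentity, library = lib)
    ctg <- ctg[!S4Vectors::mcols(ctg)$is_singlet]
    if (length(ctg)) {
      names(ctg) <- sprintf("%s_%04d", gsub("[^A-Za-z0-9_]+", "_", b),
                            seq_along(ctg))
      contigs[[b]] <- ctg
    }
  }
  if (!length(contigs)) return(Biostrings::DNAStringSet())
  out <- do.call(c, unname(lapply(contigs, function(x)
    Biostrings::DNAStringSet(setNames(as.character(x), names(x))))))
  libs <- rep(vapply(names(contigs), function(b) sub("::.*$", "", b),
                     character(1)), vapply(contigs, length, integer(1)))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(library = libs)
  out
}

#' Run the full virome pipeline on a simulated community
#'
#' Orchestrates every stage under one configuration and seed: simulate,
#' clean (dedup / quality trim / adapter trim / length filter), classify
#' (translated search + NVNR competitive filter, with the profile fallback
#' for assembled contigs), tabulate and analyze the viral community
#' (Bray-Curtis, UPGMA, PCoA, ANOSIM, shared species), reconstruct phage ORFs
#' (taxon-binned subassembly by default, or full per-library assembly before
#' triage when `assembleAll = TRUE` - practical for small libraries),
#' annotate hallmark genes, build hallmark trees, and quantify phage ARGs and
#' functional genes (ppm / FPKM, class aggregates, group exclusives).
#' Reruns with an identical configuration are reproducible; the report
#' carries every derived seed and per-stage counts.
#'
#' @param config a [SimConfig-class].
#' @param outDir output directory for tables/sequences/trees, or NULL for no
#'   file output.
#' @param assembleAll assemble each library fully before triage (classic
#'   order; quadratic in library size) instead of triaging reads as singlets
#'   and subassembling per assigned taxon.
#' @param useFallback apply the hallmark-profile fallback to unassigned
#'   contigs.
#' @param phred,minLen,eCutoff,minOverlap,minIdentity stage parameters for
#'   cleaning, searching and assembly.
#' @param minOrfSize,maxGapFraction,nPerm,decoyFraction,binCap stage
#'   parameters for annotation, phylogenetics, ANOSIM and subassembly.
#' @return list with the simulation, per-stage results and a `report` list of
#'   counts and seeds (also written as `report.json` under `outDir`).
#' @export
runPipeline <- function(config = simConfig(), outDir = NULL,
                        assembleAll = FALSE, useFallback = TRUE,
                        phred = 10L, minLen = 50L, eCutoff = 1e-5,
                        minOverlap = 35L, minIdentity = 0.98,
                        minOrfSize = 300L, maxGapFraction = 0.5,
                        nPerm = 999L, decoyFraction = 0.2, binCap = 200L) {
  seeds <- deriveSeeds(config@seed, c("clean", "anosim"))
  sim <- simulateVirome(config, decoyFraction = decoyFraction)
  libs <- config@libraries

  ## clean every library (blank control included)
  cleaned <- list(); reports <- list()
  adapters <- config@adapterSeq
  for (lib in names(sim@reads)) {
    cl <- cleanReads(sim@reads[[lib]], adapters = adapters, phred = phred,
                     minLen = minLen, seed = seeds[["clean"]])
    cleaned[[lib]] <- cl$reads
    reports[[lib]] <- cl$report
  }

  ## queries for triage
  if (assembleAll) {
    queries <- Biostrings::DNAStringSet()
    libraryOf <- character(); memberCounts <- integer()
    for (lib in names(cleaned)) {
      ctg <- greedyAssemble(Biostrings::DNAStringSet(
        as.character(cleaned[[lib]])), minOverlap = minOverlap,
        minIdentity = minIdentity, library = lib)
      queries <- c(queries, Biostrings::DNAStringSet(
        setNames(as.character(ctg), names(ctg))))
      libraryOf <- c(libraryOf, setNames(rep(lib, length(ctg)), names(ctg)))
      memberCounts <- c(memberCounts, setNames(
        lengths(S4Vectors::mcols(ctg)$members), names(ctg)))
    }
  } else {
    queries <- Biostrings::DNAStringSet(unlist(lapply(
      names(cleaned), function(lib) as.character(cleaned[[lib]]))))
    libraryOf <- setNames(rep(names(cleaned),
                              vapply(cleaned, length, integer(1))),
                          names(queries))
    memberCounts <- setNames(rep(1L, length(queries)), names(queries))
  }

  ## triage; the profile fallback is reserved for assembled contigs
  tri <- triageSequences(queries, sim@databases$viral, sim@databases$nvnr,
                         profiles = if (useFallback && assembleAll)
                           sim@profiles else NULL,
                         libraryOf = libraryOf,
                         memberCounts = memberCounts, eCutoff = eCutoff)
  asg <- tri$assignments
  controlViral <- sum(asg$library == "Control", na.rm = TRUE)
  asgLib <- asg[!is.na(asg$library) & asg$library %in% libs, , drop = FALSE]

  ## community tables + ecology
  famMat <- tabulateAssignments(asgLib, sim@lineage, level = "family",
                                libraries = libs)
  spMat <- tabulateAssignments(asgLib, sim@lineage, level = "species",
                               libraries = libs)
  ecology <- NULL
  if (all(rowSums(famMat@.Data) > 0) && nrow(famMat@.Data) >= 3) {
    d <- brayCurtis(famMat)
    ecology <- list(
      distance = d, upgma = upgmaTree(d), pcoa = pcoaOrdination(d),
      anosim = anosimTest(d, config@groupLabels[libs], nPerm = nPerm,
                          seed = seeds[["anosim"]]),
      shared = sharedSpecies(spMat, groups = config@groupLabels))
  }

  ## phage ORF reconstruction
  phageIds <- selectPhageSequences(asgLib, sim@lineage)
  if (assembleAll) {
    phageContigs <- queries[names(queries) %in% phageIds]
  } else {
    phageContigs <- .binnedAssembly(
      cleaned, asgLib[asgLib$query %in% phageIds, , drop = FALSE],
      binCap = binCap, minOverlap = minOverlap, minIdentity = minIdentity)
  }
  orfs <- predictOrfs(phageContigs, minSize = minOrfSize)
  hallmarks <- callHallmarks(orfs, sim@profiles)

  ## hallmark phylogenetics on complete CDSs
  trees <- list()
  if (nrow(hallmarks)) {
    complete <- hallmarks[hallmarks$complete_cds, , drop = FALSE]
    for (h in unique(complete$hallmark)) {
      ids <- complete$orf_id[complete$hallmark == h]
      aa <- setNames(orfs$aa_sequence[match(ids, orfs$id)], ids)
      aa <- aa[!duplicated(aa)]
      if (length(aa) < 3L) next
      msa <- filterGapColumns(progressiveAlign(aa),
                              maxGapFraction = maxGapFraction)
      trees[[h]] <- njTree(proteinDistance(msa))
    }
  }

  ## quantification of ARGs and functional genes on phage ORFs
  quant <- list()
  if (nrow(orfs)) {
    orfSeqs <- setNames(substring(as.character(phageContigs)[
      match(orfs$contig_id, names(phageContigs))],
      orfs$start + 1L, orfs$end), orfs$id)
    rawReads <- lapply(sim@reads[libs], as.character)
    librarySizes <- setNames(rep(config@readsPerLibrary, length(libs)), libs)
    # one mapping pass per library over the full phage ORF set
    mapCounts <- lapply(rawReads, function(r) mapReads(r, orfSeqs)$counts)
    for (dbrole in c("arg", "fun")) {
      calls <- annotateGenes(orfs, sim@databases[[dbrole]], eCutoff = eCutoff)
      if (nrow(calls) == 0L) next
      ab <- quantifyGenes(calls, orfSeqs[calls$orf_id], rawReads,
                          librarySizes = librarySizes,
                          mapCounts = mapCounts)
      quant[[dbrole]] <- list(
        abundance = ab,
        aggregates = if (dbrole == "arg") list(
          drug_class = aggregateAbundance(ab, "drug_class"),
          mechanism = aggregateAbundance(ab, "mechanism")) else list(
          category = aggregateAbundance(ab, "category")),
        exclusives = exclusiveGenes(ab, config@groupLabels))
    }
  }

  report <- list(
    seeds = as.list(c(master = config@seed, seeds)),
    cleaning = lapply(reports, as.list),
    queries = length(queries),
    assignments = nrow(asg),
    control_viral_assignments = controlViral,
    family_counts = as.list(rowSums(famMat@.Data)),
    anosim = if (!is.null(ecology)) list(R = ecology$anosim$statistic,
                                         p = ecology$anosim$p.value),
    shared_core_species = if (!is.null(ecology)) ecology$shared$core$count,
    phage_contigs = length(phageContigs),
    orfs = nrow(orfs),
    hallmark_calls = nrow(hallmarks),
    trees = names(trees),
    arg_genes = if (!is.null(quant$arg))
      length(unique(quant$arg$abundance$gene)) else 0L)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeSimConfig(config, file.path(outDir, "config.yaml"))
    writeTsv(asg, file.path(outDir, "assignments.tsv"))
    writeTsv(as.data.frame(famMat@.Data), file.path(outDir,
                                                    "family_counts.tsv"))
    if (!is.null(ecology)) {
      writeTsv(as.data.frame(ecology$distance), file.path(outDir,
                                                          "bray_curtis.tsv"))
      ape::write.tree(ecology$upgma, file.path(outDir, "upgma.nwk"))
    }
    for (h in names(trees))
      ape::write.tree(trees[[h]], file.path(outDir, sprintf("%s_nj.nwk", h)))
    if (!is.null(quant$arg))
      writeTsv(quant$arg$abundance, file.path(outDir, "arg_abundance.tsv"))
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  list(simulation = sim, cleaned = cleaned, reports = reports,
       triage = tri, familyMatrix = famMat, speciesMatrix = spMat,
       ecology = ecology, phageContigs = phageContigs, orfs = orfs,
       hallmarks = hallmarks, trees = trees, quant = quant, report = report)
}
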