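#' @include utils.R
NULL

#' Read / write FASTQ (Phred+33)
#'
#' Thin wrappers around Biostrings' quality-scaled string sets.
#'
#' @param path file path.
#' @param reads a `QualityScaledDNAStringSet`.
#' @return `readFastq` returns a `QualityScaledDNAStringSet`.
#' @export
readFastq <- function(path) {
  # the reader re-wraps the string set and emits a benign note about
  # dropped metadata columns; muffle just that
  withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' @rdname readFastq
#' @export
writeFastq <- function(reads, path) {
  Biostrings::writeXStringSet(as(reads, "DNAStringSet"), path,
                              format = "fastq",
                              qualities = Biostrings::quality(reads))
  invisible(path)
}

#' Write a data.frame as TSV
#'
#' @param x data.frame.
#' @param path file path.
#' @export
writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a hit table in 14-column tabular layout
#'
#' Mirrors the de facto tabular alignment format: query, subject, percent
#' identity, alignment length, mismatches, gap opens, q. start, q. end,
#' s. start, s. end, evalue, bit score, plus frame and database role.
#'
#' @param hits hit table from [translatedSearch()].
#' @param path file path.
#' @export
writeHitTable <- function(hits, path) {
  out <- data.frame(
    query = hits$query, subject = hits$subject,
    pident = round(100 * hits$identity, 2), length = hits$length,
    mismatches = hits$mismatches, gaps = hits$gaps,
    qstart = hits$qstart, qend = hits$qend,
    sstart = hits$sstart, send = hits$send,
    evalue = signif(hits$evalue, 3), bitscore = round(hits$bitscore, 1),
    frame = hits$frame, db_role = hits$db_role,
    stringsAsFactors = FALSE)
  writeTsv(out, path)
}

#' Serialize / restore a simulation configuration as YAML
#'
#' @param config a [SimConfig-class].
#' @param path file path.
#' @export
writeSimConfig <- function(config, path) {
  sl <- methods::slotNames(config)
  lst <- lapply(sl, function(s) {
    v <- methods::slot(config, s)
    if (is.matrix(v))
      list(families = colnames(v), libraries = rownames(v),
           values = as.vector(t(v)))
    else if (!is.null(names(v))) as.list(v)   # keep names (YAML map)
    else v
  })
  names(lst) <- sl
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Write a simulation bundle to disk
#'
#' Emits the standard file interface of the simulator: per-library FASTQ
#' (Phred+33), the four protein databases as FASTA, the lineage table and
#' ARG metadata as TSV, the ground-truth manifest as JSON and the
#' configuration echo as YAML.
#'
#' @param sim a [ViromeSimulation-class].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (lib in names(sim@reads))
    writeFastq(sim@reads[[lib]], file.path(dir, paste0(lib, ".fastq")))
  Biostrings::writeXStringSet(sim@genomes, file.path(dir, "genomes.fasta"))
  for (dbn in names(sim@databases))
    Biostrings::writeXStringSet(sim@databases[[dbn]],
                                file.path(dir, paste0("db_", dbn, ".fasta")))
  writeTsv(sim@lineage, file.path(dir, "lineage.tsv"))
  writeTsv(argCatalog()[, c("gene", "drug_class", "mechanism")],
           file.path(dir, "arg_metadata.tsv"))
  jsonlite::write_json(sim@manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  writeSimConfig(sim@config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname writeSimConfig
#' @export
readSimConfig <- function(path) {
  lst <- yaml::read_yaml(path)
  comp <- matrix(unlist(lst$composition$values),
                 nrow = length(lst$composition$libraries), byrow = TRUE,
                 dimnames = list(unlist(lst$composition$libraries),
                                 unlist(lst$composition$families)))
  simConfig(seed = lst$seed, libraries = unlist(lst$libraries),
            readLength = lst$readLength,
            readsPerLibrary = lst$readsPerLibrary, composition = comp,
            duplicateRate = lst$duplicateRate,
            partialDuplicates = lst$partialDuplicates,
            adapterSeq = lst$adapterSeq, adapterRate = lst$adapterRate,
            insertMean = lst$insertMean, insertSd = lst$insertSd,
            qualityStart = lst$qualityStart, qualityEnd = lst$qualityEnd,
            qualitySd = lst$qualitySd,
            groupLabels = unlist(lst$groupLabels),
            controlReads = lst$controlReads,
            speciesPerFamily = lst$speciesPerFamily)
}
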