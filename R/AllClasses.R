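#' @include utils.R
NULL

#' Simulation configuration
#'
#' Holds every knob of the synthetic-community generator: library layout,
#' per-library family composition, read geometry, duplicate/adapter artifact
#' rates and the positional quality-decay model. Defaults reproduce the study
#' conditions the package emulates: six virome libraries (two lizard host
#' species, PE and PT, across sites) of 250-bp reads plus a near-empty blank
#' control.
#'
#' @slot seed master seed; every downstream draw derives from it.
#' @slot libraries library identifiers (species_site).
#' @slot readLength read length in nt (250).
#' @slot readsPerLibrary reads emitted per library.
#' @slot composition numeric matrix, libraries x family labels, rows sum to 1.
#' @slot duplicateRate fraction of reads re-emitted as duplicates, in [0,1).
#' @slot partialDuplicates if TRUE duplicates are identical only over bases
#'   5-55 (stressing the positional dedup rule); default FALSE emits exact
#'   full-length copies.
#' @slot adapterSeq adapter sequence carried over into read-through 3' ends.
#' @slot adapterRate fraction of reads with adapter read-through.
#' @slot insertMean,insertSd fragment-size model for mate pairs (nt).
#' @slot qualityStart,qualityEnd,qualitySd linear positional Phred decay:
#'   mean quality at first/last cycle and per-base gaussian spread.
#' @slot groupLabels named character, library -> host species group (PE/PT).
#' @slot controlReads reads emitted for the blank control library.
#' @slot speciesPerFamily mock species generated per viral family.
#' @export
setClass("SimConfig", representation(
  seed = "integer", libraries = "character", readLength = "integer",
  readsPerLibrary = "integer", composition = "matrix",
  duplicateRate = "numeric", partialDuplicates = "logical",
  adapterSeq = "character", adapterRate = "numeric",
  insertMean = "numeric", insertSd = "numeric",
  qualityStart = "numeric", qualityEnd = "numeric", qualitySd = "numeric",
  groupLabels = "character", controlReads = "integer",
  speciesPerFamily = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (length(object@seed) != 1L) msg <- c(msg, "seed must be a single integer")
  if (object@readLength <= 55L)
    msg <- c(msg, "readLength must exceed 55 (the dedup window must exist)")
  if (object@duplicateRate < 0 || object@duplicateRate >= 1)
    msg <- c(msg, "duplicateRate must lie in [0, 1)")
  if (object@adapterRate < 0 || object@adapterRate > 1)
    msg <- c(msg, "adapterRate must lie in [0, 1]")
  comp <- object@composition
  if (!identical(rownames(comp), object@libraries))
    msg <- c(msg, "composition rows must match libraries")
  if (any(comp < 0)) msg <- c(msg, "composition proportions must be >= 0")
  if (any(abs(rowSums(comp) - 1) > 1e-9))
    msg <- c(msg, "each library's composition must sum to 1 (tolerance 1e-9)")
  if (!identical(sort(names(object@groupLabels)), sort(object@libraries)))
    msg <- c(msg, "groupLabels must be named by the libraries")
  if (length(msg)) msg else TRUE
})

#' Virome simulation bundle
#'
#' The full output of one simulator run: mock genomes with their gene map,
#' the derived protein databases and hallmark profiles, per-library reads, and
#' the ground-truth manifest used as the acceptance oracle.
#'
#' @slot config the [SimConfig-class] that produced the bundle.
#' @slot genomes `DNAStringSet` of mock genomes.
#' @slot genomeInfo data.frame: genome id, category, family, species.
#' @slot genes data.frame of planted ORFs (hallmark / ARG / functional / core
#'   genes) with genome coordinates and strand.
#' @slot lineage data.frame lineage table (realm/order/family/species + phage
#'   flag), including the profile-fallback placeholder taxa.
#' @slot databases list of `AAStringSet`s: `viral`, `nvnr`, `arg`, `fun`,
#'   each with metadata in `mcols()`.
#' @slot profiles list of hallmark PSSMs (see [buildDatabases()]).
#' @slot reads list of `QualityScaledDNAStringSet`, one per library (the blank
#'   control included).
#' @slot manifest list with `perRead`, `perLibrary` and `perGene` data.frames.
#' @export
setClass("ViromeSimulation", representation(
  config = "SimConfig", genomes = "ANY", genomeInfo = "data.frame",
  genes = "data.frame", lineage = "data.frame", databases = "list",
  profiles = "list", reads = "list", manifest = "list"
))

#' Libraries-by-taxa abundance matrix
#'
#' A numeric matrix of read counts (or row-normalized fractions) with
#' libraries as rows and taxa (family- or species-level) as columns; the basis
#' of all ecology and quantification outputs.
#'
#' @slot level `"family"` or `"species"`.
#' @slot normalized logical; TRUE when rows are fractions summing to 1.
#' @export
setClass("AbundanceMatrix", contains = "matrix",
         representation(level = "character", normalized = "logical"))

setValidity("AbundanceMatrix", function(object) {
  msg <- character()
  if (!object@level %in% c("family", "species", "gene"))
    msg <- c(msg, "level must be 'family', 'species' or 'gene'")
  if (any(object@.Data < 0)) msg <- c(msg, "abundances must be non-negative")
  if (!object@normalized && any(object@.Data != round(object@.Data)))
    msg <- c(msg, "unnormalized abundances must be integral counts")
  if (object@normalized) {
    rs <- rowSums(object@.Data)
    if (any(abs(rs[rs > 0] - 1) > 1e-9))
      msg <- c(msg, "normalized rows must sum to 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an abundance matrix
#'
#' @param counts numeric matrix, libraries x taxa.
#' @param level taxonomic level of the columns.
#' @param normalized whether `counts` holds row fractions rather than counts.
#' @return An [AbundanceMatrix-class].
#' @export
AbundanceMatrix <- function(counts, level = c("family", "species", "gene"),
                            normalized = FALSE) {
  level <- match.arg(level)
  counts <- as.matrix(counts)
  new("AbundanceMatrix", counts, level = level, normalized = normalized)
}

#' Row-normalize an abundance matrix to fractions
#'
#' @param x an [AbundanceMatrix-class] of counts.
#' @return An [AbundanceMatrix-class] whose non-empty rows sum to 1.
#' @export
normalizeAbundance <- function(x) {
  stopifnot(is(x, "AbundanceMatrix"))
  m <- x@.Data
  rs <- rowSums(m)
  m[rs > 0, ] <- m[rs > 0, , drop = FALSE] / rs[rs > 0]
  new("AbundanceMatrix", m, level = x@level, normalized = TRUE)
}

#' @describeIn AbundanceMatrix taxonomic level of the columns.
#' @param x an `AbundanceMatrix`.
#' @export
abundanceLevel <- function(x) x@level

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", length(object@libraries), "libraries +",
      "blank control,", object@readsPerLibrary, "reads/library,",
      object@readLength, "nt reads, seed", object@seed, "\n")
  cat("  families:", paste(colnames(object@composition), collapse = ", "), "\n")
  cat("  duplicate rate", object@duplicateRate, "| adapter rate",
      object@adapterRate, "\n")
})

setMethod("show", "ViromeSimulation", function(object) {
  cat("ViromeSimulation:", length(object@genomes), "genomes,",
      length(object@reads), "read libraries\n")
  for (db in names(object@databases))
    cat("  db", db, ":", length(object@databases[[db]]), "proteins\n")
  cat("  profiles:", paste(names(object@profiles), collapse = ", "), "\n")
})

setMethod("show", "AbundanceMatrix", function(object) {
  cat("AbundanceMatrix (", object@level, if (object@normalized)
    ", normalized", "): ", nrow(object), " libraries x ", ncol(object),
    " taxa\n", sep = "")
  print(head(object@.Data[, seq_len(min(6, ncol(object))), drop = FALSE]))
})

#' @rdname ViromeSimulation-class
#' @param x a `ViromeSimulation`.
#' @export
setGeneric("simulationConfig", function(x) standardGeneric("simulationConfig"))
#' @rdname ViromeSimulation-class
#' @export
setGeneric("genomes", function(x) standardGeneric("genomes"))
#' @rdname ViromeSimulation-class
#' @export
setGeneric("genomeInfo", function(x) standardGeneric("genomeInfo"))
#' @rdname ViromeSimulation-class
#' @export
setGeneric("lineageTable", function(x) standardGeneric("lineageTable"))
#' @rdname ViromeSimulation-class
#' @param role which protein database: viral, nvnr, arg or fun.
#' @export
setGeneric("proteinDb", function(x, role) standardGeneric("proteinDb"))
#' @rdname ViromeSimulation-class
#' @export
setGeneric("hallmarkProfiles", function(x) standardGeneric("hallmarkProfiles"))
#' @rdname ViromeSimulation-class
#' @export
setGeneric("readLibraries", function(x) standardGeneric("readLibraries"))
#' @rdname ViromeSimulation-class
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

setMethod("simulationConfig", "ViromeSimulation", function(x) x@config)
setMethod("genomes", "ViromeSimulation", function(x) x@genomes)
setMethod("genomeInfo", "ViromeSimulation", function(x) x@genomeInfo)
setMethod("lineageTable", "ViromeSimulation", function(x) x@lineage)
setMethod("proteinDb", "ViromeSimulation", function(x, role) {
  if (!role %in% names(x@databases)) stopf("no database with role '%s'", role)
  x@databases[[role]]
})
setMethod("hallmarkProfiles", "ViromeSimulation", function(x) x@profiles)
setMethod("readLibraries", "ViromeSimulation", function(x) x@reads)
setMethod("groundTruth", "ViromeSimulation", function(x) x@manifest)
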