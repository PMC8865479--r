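#' @include AllClasses.R
NULL

# Family panel of the mock community: bacteriophage orders/families dominate,
# with eukaryotic DNA/RNA viruses, CRESS DNA viruses and a cellular background,
# each viral category tied to its hallmark (marker) gene.
familyTable <- function() {
  data.frame(
    family = c("Siphoviridae", "Myoviridae", "Podoviridae", "Ackermannviridae",
               "Microviridae", "Parvoviridae", "Circoviridae", "Smacoviridae",
               "Astroviridae", "Picornaviridae", "bacterial", "host"),
    realm = c(rep("Duplodnaviria", 4), "Monodnaviria", "Monodnaviria",
              "Monodnaviria", "Monodnaviria", "Riboviria", "Riboviria",
              "cellular", "cellular"),
    order = c(rep("Caudovirales", 4), "Petitvirales", "Piccovirales",
              "Cirlivirales", "Cremevirales", "Stellavirales",
              "Picornavirales", "Eubacteriales", "Squamata"),
    category = c(rep("phage_dsDNA", 4), "phage_ssDNA", "euk_virus_DNA",
                 "cress", "cress", "euk_virus_RNA", "euk_virus_RNA",
                 "bacterial", "host"),
    hallmark = c(rep("TerL", 4), "MCP", "NS1", "Rep", "Rep", "RdRp", "RdRp",
                 NA, NA),
    phage = c(rep(TRUE, 5), rep(FALSE, 7)),
    stringsAsFactors = FALSE
  )
}

#' Mock antibiotic-resistance-gene catalogue
#'
#' Eighteen phage-borne ARGs with drug class and resistance mechanism
#' metadata: thirteen "core" genes planted in tailed-phage genomes sampled by
#' every library, and five genes planted only in the phage family restricted
#' to PT-group libraries; two additional genes occur only in bacterial
#' genomes (they must never surface in phage ARG tables).
#'
#' @return data.frame with columns gene, drug_class, mechanism, placement.
#' @export
argCatalog <- function() {
  data.frame(
    gene = c("cmeB", "macB", "oprM", "cmeA", "tolC", "acrB", "mdtB", "emrB",
             "mphA", "catB", "floR", "tetA", "sul1",
             "arnA", "ugd", "ileS", "tet36", "dfrE",
             "blaTEM", "vanA"),
    drug_class = c("multidrug", "macrolide", "multidrug", "multidrug",
                   "multidrug", "multidrug", "multidrug", "multidrug",
                   "macrolide", "phenicol", "phenicol", "tetracycline",
                   "sulfonamide",
                   "peptide", "peptide", "mupirocin-like", "tetracycline",
                   "diaminopyrimidine",
                   "beta-lactam", "glycopeptide"),
    mechanism = c("antibiotic efflux", "antibiotic efflux", "antibiotic efflux",
                  "antibiotic efflux", "antibiotic efflux", "antibiotic efflux",
                  "antibiotic efflux", "antibiotic efflux",
                  "antibiotic inactivation", "antibiotic inactivation",
                  "antibiotic efflux", "antibiotic efflux",
                  "antibiotic target replacement",
                  "antibiotic target alteration", "antibiotic target alteration",
                  "antibiotic target alteration", "antibiotic target protection",
                  "antibiotic target replacement",
                  "antibiotic inactivation", "antibiotic target alteration"),
    placement = c(rep("core_phage", 13), rep("pt_exclusive", 5),
                  rep("bacterial_only", 2)),
    stringsAsFactors = FALSE
  )
}

#' Mock functional-gene catalogue
#'
#' Phage-encoded auxiliary metabolic genes with a two-level pathway
#' annotation (category), dominated by energy metabolism.
#'
#' @return data.frame with columns gene and category.
#' @export
funCatalog <- function() {
  data.frame(
    gene = c("nrdA", "cobS", "phoH", "mazG", "talC", "cpeT", "psbA", "glnK"),
    category = c("Energy metabolism", "Energy metabolism", "Energy metabolism",
                 "Nucleotide metabolism", "Carbohydrate metabolism",
                 "Amino acid metabolism", "Energy metabolism",
                 "Amino acid metabolism"),
    stringsAsFactors = FALSE
  )
}

# Default per-library family proportions (fractions of reads). Tailed phages
# dominate all libraries, the PE_NMC (Namtso) library is parvovirus-rich, and
# one tailed-phage family occurs only in PT-group libraries.
defaultComposition <- function(libraries = defaultLibraries()) {
  fams <- familyTable()$family
  pe  <- c(.16, .11, .05, 0,   .05, .02, .01, .005, .035, .01, .49, .06)
  nmc <- c(.10, .08, .04, 0,   .03, .12, .01, .005, .04, .015, .50, .06)
  pt  <- c(.15, .10, .05, .03, .05, .01, .005, .005, .03, .01, .50, .06)
  comp <- rbind(PE_NMC = nmc, PE_NQ = pe, PE_ZB = pe,
                PT_NQ = pt, PT_SZZ = pt, PT_RT = pt)
  colnames(comp) <- fams
  comp[libraries, , drop = FALSE]
}

defaultLibraries <- function() c("PE_NMC", "PE_NQ", "PE_ZB",
                                 "PT_NQ", "PT_SZZ", "PT_RT")

#' Build a simulation configuration
#'
#' Defaults emulate the emulated study's layout: six pooled virome libraries
#' from two lizard host species (PE, PT) across sites, 250-nt reads, a
#' parvovirus-rich PE_NMC library, Nextera adapter read-through, positional
#' quality decay and a near-empty blank control.
#'
#' @param seed master seed for all derived randomness.
#' @param libraries library names; must match `composition` rownames.
#' @param readLength read length (nt); must exceed 55.
#' @param readsPerLibrary reads per library.
#' @param composition libraries x family proportion matrix, rows summing to 1.
#' @param duplicateRate fraction of reads emitted as duplicates of others.
#' @param partialDuplicates emit duplicates identical only over bases 5-55.
#' @param adapterSeq,adapterRate adapter sequence and read-through fraction.
#' @param insertMean,insertSd mate-pair fragment-size model (nt).
#' @param qualityStart,qualityEnd,qualitySd Phred decay model (mean quality at
#'   first and last cycle, per-base sd).
#' @param groupLabels named character: library -> host-species group.
#' @param controlReads reads in the blank control library.
#' @param speciesPerFamily mock species per viral family.
#' @return A validated [SimConfig-class].
#' @examples
#' cfg <- simConfig(seed = 7, readsPerLibrary = 500L)
#' cfg
#' @export
simConfig <- function(seed = 1L,
                      libraries = defaultLibraries(),
                      readLength = 250L,
                      readsPerLibrary = 10000L,
                      composition = defaultComposition(libraries),
                      duplicateRate = 0.1,
                      partialDuplicates = FALSE,
                      adapterSeq = "CTGTCTCTTATACACATCTCCGAGCCCACGAGAC",
                      adapterRate = 0.05,
                      insertMean = 400, insertSd = 50,
                      qualityStart = 36, qualityEnd = 24, qualitySd = 3,
                      groupLabels = NULL,
                      controlReads = 60L,
                      speciesPerFamily = 3L) {
  if (is.null(groupLabels))
    groupLabels <- setNames(sub("_.*$", "", libraries), libraries)
  new("SimConfig", seed = as.integer(seed), libraries = libraries,
      readLength = as.integer(readLength),
      readsPerLibrary = as.integer(readsPerLibrary),
      composition = composition, duplicateRate = duplicateRate,
      partialDuplicates = partialDuplicates, adapterSeq = adapterSeq,
      adapterRate = adapterRate, insertMean = insertMean, insertSd = insertSd,
      qualityStart = qualityStart, qualityEnd = qualityEnd,
      qualitySd = qualitySd, groupLabels = groupLabels,
      controlReads = as.integer(controlReads),
      speciesPerFamily = as.integer(speciesPerFamily))
}

# Hallmark ancestor lengths (aa); conserved marker proteins of each category.
.hallmarkLengths <- c(TerL = 160L, MCP = 150L, Rep = 140L, NS1 = 150L,
                      RdRp = 170L)

# number of non-hallmark backbone genes per genome category
.backboneGenes <- c(phage_dsDNA = 6L, phage_ssDNA = 5L, euk_virus_DNA = 5L,
                    cress = 2L, euk_virus_RNA = 5L, bacterial = 12L,
                    host = 12L)

#' Generate mock genomes with a known gene map
#'
#' Builds gene-dense mock genomes for every family named in the configuration's
#' composition: each viral genome embeds exactly one hallmark ORF matching its
#' category (TerL, MCP, Rep, NS1 or RdRp), backbone protein genes, and -
#' depending on the family - planted ARG and functional-gene ORFs; bacterial
#' genomes carry NVNR genes and their own ARGs (which must never be counted as
#' phage-borne), and one tailed-phage genome carries mutated copies of
#' bacterial genes (prophage-like decoys exercising the competitive filter).
#' Every ORF is laid down as an in-frame stop pad, ATG, stop-free codon body
#' and stop codon, so planted coordinates are exact ground truth. RNA-virus
#' genomes are emitted as cDNA (DNA alphabet throughout).
#'
#' @param config a [SimConfig-class].
#' @return list with `genomes` (`DNAStringSet`), `genomeInfo`, `genes`,
#'   `lineage`, `argCatalog`, `funCatalog`, and the `config`.
#' @export
generateGenomes <- function(config) {
  fams <- familyTable()
  need <- colnames(config@composition)
  unknown <- setdiff(need, fams$family)
  if (length(unknown))
    stopf("composition references unknown family label(s): %s",
          paste(unknown, collapse = ", "))
  seeds <- deriveSeeds(config@seed, c("genomes", "databases", "reads"))
  args <- argCatalog()
  funs <- funCatalog()
  withSeed(seeds[["genomes"]], {
    # ancestral hallmark proteins, shared within a category so that one
    # profile detects all its families (with divergence between families)
    hallAnc <- lapply(.hallmarkLengths, function(L)
      paste0("M", randomProtein(L - 1L)))
    argAA <- setNames(vapply(seq_len(nrow(args)), function(i)
      paste0("M", randomProtein(149L)), character(1)), args$gene)
    funAA <- setNames(vapply(seq_len(nrow(funs)), function(i)
      paste0("M", randomProtein(129L)), character(1)), funs$gene)

    useFams <- fams[fams$family %in% need, ]
    # cellular genomes first so phage genomes can borrow prophage decoy genes
    useFams <- useFams[order(!useFams$category %in% c("bacterial", "host")), ]
    genomeSeq <- character()
    ginfo <- list()
    genes <- list()
    lineageRows <- list()

    # ARG split across the three ubiquitous tailed-phage families
    core <- args$gene[args$placement == "core_phage"]
    coreBy <- split(core, rep(c("Siphoviridae", "Myoviridae", "Podoviridae"),
                              length.out = length(core)))
    ptArgs <- args$gene[args$placement == "pt_exclusive"]
    bactArgs <- args$gene[args$placement == "bacterial_only"]

    bactGeneAA <- list()  # per bacterial species gene proteins, reused as decoys

    for (f in seq_len(nrow(useFams))) {
      fam <- useFams$family[f]
      cat_ <- useFams$category[f]
      viral <- !cat_ %in% c("bacterial", "host")
      nSpecies <- if (viral) config@speciesPerFamily
                  else if (cat_ == "bacterial") 2L else 1L
      nBack <- .backboneGenes[[cat_]]
      backAnc <- replicate(nBack, paste0("M", randomProtein(
        sample(110:140, 1))))
      famHall <- if (viral) mutateProtein(hallAnc[[useFams$hallmark[f]]], 0.78)
      for (sp in seq_len(nSpecies)) {
        species <- if (viral) sprintf("%s sp%d", fam, sp)
                   else if (cat_ == "bacterial") sprintf("Firmicutes bacterium sp%d", sp)
                   else "Phrynocephalus host"
        gid <- sprintf("G_%s_sp%d", fam, sp)
        geneAA <- vapply(backAnc, function(a) mutateProtein(a, 0.88),
                         character(1))
        geneName <- sprintf("%s_backbone%d", gid, seq_len(nBack))
        geneRole <- rep("other", nBack)
        geneHall <- rep(NA_character_, nBack)
        if (viral) {
          geneAA <- c(mutateProtein(famHall, 0.88), geneAA)
          geneName <- c(sprintf("%s_%s", gid, useFams$hallmark[f]), geneName)
          geneRole <- c("hallmark", geneRole)
          geneHall <- c(useFams$hallmark[f], geneHall)
        }
        plantArg <- character()
        if (fam %in% names(coreBy)) plantArg <- coreBy[[fam]]
        if (fam == "Ackermannviridae") plantArg <- ptArgs
        if (cat_ == "bacterial") plantArg <- c(bactArgs, core[seq_len(2)])
        if (length(plantArg)) {
          # genome copies diverge from the canonical catalogue protein
          geneAA <- c(geneAA, vapply(unname(argAA[plantArg]), function(a)
            mutateProtein(a, 0.92), character(1)))
          geneName <- c(geneName, sprintf("%s_%s", gid, plantArg))
          geneRole <- c(geneRole, rep("arg", length(plantArg)))
          geneHall <- c(geneHall, rep(NA, length(plantArg)))
        }
        argOf <- c(rep(NA_character_, length(geneName) - length(plantArg)),
                   plantArg)
        if (cat_ %in% c("phage_dsDNA", "phage_ssDNA")) {
          pick <- funs$gene[(seq_len(2) + sp) %% nrow(funs) + 1L]
          geneAA <- c(geneAA, vapply(unname(funAA[pick]), function(a)
            mutateProtein(a, 0.92), character(1)))
          geneName <- c(geneName, sprintf("%s_%s", gid, pick))
          geneRole <- c(geneRole, rep("function", length(pick)))
          geneHall <- c(geneHall, rep(NA, length(pick)))
          argOf <- c(argOf, pick)
        }
        if (cat_ == "bacterial") bactGeneAA[[gid]] <- setNames(geneAA, geneName)
        # prophage-like decoys: mutated bacterial genes inside one phage genome
        if (fam == "Siphoviridae" && sp == 1L && length(bactGeneAA)) {
          src <- bactGeneAA[[1]][seq_len(2)]
          geneAA <- c(geneAA, vapply(src, function(a) mutateProtein(a, 0.85),
                                     character(1)))
          geneName <- c(geneName, sprintf("%s_prophage%d", gid, seq_along(src)))
          geneRole <- c(geneRole, rep("bacterial_like", length(src)))
          geneHall <- c(geneHall, rep(NA, length(src)))
          argOf <- c(argOf, rep(NA, length(src)))
        }
        # planted ORFs must start with ATG: mutation may have touched the
        # initial residue, so pin it back to M
        geneAA <- vapply(geneAA, function(a)
          paste0("M", substr(a, 2, nchar(a))), character(1), USE.NAMES = FALSE)
        # lay the genome down: spacer | TAA pad | ATG..body..stop | spacer ...
        segs <- randomDNA(sample(12:20, 1))
        gstart <- integer(length(geneAA)); gend <- integer(length(geneAA))
        for (g in seq_along(geneAA)) {
          orf <- paste0(reverseTranslate(geneAA[g]),
                        sample(c("TAA", "TAG", "TGA"), 1))
          segs <- paste0(segs, "TAA")
          gstart[g] <- nchar(segs)            # 0-based start of ATG
          segs <- paste0(segs, orf, randomDNA(sample(12:20, 1)))
          gend[g] <- gstart[g] + nchar(orf)   # half-open, includes stop codon
        }
        genomeSeq[gid] <- segs
        ginfo[[gid]] <- data.frame(
          genome = gid, category = cat_, family = fam, species = species,
          length = nchar(segs), stringsAsFactors = FALSE)
        genes[[gid]] <- data.frame(
          gene = geneName, genome = gid, start = gstart, end = gend,
          strand = "+", role = geneRole, hallmark = geneHall,
          product = argOf, aa = geneAA, stringsAsFactors = FALSE)
        lineageRows[[paste(gid)]] <- data.frame(
          realm = useFams$realm[f], order = useFams$order[f], family = fam,
          species = species, phage = useFams$phage[f], stringsAsFactors = FALSE)
      }
    }
    lineage <- unique(do.call(rbind, lineageRows))
    # placeholder taxa used when only a hallmark profile (remote homology)
    # supports an assignment
    fallback <- data.frame(
      realm = c("Duplodnaviria", "Monodnaviria", "Monodnaviria",
                "Monodnaviria", "Riboviria"),
      order = c("Caudovirales", "Petitvirales", "unclassified",
                "Piccovirales", "unclassified"),
      family = paste0("unclassified ", c("Caudovirales", "Microviridae",
                                         "CRESS DNA virus", "Parvoviridae",
                                         "Riboviria")),
      species = paste0("unclassified ",
                       c("TerL", "MCP", "Rep", "NS1", "RdRp"),
                       "-encoding virus"),
      phage = c(TRUE, TRUE, FALSE, FALSE, FALSE),
      stringsAsFactors = FALSE)
    lineage <- rbind(lineage, fallback)
    rownames(lineage) <- NULL
    list(genomes = Biostrings::DNAStringSet(genomeSeq),
         genomeInfo = do.call(rbind, c(ginfo, make.row.names = FALSE)),
         genes = do.call(rbind, c(genes, make.row.names = FALSE)),
         lineage = lineage, argCatalog = args, funCatalog = funs,
         argProteins = argAA, funProteins = funAA,
         config = config)
  })
}

# Per-column log-odds PSSM from equal-length hallmark instances. The
# reporting threshold is the 1st percentile of a true-positive panel built by
# degrading the instances down to the remote-homology regime (35 percent
# identity), so the fallback retains the remote-detection role that pairwise
# search lacks while staying far above null (random-sequence) window scores.
.buildProfile <- function(instances, name, fallbackLineage) {
  W <- nchar(instances[1])
  chars <- do.call(rbind, strsplit(instances, ""))
  aas <- names(.aaBackground)
  mat <- matrix(0, nrow = W, ncol = length(aas), dimnames = list(NULL, aas))
  for (j in seq_len(W)) {
    cnt <- table(factor(chars[, j], levels = aas))
    p <- (as.numeric(cnt) + .aaBackground) / (nrow(chars) + 1)
    mat[j, ] <- log2(p / .aaBackground)
  }
  scoreOf <- function(aa)
    sum(mat[cbind(seq_len(W), match(strsplit(aa, "")[[1]], aas))])
  self <- vapply(instances, scoreOf, numeric(1))
  panel <- unlist(lapply(instances, function(a)
    vapply(c(0.35, 0.5, 0.65, 0.8), function(id)
      scoreOf(mutateProtein(a, id)), numeric(1))))
  # threshold on the per-column (coverage-normalized) score, so windows of
  # different overlap are comparable
  list(name = name, matrix = mat,
       threshold = as.numeric(quantile(panel, 0.01, type = 1)) / W,
       selfScores = unname(self), panelScores = panel,
       family = fallbackLineage$family, species = fallbackLineage$species,
       lineage = fallbackLineage)
}

#' Derive protein databases and hallmark profiles from mock genomes
#'
#' Partitions the planted proteome into the four search databases of the
#' triage stage: `viral` (every ORF of every viral genome, with lineage),
#' `nvnr` (bacterial and host proteins plus a controlled fraction of decoy
#' homologs of viral proteins), `arg` (resistance genes with drug class and
#' mechanism) and `fun` (functional genes with pathway category). Also builds
#' one log-odds PSSM per hallmark from the simulated hallmark instances, with
#' the reporting threshold set at the 1st percentile of true-positive
#' self-scores.
#'
#' @param gen output of [generateGenomes()].
#' @param decoyFraction fraction of the final NVNR database made of mutated
#'   copies of viral proteins.
#' @return list with elements `viral`, `nvnr`, `arg`, `fun` (each an
#'   `AAStringSet` with metadata columns) and `profiles`.
#' @export
buildDatabases <- function(gen, decoyFraction = 0.2) {
  config <- gen$config
  seeds <- deriveSeeds(config@seed, c("genomes", "databases", "reads"))
  withSeed(seeds[["databases"]], {
    genes <- gen$genes
    info <- gen$genomeInfo
    lin <- gen$lineage
    cat_ <- info$category[match(genes$genome, info$genome)]
    fam <- info$family[match(genes$genome, info$genome)]
    spc <- info$species[match(genes$genome, info$genome)]
    linIdx <- match(spc, lin$species)
    viralSel <- !cat_ %in% c("bacterial", "host")

    mkdb <- function(sel, role) {
      db <- Biostrings::AAStringSet(setNames(genes$aa[sel], genes$gene[sel]))
      S4Vectors::mcols(db) <- S4Vectors::DataFrame(
        source_genome = genes$genome[sel], db_role = role,
        realm = lin$realm[linIdx[sel]], order = lin$order[linIdx[sel]],
        family = fam[sel], species = spc[sel], decoy = FALSE)
      db
    }
    viral <- mkdb(viralSel, "viral")
    nvnr <- mkdb(!viralSel, "nvnr")
    nBase <- length(nvnr)
    nDecoy <- round(decoyFraction / (1 - decoyFraction) * nBase)
    if (nDecoy > 0) {
      pick <- sample(length(viral), nDecoy, replace = nDecoy > length(viral))
      dec <- vapply(as.character(viral[pick]), function(a)
        mutateProtein(a, 0.85), character(1))
      decSet <- Biostrings::AAStringSet(setNames(
        unname(dec), paste0("NVNR_homolog_", names(viral)[pick])))
      S4Vectors::mcols(decSet) <- S4Vectors::DataFrame(
        source_genome = NA_character_, db_role = "nvnr", realm = "cellular",
        order = "Eubacteriales", family = "bacterial",
        species = "uncultured bacterium", decoy = TRUE)
      nvnr <- c(nvnr, decSet)
    }
    # catalogue databases carry the canonical proteins (genome copies diverge)
    args <- gen$argCatalog
    arg <- Biostrings::AAStringSet(gen$argProteins)
    meta <- args[match(names(arg), args$gene), ]
    S4Vectors::mcols(arg) <- S4Vectors::DataFrame(
      gene = meta$gene, drug_class = meta$drug_class,
      mechanism = meta$mechanism, db_role = "arg")
    funs <- gen$funCatalog
    fun <- Biostrings::AAStringSet(gen$funProteins)
    fmeta <- funs[match(names(fun), funs$gene), ]
    S4Vectors::mcols(fun) <- S4Vectors::DataFrame(
      gene = fmeta$gene, category = fmeta$category, db_role = "function")

    hallSel <- genes$role == "hallmark"
    profiles <- list()
    for (h in unique(genes$hallmark[hallSel])) {
      inst <- genes$aa[hallSel & genes$hallmark == h]
      fb <- lin[lin$species == sprintf("unclassified %s-encoding virus", h), ]
      profiles[[h]] <- .buildProfile(inst, h, fb)
    }
    list(viral = viral, nvnr = nvnr, arg = arg, fun = fun,
         profiles = profiles)
  })
}

# draw one library's reads (vectorized over fragments); returns sequences,
# qualities and per-read truth rows
.simulateLibrary <- function(lib, nReads, gen, config, seed, comp) {
  gi <- gen$genomeInfo
  gseq <- as.character(gen$genomes)
  L <- config@readLength
  withSeed(seed, {
    nDup <- floor(config@duplicateRate * nReads)
    nOrig <- nReads - nDup
    nFrag <- ceiling(nOrig / 2)
    famPool <- names(comp)[comp > 0]
    missing <- famPool[!famPool %in% gi$family]
    if (length(missing))
      stopf("composition of %s names families with no genome: %s", lib,
            paste(missing, collapse = ", "))
    fam <- sample(names(comp), nFrag, replace = TRUE, prob = comp)
    gidx <- integer(nFrag)
    for (f in unique(fam)) {
      cand <- which(gi$family == f)
      sel <- fam == f
      gidx[sel] <- if (length(cand) == 1L) cand else
        sample(cand, sum(sel), replace = TRUE)
    }
    glen <- gi$length[gidx]
    insert <- pmin(pmax(round(rnorm(nFrag, config@insertMean, config@insertSd)),
                        L), glen)
    fstart <- floor(runif(nFrag, 1, glen - insert + 1 + 1e-9))
    r1 <- substring(gseq[gidx], fstart, fstart + L - 1L)
    r2start <- fstart + insert - L
    r2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
      substring(gseq[gidx], r2start, r2start + L - 1L))))
    seqs <- c(rbind(r1, r2))[seq_len(nOrig)]
    genome <- gi$genome[gidx]
    truth <- data.frame(
      genome = rep(genome, each = 2)[seq_len(nOrig)],
      family = rep(gi$family[gidx], each = 2)[seq_len(nOrig)],
      species = rep(gi$species[gidx], each = 2)[seq_len(nOrig)],
      start = c(rbind(fstart, r2start))[seq_len(nOrig)],
      strand = rep(c("+", "-"), nFrag)[seq_len(nOrig)],
      mate = rep(c(1L, 2L), nFrag)[seq_len(nOrig)],
      stringsAsFactors = FALSE)
    # positional quality decay + sequencing errors implied by the qualities
    mu <- config@qualityStart +
      (config@qualityEnd - config@qualityStart) * (seq_len(L) - 1) / (L - 1)
    qmat <- matrix(pmin(pmax(round(rnorm(nOrig * L, mean = rep(mu, each = nOrig),
                                         sd = config@qualitySd)), 2), 41),
                   nrow = nOrig)
    cm <- matrix(unlist(strsplit(seqs, "")), nrow = nOrig, byrow = TRUE)
    errs <- which(matrix(runif(nOrig * L), nrow = nOrig) < 10^(-qmat / 10))
    if (length(errs)) {
      alt <- c("A", "C", "G", "T")
      repl <- sample(alt, length(errs), replace = TRUE)
      same <- repl == cm[errs]
      while (any(same)) {
        repl[same] <- sample(alt, sum(same), replace = TRUE)
        same <- repl == cm[errs]
      }
      cm[errs] <- repl
    }
    # adapter read-through at a fraction of 3' ends
    hasAd <- runif(nOrig) < config@adapterRate
    if (any(hasAd)) {
      adChars <- strsplit(config@adapterSeq, "")[[1]]
      for (i in which(hasAd)) {
        t0 <- sample(seq(floor(L * 0.55), L - 16L), 1)
        fill <- c(adChars, sample(c("A", "C", "G", "T"), L, replace = TRUE))
        cm[i, (t0 + 1):L] <- fill[seq_len(L - t0)]
      }
    }
    seqs <- apply(cm, 1, paste, collapse = "")
    # exact-copy duplicates (optionally identical only over bases 5-55)
    dupOf <- rep(NA_integer_, nReads)
    if (nDup > 0) {
      src <- sample(nOrig, nDup, replace = TRUE)
      dupSeq <- seqs[src]
      if (config@partialDuplicates) {
        dm <- matrix(unlist(strsplit(dupSeq, "")), nrow = nDup, byrow = TRUE)
        for (i in seq_len(nDup)) {
          pos <- sample(c(1:4, 56:L), 3)
          dm[i, pos] <- sample(c("A", "C", "G", "T"), 3, replace = TRUE)
        }
        dupSeq <- apply(dm, 1, paste, collapse = "")
      }
      seqs <- c(seqs, dupSeq)
      qmat <- rbind(qmat, matrix(pmin(pmax(round(rnorm(
        nDup * L, mean = rep(mu, each = nDup), sd = config@qualitySd)), 2), 41),
        nrow = nDup))
      truth <- rbind(truth, truth[src, ])
      dupOf[nOrig + seq_len(nDup)] <- src
      hasAd <- c(hasAd, hasAd[src])
    }
    ids <- sprintf("%s_R%06d", lib, seq_len(nReads))
    qual <- apply(qmat, 1, function(q) intToUtf8(q + 33L))
    perRead <- data.frame(
      read_id = ids, library = lib, truth,
      is_duplicate_of = ifelse(is.na(dupOf), NA_character_, ids[dupOf]),
      has_adapter = hasAd, stringsAsFactors = FALSE)
    reads <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(setNames(seqs, ids)),
      Biostrings::PhredQuality(setNames(qual, ids)))
    list(reads = reads, perRead = perRead)
  })
}

#' Simulate per-library paired-end reads with ground truth
#'
#' Draws mate-pair fragments from the mock genomes according to each library's
#' family composition, applies positional quality decay with matching
#' substitution errors, adapter read-through and exact-copy PCR duplicates,
#' and emits a near-empty blank control library drawn only from the cellular
#' background. The returned manifest is the acceptance oracle: every read's
#' true origin and every library's true family composition.
#'
#' @param gen output of [generateGenomes()].
#' @param config the same [SimConfig-class] used to generate the genomes.
#' @return list with `reads` (named list of `QualityScaledDNAStringSet`,
#'   libraries plus `"Control"`) and `manifest` (list of `perRead`,
#'   `perLibrary`, `perGene` data.frames).
#' @export
simulateReads <- function(gen, config = gen$config) {
  seeds <- deriveSeeds(config@seed, c("genomes", "databases", "reads"))
  libSeeds <- deriveSeeds(seeds[["reads"]],
                          c(config@libraries, "Control"))
  reads <- list()
  perRead <- list()
  for (lib in config@libraries) {
    out <- .simulateLibrary(lib, config@readsPerLibrary, gen, config,
                            libSeeds[[lib]],
                            config@composition[lib, , drop = TRUE])
    reads[[lib]] <- out$reads
    perRead[[lib]] <- out$perRead
  }
  # blank control: only cellular background, no artifacts
  ctrlComp <- setNames(numeric(ncol(config@composition)),
                       colnames(config@composition))
  ctrlComp[c("bacterial", "host")] <- c(0.9, 0.1)
  ctrlCfg <- config
  ctrlCfg@duplicateRate <- 0
  ctrlCfg@adapterRate <- 0
  if (config@controlReads > 0) {
    out <- .simulateLibrary("Control", config@controlReads, gen, ctrlCfg,
                            libSeeds[["Control"]], ctrlComp)
    reads[["Control"]] <- out$reads
    perRead[["Control"]] <- out$perRead
  }
  perRead <- do.call(rbind, c(perRead, make.row.names = FALSE))
  perLibrary <- as.data.frame(table(library = perRead$library,
                                    family = perRead$family),
                              stringsAsFactors = FALSE)
  names(perLibrary)[3] <- "reads"
  list(reads = reads,
       manifest = list(perRead = perRead, perLibrary = perLibrary,
                       perGene = gen$genes[, setdiff(names(gen$genes), "aa")]))
}

#' Run the complete simulator
#'
#' Convenience wrapper: [generateGenomes()], [buildDatabases()] and
#' [simulateReads()] under one configuration, bundled as a
#' [ViromeSimulation-class].
#'
#' @param config a [SimConfig-class].
#' @param decoyFraction passed to [buildDatabases()].
#' @return A [ViromeSimulation-class].
#' @examples
#' sim <- simulateVirome(simConfig(seed = 7, readsPerLibrary = 200L))
#' sim
#' @export
simulateVirome <- function(config = simConfig(), decoyFraction = 0.2) {
  gen <- generateGenomes(config)
  dbs <- buildDatabases(gen, decoyFraction = decoyFraction)
  rd <- simulateReads(gen, config)
  new("ViromeSimulation", config = config, genomes = gen$genomes,
      genomeInfo = gen$genomeInfo, genes = gen$genes, lineage = gen$lineage,
      databases = dbs[c("viral", "nvnr", "arg", "fun")],
      profiles = dbs$profiles, reads = rd$reads, manifest = rd$manifest)
}
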