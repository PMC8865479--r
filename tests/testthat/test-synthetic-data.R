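test_that("the simulator is deterministic given a seed and varies with it", {
  cfg <- simConfig(seed = 11, readsPerLibrary = 120L, speciesPerFamily = 2L)
  s1 <- simulateVirome(cfg)
  s2 <- simulateVirome(cfg)
  expect_identical(as.character(genomes(s1)), as.character(genomes(s2)))
  expect_identical(as.character(readLibraries(s1)[["PE_NQ"]]),
                   as.character(readLibraries(s2)[["PE_NQ"]]))
  expect_identical(groundTruth(s1)$perRead, groundTruth(s2)$perRead)
  s3 <- simulateVirome(simConfig(seed = 12, readsPerLibrary = 120L,
                                 speciesPerFamily = 2L))
  expect_equal(length(genomes(s3)), length(genomes(s1)))
  expect_false(identical(as.character(genomes(s3)),
                         as.character(genomes(s1))))
})

test_that("every viral genome embeds its hallmark ORF at the recorded locus", {
  sim <- tinySim()
  g <- sim@genes
  hall <- g[g$role == "hallmark", ]
  info <- genomeInfo(sim)
  expect_true(all(table(hall$genome) == 1))   # exactly one per viral genome
  viralGenomes <- info$genome[!info$category %in% c("bacterial", "host")]
  expect_setequal(hall$genome, viralGenomes)
  gs <- as.character(genomes(sim))
  for (i in seq_len(nrow(hall))) {
    orf <- unname(substr(gs[hall$genome[i]], hall$start[i] + 1, hall$end[i]))
    expect_identical(substr(orf, 1, 3), "ATG")
    expect_true(substr(orf, nchar(orf) - 2, nchar(orf)) %in%
                  c("TAA", "TAG", "TGA"))
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(
      substr(orf, 1, nchar(orf) - 3))))
    expect_identical(aa, hall$aa[i])
  }
  # category -> hallmark pairing
  cat_ <- info$category[match(hall$genome, info$genome)]
  map <- c(phage_dsDNA = "TerL", phage_ssDNA = "MCP", cress = "Rep",
           euk_virus_DNA = "NS1", euk_virus_RNA = "RdRp")
  expect_identical(unname(map[cat_]), hall$hallmark)
})

test_that("per-library composition tracks the configured proportions", {
  cfg <- simConfig(seed = 5, readsPerLibrary = 4000L)
  sim <- simulateVirome(cfg)
  gt <- groundTruth(sim)$perRead
  lib <- "PT_SZZ"
  comp <- cfg@composition[lib, ]
  x <- gt[gt$library == lib, ]
  nFrag <- nrow(x) / 2   # mates share a fragment; fragments are independent
  for (fam in names(comp)[comp > 0.02]) {
    phat <- mean(x$family == fam)
    se <- sqrt(comp[fam] * (1 - comp[fam]) / nFrag)
    expect_lt(abs(phat - comp[fam]), 3 * se + 1e-12)
  }
})

test_that("duplicate emission is exact in count and acyclic", {
  cfg <- simConfig(seed = 8, readsPerLibrary = 1000L, duplicateRate = 0.1)
  sim <- simulateVirome(cfg)
  gt <- groundTruth(sim)$perRead
  x <- gt[gt$library == "PE_NQ", ]
  expect_equal(sum(!is.na(x$is_duplicate_of)), floor(0.1 * 1000))
  # duplicate pointers reference non-duplicate originals (acyclic by design)
  src <- x$is_duplicate_of[!is.na(x$is_duplicate_of)]
  expect_true(all(is.na(x$is_duplicate_of[match(src, x$read_id)])))
  # duplicates copy the source sequence exactly
  rd <- as.character(readLibraries(sim)[["PE_NQ"]])
  expect_identical(unname(rd[x$read_id[!is.na(x$is_duplicate_of)]]),
                   unname(rd[src]))
  # zero rate -> no duplicates anywhere
  sim0 <- simulateVirome(simConfig(seed = 8, readsPerLibrary = 200L,
                                   duplicateRate = 0))
  expect_true(all(is.na(groundTruth(sim0)$perRead$is_duplicate_of)))
})

test_that("degenerate all-bacterial composition yields no viral reads", {
  comp <- matrix(0, 1, 3, dimnames = list("L1", c("Siphoviridae",
                                                  "bacterial", "host")))
  comp[1, "bacterial"] <- 1
  cfg <- simConfig(seed = 4, libraries = "L1", readsPerLibrary = 200L,
                   composition = comp,
                   groupLabels = c(L1 = "PE"), controlReads = 0L)
  sim <- simulateVirome(cfg)
  gt <- groundTruth(sim)$perRead
  expect_true(all(gt$family == "bacterial"))
})

test_that("NVNR decoy fraction is honoured and databases partition correctly", {
  sim <- tinySim()
  nvnr <- proteinDb(sim, "nvnr")
  nDecoy <- sum(S4Vectors::mcols(nvnr)$decoy)
  expect_equal(nDecoy, round(0.2 * length(nvnr)))
  viral <- proteinDb(sim, "viral")
  info <- genomeInfo(sim)
  srcCat <- info$category[match(S4Vectors::mcols(viral)$source_genome,
                                info$genome)]
  expect_false(any(srcCat %in% c("bacterial", "host")))
  expect_gt(length(viral), 0)
  expect_gt(length(nvnr), 0)
})

test_that("hallmark instances self-detect against their own profile", {
  sim <- tinySim()
  pf <- hallmarkProfiles(sim)
  g <- sim@genes
  hall <- g[g$role == "hallmark", ]
  for (i in seq_len(nrow(hall))) {
    p <- pf[[hall$hallmark[i]]]
    sc <- viromine:::pssmScan(hall$aa[i], p$matrix)
    expect_gte(sc$perColumn, p$threshold)
    expect_equal(sc$coverage, 1)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(readLength = 50L), "readLength")
  expect_error(simConfig(duplicateRate = 1), "duplicateRate")
  comp <- defaultComposition()
  comp[1, 1] <- comp[1, 1] + 0.1
  expect_error(simConfig(composition = comp), "sum to 1")
  badcomp <- matrix(1, 1, 1, dimnames = list("L1", "NoSuchFamily"))
  cfg <- simConfig(libraries = "L1", composition = badcomp,
                   groupLabels = c(L1 = "PE"))
  expect_error(generateGenomes(cfg), "unknown family")
})

test_that("a simulation bundle writes its full file interface", {
  sim <- tinySim()
  dir <- tempfile("bundle_")
  writeSimulation(sim, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "PE_NMC.fastq", "Control.fastq", "genomes.fasta", "db_viral.fasta",
    "db_nvnr.fasta", "lineage.tsv", "arg_metadata.tsv", "manifest.json",
    "config.yaml")))))
  back <- readFastq(file.path(dir, "PE_NMC.fastq"))
  orig <- readLibraries(sim)[["PE_NMC"]]
  expect_identical(as.character(back), as.character(orig))
  # quality strings round-trip (the reader does not name the quality set)
  expect_identical(unname(as.character(Biostrings::quality(back))),
                   unname(as.character(Biostrings::quality(orig))))
  unlink(dir, recursive = TRUE)
})

test_that("simulation configs round-trip through YAML", {
  cfg <- simConfig(seed = 42, readsPerLibrary = 500L, duplicateRate = 0.07)
  path <- tempfile(fileext = ".yaml")
  writeSimConfig(cfg, path)
  cfg2 <- readSimConfig(path)
  for (s in methods::slotNames(cfg))
    expect_equal(methods::slot(cfg2, s), methods::slot(cfg, s))
})
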