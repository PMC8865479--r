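test_that("six-frame translation follows the standard code on both strands", {
  fr <- sixFrameTranslate("ATGGCC")
  expect_identical(fr[["+1"]], "MA")
  # a coding sequence is recovered from its reverse complement in frame -1
  cds <- "ATGAAAGGGTGTTTT"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  expect_identical(sixFrameTranslate(rc)[["-1"]],
                   sixFrameTranslate(cds)[["+1"]])
  expect_identical(unname(nchar(sixFrameTranslate(""))), rep(0L, 6))
})

test_that("all six frames agree with an independent codon-table lookup", {
  set.seed(9)
  code <- as.character(Biostrings::GENETIC_CODE)
  names(code) <- names(Biostrings::GENETIC_CODE)
  lookup <- function(s) {
    n <- nchar(s) - nchar(s) %% 3
    if (n < 3) return("")
    cods <- substring(s, seq(1, n, 3), seq(3, n, 3))
    paste(code[cods], collapse = "")
  }
  for (i in 1:10) {
    s <- randomDnaStr(300 + sample(0:2, 1))
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    fr <- sixFrameTranslate(s)
    for (f in 1:3) {
      expect_identical(fr[[sprintf("+%d", f)]], lookup(substring(s, f)))
      expect_identical(fr[[sprintf("-%d", f)]], lookup(substring(rc, f)))
    }
  }
})

test_that("bit scores and E-values follow the Karlin-Altschul formula", {
  # direct arithmetic oracle, independent of the package constants' storage
  bits <- (0.267 * 100 - log(0.041)) / log(2)
  expect_equal(bitScore(100), bits)
  expect_equal(eValue(bits, 100, 10000), 1e6 * 2^(-bits))
  # E monotonicity: larger database, larger E at fixed score
  expect_gt(eValue(bits, 100, 1e5), eValue(bits, 100, 1e4))
  expect_gt(eValue(bits, 200, 1e4), eValue(bits, 100, 1e4))
})

test_that("an exact coding query returns a full-identity self-hit first", {
  sim <- tinySim()
  db <- proteinDb(sim, "viral")
  aa <- as.character(db[[5]])
  nt <- viromine:::withSeed(1, viromine:::reverseTranslate(aa))
  h <- translatedSearch(setNames(nt, "q"), db)
  expect_gt(nrow(h), 0)
  expect_identical(h$subject[1], names(db)[5])
  expect_equal(h$identity[1], 1)
  expect_equal(h$qstart[1], 0L)
  expect_equal(h$qend[1], nchar(aa))
  expect_equal(h$sstart[1], 0L)
  expect_equal(h$send[1], nchar(aa))
  expect_equal(h$frame[1], 1L)
  expect_lt(h$evalue[1], 1e-5)
  # empty database -> no hits
  expect_equal(nrow(translatedSearch(setNames(nt, "q"),
                                     Biostrings::AAStringSet())), 0L)
})

test_that("the competitive filter removes decoys, keeps phages, keeps ties", {
  sim <- tinySim()
  gs <- as.character(genomes(sim))
  info <- genomeInfo(sim)
  g <- sim@genes
  # a bacterial read from a gene with a mutated copy in a phage genome
  pro <- g[g$role == "bacterial_like", ][1, ]
  bactGenome <- info$genome[info$category == "bacterial"][1]
  srcGene <- g[g$genome == bactGenome, ][1:2, ]   # decoy sources
  bactRead <- unname(substr(gs[bactGenome], srcGene$start[1] + 1,
                            srcGene$start[1] + 250))
  # a genuine phage read from the hallmark of a phage with no NVNR homolog
  phageGenome <- g$genome[g$role == "hallmark"][2]
  hrow <- g[g$role == "hallmark", ][2, ]
  phageRead <- unname(substr(gs[phageGenome], hrow$start[1] + 1,
                             hrow$start[1] + 250))
  qs <- Biostrings::DNAStringSet(c(bact = bactRead, phage = phageRead))
  vh <- translatedSearch(qs, proteinDb(sim, "viral"))
  expect_true(all(c("bact", "phage") %in% vh$query))
  cf <- competitiveFilter(vh, qs, proteinDb(sim, "nvnr"))
  expect_true("bact" %in% cf$removed$query)
  expect_false("phage" %in% cf$removed$query)
  expect_true("phage" %in% cf$hits$query)
  # exact tie favours the viral assignment
  p <- as.character(proteinDb(sim, "viral")[[1]])
  tieV <- Biostrings::AAStringSet(c(tie = p))
  tieN <- Biostrings::AAStringSet(c(tie_nv = p))
  q <- Biostrings::DNAStringSet(c(
    q1 = viromine:::withSeed(2, viromine:::reverseTranslate(p))))
  vh2 <- translatedSearch(q, tieV)
  cf2 <- competitiveFilter(vh2, q, tieN)
  expect_equal(nrow(cf2$removed), 0L)
  expect_true("q1" %in% cf2$hits$query)
  # removeOnAnyHit removes the tie
  cf3 <- competitiveFilter(vh2, q, tieN, removeOnAnyHit = TRUE)
  expect_true("q1" %in% cf3$removed$query)
})

test_that("profiles detect remote hallmark homologs and reject noise", {
  sim <- tinySim()
  pf <- hallmarkProfiles(sim)
  g <- sim@genes
  terl <- g$aa[g$role == "hallmark" & g$hallmark == "TerL"][1]
  # a remote homolog of the *category ancestor* (a novel family): well below
  # pairwise sensitivity but within the profile's calibrated range
  mut <- viromine:::withSeed(41, viromine:::mutateProtein(terl, 0.37))
  nt <- viromine:::withSeed(42, viromine:::reverseTranslate(mut))
  fb <- profileFallback(setNames(nt, "remote"), pf)
  expect_equal(nrow(fb), 1L)
  expect_identical(fb$hallmark, "TerL")
  expect_identical(fb$route, "profile_fallback")
  # random sequences stay below threshold
  rnd <- setNames(vapply(1:40, function(i)
    viromine:::withSeed(100 + i, viromine:::randomDNA(600)), character(1)),
    sprintf("n%02d", 1:40))
  expect_lte(nrow(profileFallback(rnd, pf)) / 40, 0.05)
  # the exact hallmark's best window score equals its per-column sum
  p <- pf[["TerL"]]
  sc <- viromine:::pssmScan(terl, p$matrix)
  chars <- strsplit(terl, "")[[1]]
  manual <- sum(p$matrix[cbind(seq_along(chars),
                               match(chars, colnames(p$matrix)))])
  expect_equal(sc$score, manual)
})

test_that("tabulation sums member reads and validates taxa", {
  lin <- data.frame(realm = "x", order = "y",
                    family = c("Siphoviridae", "Microviridae"),
                    species = c("Siphoviridae sp1", "Microviridae sp1"),
                    phage = TRUE)
  asg <- data.frame(query = c("c1", "c2"), library = c("L1", "L2"),
                    family = c("Siphoviridae", "Microviridae"),
                    species = c("Siphoviridae sp1", "Microviridae sp1"),
                    n_reads = c(7L, 2L), route = "primary_search")
  m <- tabulateAssignments(asg, lin, level = "family")
  expect_s4_class(m, "AbundanceMatrix")
  expect_equal(m["L1", "Siphoviridae"], 7)
  expect_equal(m["L2", "Siphoviridae"], 0)
  norm <- tabulateAssignments(asg, lin, level = "family", normalize = TRUE)
  expect_equal(unname(rowSums(norm@.Data)), c(1, 1))
  bad <- asg; bad$family[1] <- "Nonexistviridae"
  expect_error(tabulateAssignments(bad, lin, level = "family"),
               "not in the lineage")
  empty <- tabulateAssignments(asg[0, ], lin, level = "family",
                               libraries = c("L1", "L2"))
  expect_true(all(empty@.Data == 0))
})

test_that("no query is both retained and NVNR-removed", {
  sim <- tinySim()
  rd <- readLibraries(sim)[["PT_RT"]]
  q <- Biostrings::DNAStringSet(as.character(rd)[1:150])
  tri <- triageSequences(q, proteinDb(sim, "viral"), proteinDb(sim, "nvnr"),
                         libraryOf = setNames(rep("PT_RT", 150), names(q)))
  expect_length(intersect(tri$assignments$query, tri$removed$query), 0)
})
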