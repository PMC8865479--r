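test_that("ppm and FPKM follow their closed forms", {
  set.seed(41)
  orf <- randomDnaStr(1000)
  reads <- substring(orf, s <- sample(1:750, 100, TRUE), s + 249)
  names(reads) <- sprintf("r%03d", 1:100)
  calls <- data.frame(orf_id = "o1", contig_id = "c1", gene = "cmeB",
                      evalue = 1e-20, bitscore = 100, identity = 1,
                      drug_class = "multidrug",
                      mechanism = "antibiotic efflux")
  ab <- quantifyGenes(calls, c(o1 = orf), list(L1 = reads),
                      librarySizes = c(L1 = 1e6))
  expect_equal(ab$read_hits, 100L)
  expect_equal(ab$ppm, 100)                       # 100 * 1e6 / 1e6
  expect_equal(ab$fpkm, 100)                      # 100 * 1e9 / (1000 * 1e6)
  expect_identical(ab$drug_class, "multidrug")
  # scale invariance: doubling hits and N leaves ppm unchanged
  ab2 <- quantifyGenes(calls, c(o1 = orf),
                       list(L1 = setNames(rep(reads, 2),
                                          sprintf("r%03d", 1:200))),
                       librarySizes = c(L1 = 2e6))
  expect_equal(ab2$ppm, ab$ppm)
  expect_error(quantifyGenes(calls, c(o1 = orf), list(L1 = reads),
                             librarySizes = c(L1 = 0)), "positive")
})

test_that("each read is counted once even with duplicated gene models", {
  set.seed(42)
  orf <- randomDnaStr(600)
  reads <- substring(orf, s <- sample(1:350, 60, TRUE), s + 249)
  names(reads) <- sprintf("r%02d", 1:60)
  calls <- data.frame(orf_id = c("o1", "o2"), contig_id = c("c1", "c2"),
                      gene = c("gA", "gB"), evalue = 1e-20, bitscore = 100,
                      identity = 1, drug_class = "x", mechanism = "y")
  ab <- quantifyGenes(calls, c(o1 = orf, o2 = orf), list(L1 = reads),
                      librarySizes = c(L1 = 1000))
  expect_lte(sum(ab$read_hits), 60L)
})

test_that("class aggregation sums ppm and normalizes proportions", {
  ab <- data.frame(gene = c("g1", "g2", "g3"), library = "L1",
                   read_hits = c(3L, 1L, 2L), ppm = c(30, 10, 0),
                   fpkm = c(1, 2, 0),
                   drug_class = c("multidrug", "macrolide", "multidrug"))
  agg <- aggregateAbundance(ab, by = "drug_class")
  expect_equal(agg$proportion[agg$class == "multidrug"], 0.75)
  expect_equal(agg$proportion[agg$class == "macrolide"], 0.25)
  expect_equal(sum(agg$proportion), 1, tolerance = 1e-9)
  # single class
  one <- aggregateAbundance(ab[1, ], by = "drug_class")
  expect_equal(one$proportion, 1)
  # random tables match the brute-force group-sum oracle
  set.seed(43)
  for (i in 1:40) {
    df <- data.frame(gene = sprintf("g%d", 1:12),
                     library = sample(c("L1", "L2"), 12, TRUE),
                     ppm = round(rexp(12, 0.1), 3),
                     drug_class = sample(c("a", "b", "c"), 12, TRUE))
    agg <- aggregateAbundance(df, by = "drug_class")
    ora <- bruteAggregate(df, "drug_class")
    key <- paste(agg$library, agg$class)
    okey <- paste(ora$library, ora$class)
    expect_setequal(key, okey)
    expect_equal(agg$ppm[match(okey, key)], ora$ppm)
    for (lib in unique(df$library))
      expect_equal(sum(agg$proportion[agg$library == lib]), 1,
                   tolerance = 1e-9)
  }
})

test_that("group exclusives and core genes follow the presence logic", {
  mk <- function(gene, lib, ppm) data.frame(gene = gene, library = lib,
                                            read_hits = 1L, ppm = ppm,
                                            fpkm = ppm)
  ab <- rbind(mk("ptOnly", "PT1", 5), mk("ptOnly", "PT2", 2),
              mk("both", "PE1", 3), mk("both", "PT1", 4),
              mk("core", "PE1", 1), mk("core", "PE2", 1),
              mk("core", "PT1", 1), mk("core", "PT2", 1),
              mk("absent", "PE1", 0))
  gl <- c(PE1 = "PE", PE2 = "PE", PT1 = "PT", PT2 = "PT")
  ex <- exclusiveGenes(ab, gl)
  expect_identical(sort(ex$exclusives$PT), "ptOnly")
  expect_false("both" %in% unlist(ex$exclusives))
  expect_identical(ex$core, "core")
  # random presence matrices against a brute-force membership scan
  set.seed(44)
  for (i in 1:30) {
    libs <- c("A1", "A2", "B1", "B2")
    df <- expand.grid(gene = sprintf("g%d", 1:10), library = libs,
                      stringsAsFactors = FALSE)
    df$ppm <- ifelse(runif(nrow(df)) < 0.4, 0, rexp(nrow(df)))
    df$read_hits <- 1L; df$fpkm <- df$ppm
    gl <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")
    ex <- exclusiveGenes(df, gl)
    for (g in sprintf("g%d", 1:10)) {
      inA <- any(df$ppm[df$gene == g & df$library %in% c("A1", "A2")] > 0)
      inB <- any(df$ppm[df$gene == g & df$library %in% c("B1", "B2")] > 0)
      expect_equal(g %in% ex$exclusives$A, inA && !inB)
      expect_equal(g %in% ex$exclusives$B, inB && !inA)
      all6 <- all(vapply(libs, function(l)
        any(df$ppm[df$gene == g & df$library == l] > 0), logical(1)))
      expect_equal(g %in% ex$core, all6)
    }
  }
})

test_that("phage sequence selection follows the lineage phage flag", {
  lin <- data.frame(realm = "x", order = "y",
                    family = c("Siphoviridae", "Parvoviridae"),
                    species = c("s1", "s2"), phage = c(TRUE, FALSE))
  asg <- data.frame(query = c("c1", "c2"), library = "L1",
                    family = c("Siphoviridae", "Parvoviridae"),
                    species = c("s1", "s2"), n_reads = 1L,
                    route = "primary_search")
  sel <- selectPhageSequences(asg, lin)
  expect_identical(sel, "c1")
})
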