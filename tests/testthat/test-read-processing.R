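test_that("positional dedup keys on bases 5-55 exactly", {
  base <- randomDnaStr(100)
  r1 <- base
  r2 <- base; substr(r2, 60, 60) <- if (substr(base, 60, 60) == "A") "C" else "A"
  r3 <- base; substr(r3, 30, 30) <- if (substr(base, 30, 30) == "G") "T" else "G"
  out <- deduplicateReads(qreads(c(a = r1, b = r2)), seed = 1)
  expect_equal(length(out$reads), 1L)           # identical over 5-55
  expect_equal(out$report[["duplicates_removed"]], 1L)
  out2 <- deduplicateReads(qreads(c(a = r1, c = r3)), seed = 1)
  expect_equal(length(out2$reads), 2L)          # differ inside the window
  # differences in bases 1-4 do not separate reads
  r4 <- base; substr(r4, 2, 2) <- if (substr(base, 2, 2) == "A") "C" else "A"
  out3 <- deduplicateReads(qreads(c(a = r1, d = r4)), seed = 1)
  expect_equal(length(out3$reads), 1L)
})

test_that("dedup matches the brute-force pairwise oracle and is idempotent", {
  set.seed(101)
  for (rep in 1:25) {
    keys <- replicate(sample(3:7, 1), randomDnaStr(80))
    n <- sample(20:60, 1)
    seqs <- vapply(seq_len(n), function(i) {
      k <- sample(keys, 1)
      # vary bases outside the 5-55 window freely
      paste0(randomDnaStr(4), substr(k, 5, 55), randomDnaStr(25))
    }, character(1))
    names(seqs) <- sprintf("r%03d", seq_len(n))
    out <- deduplicateReads(qreads(seqs), seed = rep)
    grp <- bruteDedupGroups(seqs)
    expect_equal(length(out$reads), length(unique(grp)))
    # exactly one survivor per brute-force group
    surv <- match(names(out$reads), names(seqs))
    expect_equal(sort(unique(grp[surv])), sort(unique(grp)))
    # idempotence under the same seed
    again <- deduplicateReads(out$reads, seed = rep)
    expect_identical(names(again$reads), names(out$reads))
  }
})

test_that("short reads are keyed conservatively and empty input is fine", {
  out <- deduplicateReads(qreads(c(x = "ACGTACGTAA", y = "ACGTACGTAA")),
                          seed = 1)
  expect_equal(length(out$reads), 1L)
  empty <- deduplicateReads(qreads(character(0)), seed = 1)
  expect_equal(length(empty$reads), 0L)
  expect_equal(empty$report[["input"]], 0L)
})

test_that("quality-tail trimming follows the suffix-maximization rule", {
  q1 <- rep(30L, 40)
  r <- qreads(c(a = randomDnaStr(40)),
              vapply(list(q1), function(q) intToUtf8(q + 33), character(1)))
  expect_equal(Biostrings::width(trimQualityTails(r, 10)), 40L)
  # [30 x 10 at Q10, then five Q2 bases] -> exactly the 5 bases removed
  q2 <- c(rep(10L, 30), rep(2L, 5))
  r2 <- qreads(c(a = randomDnaStr(35)), intToUtf8(q2 + 33))
  expect_equal(Biostrings::width(trimQualityTails(r2, 10)), 30L)
  # hopeless read trims to empty
  q3 <- rep(2L, 30)
  r3 <- qreads(c(a = randomDnaStr(30)), intToUtf8(q3 + 33))
  expect_equal(Biostrings::width(trimQualityTails(r3, 10)), 0L)
})

test_that("quality trimming agrees with the exhaustive suffix oracle", {
  set.seed(7)
  quals <- lapply(1:300, function(i)
    pmax(2L, pmin(41L, as.integer(round(rnorm(sample(30:120, 1),
                                              sample(c(8, 12, 20), 1), 6))))))
  seqs <- vapply(lengths(quals), randomDnaStr, character(1))
  names(seqs) <- sprintf("r%03d", seq_along(seqs))
  qstr <- vapply(quals, function(q) intToUtf8(q + 33), character(1))
  out <- trimQualityTails(qreads(seqs, qstr), 10)
  expected <- vapply(quals, bruteQualTrim, numeric(1), thr = 10)
  expect_equal(unname(Biostrings::width(out)), as.integer(expected))
  # sequence and quality lengths stay equal
  expect_equal(Biostrings::width(out),
               Biostrings::width(Biostrings::quality(out)))
})

test_that("adapter trimming truncates 3' matches and masks interior ones", {
  ad <- "ACTTGCAGGACCTTGCAGAT"
  body <- randomDnaStr(120)
  r <- qreads(c(a = paste0(body, ad)))
  out <- trimAdapters(r, ad)
  expect_equal(as.character(out$reads)[[1]], body)
  expect_equal(out$report[["reads_adapter_trimmed"]], 1L)
  # interior (5' half) match is masked, not truncated
  r2 <- qreads(c(a = paste0(substr(body, 1, 10), ad, randomDnaStr(120))))
  out2 <- trimAdapters(r2, ad)
  s2 <- as.character(out2$reads)[[1]]
  expect_equal(nchar(s2), 150L)
  expect_equal(substr(s2, 11, 30), strrep("N", 20))
  # no similarity -> unchanged
  r3 <- qreads(c(a = body))
  out3 <- trimAdapters(r3, "GGGGGGGGGGGGGGGGGGGG")
  expect_equal(as.character(out3$reads)[[1]], body)
})

test_that("the adapter scorer agrees with a brute-force offset scan", {
  set.seed(13)
  ad <- randomDnaStr(30)
  for (i in 1:40) {
    read <- randomDnaStr(100)
    if (i %% 2 == 0) {
      # embed a degraded adapter copy at a random position
      pos <- sample(1:70, 1)
      frag <- strsplit(substr(ad, 1, 25), "")[[1]]
      nm <- sample(0:3, 1)
      if (nm > 0) frag[sample(25, nm)] <- sample(c("A", "C", "G", "T"), nm,
                                                 replace = TRUE)
      substr(read, pos, pos + 24) <- paste(frag, collapse = "")
    }
    got <- viromine:::cpp_adapter_scan(read, c(ad, as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(ad)))), 1L, -3L)
    oracle <- max(bruteAdapterBest(read, ad)$score,
                  bruteAdapterBest(read, as.character(
                    Biostrings::reverseComplement(
                      Biostrings::DNAString(ad))))$score)
    expect_equal(got[1, 1], oracle)
  }
})

test_that("length filtering is inclusive at the boundary", {
  r <- qreads(c(a = randomDnaStr(49), b = randomDnaStr(50),
                c = randomDnaStr(51)))
  out <- filterByLength(r, 50)
  expect_identical(names(out$reads), c("b", "c"))
  expect_equal(out$report[["reads_dropped_short"]], 1L)
})

test_that("cleaning counts reconcile and duplicate removal tracks the rate", {
  sim <- tinySim()
  cfg <- simulationConfig(sim)
  rd <- readLibraries(sim)[["PE_NQ"]]
  cl <- cleanReads(rd, adapters = cfg@adapterSeq, seed = 2)
  rep <- cl$report
  expect_equal(rep[["input"]] - rep[["duplicates_removed"]] -
                 rep[["reads_dropped_short"]], rep[["output"]])
  # removed fraction within 3 binomial SE of the configured duplicate rate
  n <- rep[["input"]]
  d <- cfg@duplicateRate
  se <- sqrt(d * (1 - d) / n)
  expect_lt(abs(rep[["duplicates_removed"]] / n - d), 3 * se + 0.01)
  expect_true(all(Biostrings::width(cl$reads) >= 50))
})
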