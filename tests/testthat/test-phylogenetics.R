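test_that("pairwise progressive alignment matches the affine optimum", {
  al <- progressiveAlign(c(s1 = "MKV", s2 = "MV"))
  rows <- as.character(al)
  expect_identical(unname(rows), c("MKV", "M-V"))
  # score of the merged pair equals the Biostrings global affine optimum
  set.seed(31)
  data(BLOSUM62, package = "Biostrings", envir = environment())
  for (i in 1:10) {
    a <- paste(sample(rownames(BLOSUM62)[1:20], 30, TRUE), collapse = "")
    b <- paste(sample(rownames(BLOSUM62)[1:20], 26, TRUE), collapse = "")
    al <- as.character(progressiveAlign(c(x = a, y = b)))
    ca <- strsplit(al[["x"]], "")[[1]]; cb <- strsplit(al[["y"]], "")[[1]]
    sc <- 0; state <- "M"
    for (k in seq_along(ca)) {
      if (ca[k] == "-" || cb[k] == "-") {
        open <- state != (if (ca[k] == "-") "E" else "F")
        sc <- sc - ifelse(open, 12, 1)
        state <- if (ca[k] == "-") "E" else "F"
      } else {
        sc <- sc + BLOSUM62[ca[k], cb[k]]
        state <- "M"
      }
    }
    ora <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = BLOSUM62, gapOpening = 11, gapExtension = 1,
      type = "global")
    expect_equal(sc, Biostrings::score(ora))
  }
})

test_that("identical sequences align without gaps; rows degap to inputs", {
  al <- progressiveAlign(c(a = "MKTAYIAK", b = "MKTAYIAK"))
  expect_identical(unname(as.character(al)), c("MKTAYIAK", "MKTAYIAK"))
  set.seed(32)
  sim <- tinySim()
  g <- sim@genes
  aa <- g$aa[g$role == "hallmark" & g$hallmark == "RdRp"]
  al2 <- progressiveAlign(setNames(aa, sprintf("h%d", seq_along(aa))))
  degapped <- gsub("-", "", as.character(al2))
  expect_identical(unname(degapped), aa)
  # substitution-only homologs (equal lengths) should align essentially
  # without gap columns
  ch <- do.call(rbind, strsplit(as.character(al2), ""))
  gapFree <- mean(colSums(ch == "-") == 0)
  expect_gte(gapFree, 0.9)
})

test_that("gap-heavy columns are filtered with a strict majority rule", {
  msa <- c(a = "MK-LV-", b = "MK-LVD", c = "M--LVD", d = "MKALVD",
           e = "M-ALVD", f = "MKALV-")
  out <- filterGapColumns(msa)            # col 3 has 3/6 gaps: retained
  expect_equal(nchar(as.character(out))[[1]], 6L)
  msa2 <- c(a = "M-K", b = "M-K", c = "M-K")
  out2 <- filterGapColumns(msa2)          # all-gap column removed
  expect_identical(unname(as.character(out2)), c("MK", "MK", "MK"))
  expect_equal(attr(out2, "column_map"), c(1L, 3L))
  # idempotence and oracle equality on random gapped alignments
  set.seed(33)
  for (i in 1:40) {
    W <- sample(10:30, 1); n <- sample(3:8, 1)
    ch <- matrix(sample(c(LETTERS[1:6], "-"), W * n, TRUE,
                        prob = c(rep(0.12, 6), 0.28)), n, W)
    ch[, 1] <- "A"                        # keep at least one column
    rows <- setNames(apply(ch, 1, paste, collapse = ""),
                     sprintf("s%d", 1:n))
    out <- filterGapColumns(rows)
    keepOracle <- which(colMeans(ch == "-") <= 0.5)
    expect_equal(attr(out, "column_map"), keepOracle)
    again <- filterGapColumns(out)
    expect_identical(as.character(again), as.character(out))
  }
  expect_error(filterGapColumns(c(a = "--", b = "--")), "no columns")
})

test_that("Poisson-corrected distances follow the closed form and clamp", {
  msa <- c(a = strrep("A", 10), b = paste0(strrep("A", 9), "C"))
  d <- proteinDistance(msa)
  expect_equal(d["a", "b"], -log(1 - 0.1))
  expect_equal(d["a", "a"], 0)
  sat <- c(a = strrep("A", 10), b = strrep("C", 10))
  expect_warning(ds <- proteinDistance(sat), "clamped")
  expect_equal(ds["a", "b"], 10)
  expect_error(proteinDistance(c(a = "A-", b = "-C")), "no ungapped")
})

test_that("bootstrap support is high for well-separated clades", {
  sim <- tinySim()
  g <- sim@genes
  aa <- g$aa[g$role == "hallmark" & g$hallmark == "TerL"]
  names(aa) <- sprintf("t%02d", seq_along(aa))
  msa <- progressiveAlign(aa[1:8])
  tr <- bootstrapSupport(msa, n = 30, seed = 2)
  expect_length(tr$node.label, ape::Nnode(tr))
  sup <- as.numeric(tr$node.label)
  expect_true(all(sup >= 0 & sup <= 1))
  # same-family species (~88% identity) should form well-supported clades
  expect_gt(max(sup), 0.8)
  # reproducible given the seed
  tr2 <- bootstrapSupport(msa, n = 30, seed = 2)
  expect_identical(tr$node.label, tr2$node.label)
})

test_that("neighbor joining recovers additive trees exactly", {
  set.seed(34)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    tr <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    tr <- ape::unroot(tr)
    d <- ape::cophenetic.phylo(tr)
    got <- njTree(d)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(got), tr)), 0)
    # additive distances are reproduced by the tree metric
    expect_equal(ape::cophenetic.phylo(got)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
  }
  # degenerate star distances resolve with a zero-length internal branch
  d <- matrix(2, 4, 4); diag(d) <- 0
  dimnames(d) <- list(letters[1:4], letters[1:4])
  st <- njTree(d)
  internal <- st$edge.length[st$edge[, 2] > ape::Ntip(st)]
  expect_true(all(abs(internal) < 1e-12))
  expect_true(all(st$edge.length >= 0))
  expect_error(njTree(matrix(0, 2, 2)), "at least 3")
})
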