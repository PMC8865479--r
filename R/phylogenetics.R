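#' @include utils.R ecology.R
NULL

# fraction of shared 3-mers -> distance, for the guide tree
.kmerDistance <- function(seqs, k = 3L) {
  sets <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    unique(substring(s, seq_len(n - k + 1L), k:n))
  })
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    shared <- length(intersect(sets[[i]], sets[[j]]))
    d[i, j] <- d[j, i] <-
      1 - shared / max(1L, min(length(sets[[i]]), length(sets[[j]])))
  }
  d
}

# alphabet x W frequency profile of an aligned block (gaps contribute nothing)
.profileFreq <- function(rows, alphabet) {
  W <- nchar(rows[1])
  ch <- do.call(rbind, strsplit(rows, ""))
  f <- matrix(0, nrow = length(alphabet), ncol = W,
              dimnames = list(alphabet, NULL))
  for (j in seq_len(W)) {
    tab <- table(ch[, j])
    tab <- tab[names(tab) %in% alphabet]
    f[names(tab), j] <- as.numeric(tab) / length(rows)
  }
  f
}

# merge two aligned blocks by profile-profile affine alignment
.mergeProfiles <- function(rows1, rows2, smat, alphabet, gapOpen, gapExt) {
  f1 <- .profileFreq(rows1, alphabet)
  f2 <- .profileFreq(rows2, alphabet)
  S <- t(f1) %*% smat[alphabet, alphabet] %*% f2
  path <- cpp_affine_path(S, gapOpen, gapExt)
  expand <- function(rows, p) {
    ch <- do.call(rbind, strsplit(rows, ""))
    out <- matrix("-", nrow = nrow(ch), ncol = length(p))
    sel <- p > 0
    out[, sel] <- ch[, p[sel], drop = FALSE]
    setNames(apply(out, 1, paste, collapse = ""), names(rows))
  }
  c(expand(rows1, path$path1), expand(rows2, path$path2))
}

#' Progressive multiple alignment of protein sequences
#'
#' Guide tree from 3-mer distances (UPGMA), then profile-profile merging in
#' guide-tree order by global affine alignment (BLOSUM62, gap open 11 /
#' extend 1, terminal gaps penalized); column scores between profiles are the
#' expected substitution scores of their residue frequency vectors.
#' Deterministic for a given input.
#'
#' @param seqs named character vector or `AAStringSet` (at least 2; a single
#'   sequence returns a trivial alignment with a warning).
#' @param gapOpen,gapExt affine gap penalties.
#' @return `AAStringSet` of equal-length gapped rows, in input order.
#' @export
progressiveAlign <- function(seqs, gapOpen = 11, gapExt = 1) {
  s <- namedChars(seqs)
  if (length(s) == 1L) {
    warning("single sequence: returning trivial alignment")
    return(Biostrings::AAStringSet(s))
  }
  smat <- blosumMatrix()
  alphabet <- setdiff(colnames(smat), c("B", "J", "Z", "*"))
  if (length(s) == 2L) {
    merged <- .mergeProfiles(s[1], s[2], smat, alphabet, gapOpen, gapExt)
    names(merged) <- names(s)
    return(Biostrings::AAStringSet(merged))
  }
  d <- .kmerDistance(s)
  hc <- hclust(as.dist(d), method = "average")
  blocks <- lapply(seq_along(s), function(i) s[i])
  nodeBlock <- list()
  for (step in seq_len(nrow(hc$merge))) {
    pick <- function(v) if (v < 0) blocks[[-v]] else nodeBlock[[v]]
    nodeBlock[[step]] <- .mergeProfiles(pick(hc$merge[step, 1]),
                                        pick(hc$merge[step, 2]),
                                        smat, alphabet, gapOpen, gapExt)
  }
  aln <- nodeBlock[[nrow(hc$merge)]]
  Biostrings::AAStringSet(aln[names(s)])
}

#' Remove gap-heavy alignment columns
#'
#' Columns with strictly more than `maxGapFraction` gap characters are
#' removed (a column with exactly 50 percent gaps is retained under the
#' default). The old-to-new column mapping is kept in the `"column_map"`
#' attribute; removing every column is an error. Idempotent.
#'
#' @param msa `AAStringSet` or named character of equal-length gapped rows.
#' @param maxGapFraction maximum tolerated gap fraction (default 0.5).
#' @return `AAStringSet` of the surviving columns.
#' @export
filterGapColumns <- function(msa, maxGapFraction = 0.5) {
  rows <- namedChars(msa)
  ch <- do.call(rbind, strsplit(rows, ""))
  gapFrac <- colMeans(ch == "-")
  keep <- which(gapFrac <= maxGapFraction)
  if (!length(keep)) stopf("no columns survive the gap filter")
  out <- apply(ch[, keep, drop = FALSE], 1, paste, collapse = "")
  names(out) <- names(rows)
  res <- Biostrings::AAStringSet(out)
  attr(res, "column_map") <- keep
  res
}

#' Poisson-corrected protein distances
#'
#' Pairwise p-distance over mutually ungapped columns, corrected as
#' \eqn{d = -\ln(1 - p)}; saturated pairs (\eqn{p \to 1}) are clamped to
#' `maxDistance` with a warning. A pair sharing no ungapped column is an
#' error.
#'
#' @param msa gapped alignment (`AAStringSet`/character).
#' @param maxDistance clamp for saturated pairs (default 10).
#' @return Symmetric distance matrix.
#' @export
proteinDistance <- function(msa, maxDistance = 10) {
  rows <- namedChars(msa)
  if (length(rows) < 2L) stopf("need at least two sequences")
  ch <- do.call(rbind, strsplit(rows, ""))
  n <- nrow(ch)
  d <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  clamped <- FALSE
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- ch[i, ] != "-" & ch[j, ] != "-"
    if (!any(ok)) stopf("sequences %s and %s share no ungapped columns",
                        names(rows)[i], names(rows)[j])
    p <- mean(ch[i, ok] != ch[j, ok])
    dij <- if (p >= 1 - exp(-maxDistance)) { clamped <- TRUE; maxDistance }
           else -log(1 - p)
    d[i, j] <- d[j, i] <- dij
  }
  if (clamped) warning("saturated distances clamped to ", maxDistance)
  d
}

#' Bootstrap support for a distance tree
#'
#' Resamples alignment columns with replacement, rebuilds the
#' Poisson-corrected neighbor-joining tree for each replicate, and attaches
#' the per-node support fractions to the tree built from the full alignment
#' (as `node.label`).
#'
#' @param msa gapped alignment (`AAStringSet`/character).
#' @param n bootstrap replicates.
#' @param seed RNG seed for the column resampling.
#' @param maxDistance passed to [proteinDistance()].
#' @return The full-alignment `phylo` tree with support in `node.label`.
#' @export
bootstrapSupport <- function(msa, n = 100L, seed = 1L, maxDistance = 10) {
  rows <- namedChars(msa)
  ch <- do.call(rbind, strsplit(rows, ""))
  ref <- njTree(suppressWarnings(proteinDistance(rows, maxDistance)))
  trees <- withSeed(seed, lapply(seq_len(n), function(i) {
    idx <- sample.int(ncol(ch), replace = TRUE)
    rs <- setNames(apply(ch[, idx, drop = FALSE], 1, paste, collapse = ""),
                   names(rows))
    tryCatch(njTree(suppressWarnings(proteinDistance(rs, maxDistance))),
             error = function(e) NULL)
  }))
  trees <- trees[!vapply(trees, is.null, logical(1))]
  cnt <- ape::prop.clades(ref, trees)
  cnt[is.na(cnt)] <- 0
  ref$node.label <- sprintf("%.2f", cnt / length(trees))
  ref
}

#' Neighbor-joining tree with non-negative branch lengths
#'
#' Standard neighbor-joining (via `ape::nj`); any negative branch length is
#' set to zero and its deficit moved to the sister branch, preserving
#' leaf-to-leaf path lengths through the parent.
#'
#' @param d symmetric distance matrix over at least 3 taxa.
#' @return Unrooted `phylo` tree.
#' @export
njTree <- function(d) {
  dd <- as.dist(d)
  if (attr(dd, "Size") < 3L) stopf("neighbor-joining needs at least 3 taxa")
  tr <- ape::nj(dd)
  for (it in seq_len(10L)) {
    neg <- which(tr$edge.length < -1e-12)
    if (!length(neg)) break
    for (e in neg) {
      parent <- tr$edge[e, 1L]
      sib <- setdiff(which(tr$edge[, 1L] == parent), e)
      if (length(sib)) {
        sib <- sib[1L]
        tr$edge.length[sib] <- tr$edge.length[sib] + tr$edge.length[e]
      }
      tr$edge.length[e] <- 0
    }
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}
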