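#' @include AllClasses.R
NULL

.asCountMatrix <- function(x) {
  if (is(x, "AbundanceMatrix")) x@.Data else as.matrix(x)
}

#' Bray-Curtis dissimilarity between libraries
#'
#' \eqn{d(x,y) = 1 - 2 \sum_i \min(x_i,y_i) / (\sum_i x_i + \sum_i y_i)}
#' over the rows of a libraries-by-taxa abundance matrix.
#'
#' @param x an [AbundanceMatrix-class] or numeric matrix of non-negative
#'   abundances; all-zero rows are an error (the distance is undefined).
#' @return Symmetric numeric matrix in `[0, 1]` with zero diagonal.
#' @examples
#' brayCurtis(rbind(a = c(2, 1, 0), b = c(1, 1, 1)))["a", "b"]  # 1/3
#' @export
brayCurtis <- function(x) {
  m <- .asCountMatrix(x)
  if (any(m < 0)) stopf("abundances must be non-negative")
  if (any(rowSums(m) == 0))
    stopf("all-zero library row(s): Bray-Curtis is undefined")
  as.matrix(vegan::vegdist(m, method = "bray"))
}

#' UPGMA dendrogram of a distance matrix
#'
#' Average-linkage agglomeration with ultrametric branch lengths (node height
#' = cluster distance / 2).
#'
#' @param d symmetric distance matrix (or `dist`).
#' @return A rooted ultrametric `phylo` tree.
#' @export
upgmaTree <- function(d) {
  dd <- as.dist(d)
  if (attr(dd, "Size") < 2L) stopf("UPGMA needs at least two items")
  ape::as.phylo(hclust(dd, method = "average"))
}

#' Principal-coordinate analysis
#'
#' Gower double-centering of \eqn{-d^2/2} and eigendecomposition; coordinates
#' are eigenvectors scaled by the square root of their (positive)
#' eigenvalues. Negative eigenvalues (non-Euclidean input) are reported and
#' their axes dropped, without correction. Axis signs follow the convention
#' that the first coordinate of non-negligible magnitude on each axis is
#' positive.
#'
#' @param d symmetric distance matrix (or `dist`) over at least 3 items.
#' @return list: `points` (items x positive axes), `eigenvalues` (all),
#'   `negativeSum` (sum of |negative eigenvalues|).
#' @export
pcoaOrdination <- function(d) {
  dd <- as.dist(d)
  n <- attr(dd, "Size")
  if (n < 3L) stopf("PCoA needs at least three items")
  fit <- suppressWarnings(cmdscale(dd, k = n - 1L, eig = TRUE))
  eig <- fit$eig
  tol <- 1e-8 * max(abs(eig))
  pos <- which(eig > tol)
  pts <- fit$points[, seq_along(pos), drop = FALSE]
  for (j in seq_len(ncol(pts))) {
    nz <- which(abs(pts[, j]) > 1e-9)
    if (length(nz) && pts[nz[1L], j] < 0) pts[, j] <- -pts[, j]
  }
  colnames(pts) <- sprintf("PCo%d", seq_len(ncol(pts)))
  list(points = pts, eigenvalues = eig,
       negativeSum = sum(abs(eig[eig < -tol])))
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based ANOSIM: \eqn{R = (\bar r_B - \bar r_W) / (M/2)} with ranks over
#' all \eqn{M = n(n-1)/2} pairwise distances (i.e. divisor `n(n-1)/4`).
#' Significance by label permutation with a fixed seed:
#' \eqn{p = (1 + \#\{R^* \ge R\}) / (1 + n_{perm})}.
#'
#' @param d symmetric distance matrix (or `dist`).
#' @param groups group labels, one per item; at least two groups of two.
#' @param nPerm number of label permutations.
#' @param seed RNG seed for the permutations.
#' @return list of class `anosim_result`: `statistic` (R), `p.value`,
#'   `nPerm`, `seed`, `permuted` (the permuted statistics).
#' @export
anosimTest <- function(d, groups, nPerm = 999L, seed = 1L) {
  dd <- as.dist(d)
  n <- attr(dd, "Size")
  groups <- as.character(groups)
  if (length(groups) != n) stopf("groups must have one label per item")
  tab <- table(groups)
  if (length(tab) < 2L) stopf("ANOSIM needs at least two groups")
  if (any(tab < 2L)) stopf("every group needs at least two members")
  r <- rank(as.vector(dd))
  M <- length(r)
  ij <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  ii <- ij[, 2L]; jj <- ij[, 1L]   # dist order: columns vary slowest
  statFor <- function(g) {
    between <- g[ii] != g[jj]
    (mean(r[between]) - mean(r[!between])) / (M / 2)
  }
  R <- statFor(groups)
  permuted <- withSeed(seed, vapply(seq_len(nPerm), function(k)
    statFor(sample(groups)), numeric(1)))
  p <- (1 + sum(permuted >= R)) / (1 + nPerm)
  structure(list(statistic = R, p.value = p, nPerm = nPerm, seed = seed,
                 permuted = permuted), class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%d permutations, seed %d)\n",
              x$statistic, x$p.value, x$nPerm, x$seed))
  invisible(x)
}

#' Shared-species accounting (UpSet-style)
#'
#' Species presence per library (abundance at or above `threshold`), disjoint
#' intersection cardinalities over all observed library subsets, per-library
#' totals, the core count (species in every library), and - when `groups` is
#' given - the species exclusive to each group (present somewhere inside,
#' absent everywhere outside).
#'
#' @param x species-level [AbundanceMatrix-class] or matrix
#'   (libraries x species).
#' @param threshold presence threshold (default: at least 1 read).
#' @param groups optional named character: library -> group.
#' @return list: `intersections` (data.frame subset/count), `perLibrary`,
#'   `core` (count and species), `exclusives` (per group), `unionSize`.
#' @export
sharedSpecies <- function(x, threshold = 1, groups = NULL) {
  m <- .asCountMatrix(x) >= threshold
  libs <- rownames(m)
  present <- colSums(m) > 0
  pattern <- apply(m, 2, function(col) paste(libs[col], collapse = "&"))
  pattern <- pattern[present]
  inter <- as.data.frame(table(pattern), stringsAsFactors = FALSE)
  names(inter) <- c("subset", "count")
  inter <- inter[order(-inter$count), , drop = FALSE]
  coreSpecies <- colnames(m)[present][
    pattern == paste(libs, collapse = "&")]
  exclusives <- NULL
  if (!is.null(groups)) {
    exclusives <- lapply(unique(groups[libs]), function(g) {
      inG <- libs[groups[libs] == g]
      sel <- colSums(m[inG, , drop = FALSE]) > 0 &
        colSums(m[setdiff(libs, inG), , drop = FALSE]) == 0
      colnames(m)[sel]
    })
    names(exclusives) <- unique(groups[libs])
  }
  list(intersections = inter,
       perLibrary = rowSums(m),
       core = list(count = length(coreSpecies), species = coreSpecies),
       exclusives = exclusives,
       unionSize = sum(present))
}
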