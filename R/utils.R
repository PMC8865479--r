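# package-level cache
.vm <- new.env(parent = emptyenv())

# Gapped Karlin-Altschul constants for BLOSUM62 with affine gaps 11/1.
.KA_LAMBDA <- 0.267
.KA_K <- 0.041

#' Scoring matrix used throughout the package
#'
#' Returns the BLOSUM62 substitution matrix (25-letter protein alphabet,
#' including ambiguity codes and the stop character `*`) shipped with
#' Biostrings.
#'
#' @return An integer matrix with identical row and column names.
#' @export
blosumMatrix <- function() {
  if (is.null(.vm$blosum)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .vm$blosum <- e$BLOSUM62
  }
  .vm$blosum
}

aaAlphabet <- function() paste(colnames(blosumMatrix()), collapse = "")

# Background amino-acid frequencies (Robinson & Robinson), the composition the
# gapped BLOSUM62 Karlin-Altschul constants assume; mock proteins are sampled
# from it so that E-values of null searches are calibrated.
.aaBackground <- c(
  A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
  Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
  L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
  S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441
)

#' Convert a raw alignment score to bits
#'
#' Uses the gapped BLOSUM62 (open 11 / extend 1) Karlin-Altschul constants
#' \eqn{\lambda = 0.267}, \eqn{K = 0.041}:
#' \eqn{S' = (\lambda S - \ln K) / \ln 2}.
#'
#' @param rawScore numeric raw alignment score(s).
#' @return Bit score(s).
#' @export
bitScore <- function(rawScore) (.KA_LAMBDA * rawScore - log(.KA_K)) / log(2)

#' Karlin-Altschul expected number of chance hits
#'
#' \eqn{E = m n 2^{-S'}} for a query of `m` residues against a database of
#' `n` total residues at bit score `bits`.
#'
#' @param bits bit score(s).
#' @param m query length in residues.
#' @param n database size in residues.
#' @return E-value(s).
#' @export
eValue <- function(bits, m, n) as.numeric(m) * as.numeric(n) * 2^(-bits)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive independent per-stage seeds from one pipeline seed
#'
#' All randomized steps draw from seeds derived from a single global seed, so
#' each stage is independently reproducible.
#'
#' @param seed integer master seed.
#' @param labels character vector naming the stages.
#' @return Named integer vector of seeds, one per label.
#' @export
deriveSeeds <- function(seed, labels) {
  s <- withSeed(seed, sample.int(2147483646L, length(labels)))
  names(s) <- labels
  s
}

randomDNA <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

randomProtein <- function(len) {
  paste(sample(names(.aaBackground), len, replace = TRUE, prob = .aaBackground),
        collapse = "")
}

# Point-mutate a protein to approximately `identity` fractional identity.
mutateProtein <- function(aa, identity) {
  v <- strsplit(aa, "")[[1]]
  n <- length(v)
  k <- rbinom(1, n, 1 - identity)
  if (k > 0) {
    pos <- sample.int(n, k)
    for (p in pos) {
      repl <- sample(names(.aaBackground), 1, prob = .aaBackground)
      while (repl == v[p]) repl <- sample(names(.aaBackground), 1, prob = .aaBackground)
      v[p] <- repl
    }
  }
  paste(v, collapse = "")
}

# Reverse-translate a protein into DNA using uniformly sampled synonymous
# codons (standard code); never emits internal stops.
.codonTable <- function() {
  if (is.null(.vm$codons)) {
    cod <- as.character(Biostrings::GENETIC_CODE)
    tab <- split(names(Biostrings::GENETIC_CODE), cod)
    .vm$codons <- tab
  }
  .vm$codons
}

reverseTranslate <- function(aa) {
  tab <- .codonTable()
  v <- strsplit(aa, "")[[1]]
  paste(vapply(v, function(a) {
    opts <- tab[[a]]
    if (is.null(opts)) opts <- tab[["X"]]
    if (length(opts) == 1L) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}

revCompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# as.character() drops names from plain character vectors; keep them.
namedChars <- function(x, prefix = "seq") {
  s <- as.character(x)
  if (is.null(names(s))) names(s) <- names(x)
  if (is.null(names(s))) names(s) <- sprintf("%s%06d", prefix, seq_along(s))
  s
}
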