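# Independent brute-force oracles used across tests. Each reimplements the
# operation from its definition, sharing no code with the package internals.

# O(n^2) all-pairs duplicate grouping on the bases-5..55 rule
bruteDedupGroups <- function(seqs) {
  n <- length(seqs)
  grp <- seq_len(n)
  key <- function(s) substr(s, 5, min(55, nchar(s)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (key(seqs[i]) == key(seqs[j])) grp[grp == grp[j]] <- grp[i]
  }
  grp
}

# exhaustive suffix-score scan for quality trimming
bruteQualTrim <- function(q, thr) {
  n <- length(q)
  best <- 0; cut <- n
  for (k in n:1) {
    sc <- sum(thr - q[k:n])
    if (sc > best) { best <- sc; cut <- k - 1 }
  }
  cut
}

# exhaustive all-offset ungapped adapter scorer (+1/-3), best local run
bruteAdapterBest <- function(read, adapter, match = 1, mismatch = -3) {
  r <- strsplit(toupper(read), "")[[1]]
  a <- strsplit(toupper(adapter), "")[[1]]
  lr <- length(r); la <- length(a)
  best <- 0; span <- c(NA, NA)
  for (o in (-(la - 1)):(lr - 1)) {
    t0 <- max(1, o + 1); t1 <- min(lr, o + la)
    if (t1 < t0) next
    run <- 0; rstart <- t0
    for (t in t0:t1) {
      v <- if (r[t] == a[t - o] && r[t] != "N") match else mismatch
      if (run <= 0) { run <- v; rstart <- t } else run <- run + v
      if (run > best) { best <- run; span <- c(rstart, t) }
    }
  }
  list(score = best, span = span)
}

# six-frame ORF enumerator: every ATG, stepped codon-wise to the next stop
bruteOrfs <- function(seq, minSize = 300) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  L <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc
    atgs <- unlist(gregexpr("ATG", s, fixed = TRUE))
    atgs <- atgs[atgs > 0]
    for (a in atgs) {
      p <- a; hasStop <- FALSE
      repeat {
        cod <- substr(s, p, p + 2)
        if (nchar(cod) < 3) break
        if (p > a && cod %in% stops) { hasStop <- TRUE; break }
        p <- p + 3
      }
      endnt <- if (hasStop) p + 2 else p - 1   # 1-based inclusive end on s
      len <- endnt - a + 1
      if (len < minSize) next
      # suppress nested: skip if an earlier in-frame ATG in the same
      # stop-delimited segment exists
      q <- a - 3; nested <- FALSE
      while (q >= 1) {
        cod <- substr(s, q, q + 2)
        if (cod %in% stops) break
        if (cod == "ATG") { nested <- TRUE; break }
        q <- q - 3
      }
      if (nested) next
      st0 <- if (strand == "+") a - 1 else L - endnt
      en0 <- if (strand == "+") endnt else L - a + 1
      fr <- ((a - 1) %% 3) + 1
      out[[length(out) + 1]] <- data.frame(
        frame = if (strand == "+") fr else -fr, start = st0, end = en0,
        strand = strand, has_stop = hasStop)
    }
  }
  if (length(out)) {
    df <- do.call(rbind, out)
    df[order(df$frame, df$start), ]
  } else data.frame(frame = integer(), start = integer(), end = integer(),
                    strand = character(), has_stop = logical())
}

# brute-force average-linkage merge heights (UPGMA oracle)
bruteUpgmaHeights <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric()
  dd <- d
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      avg <- mean(d[clusters[[i]], clusters[[j]]])
      if (avg < best[1]) best <- c(avg, i, j)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# per-species membership enumeration for shared-set accounting
bruteIntersections <- function(pres) {
  libs <- rownames(pres)
  pat <- apply(pres, 2, function(col) paste(libs[col], collapse = "&"))
  table(pat[pat != ""])
}

# group-sum oracle for class aggregation
bruteAggregate <- function(df, by) {
  keys <- unique(df[, c("library", by)])
  out <- apply(keys, 1, function(k)
    sum(df$ppm[df$library == k[1] & df[[by]] == k[2]]))
  data.frame(library = keys[, 1], class = keys[, 2], ppm = out,
             stringsAsFactors = FALSE)
}

randomDnaStr <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                           replace = TRUE), collapse = "")

qreads <- function(seqs, quals = NULL) {
  if (is.null(names(seqs))) names(seqs) <- sprintf("r%03d", seq_along(seqs))
  if (is.null(quals))
    quals <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  names(quals) <- names(seqs)
  Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(quals))
}
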