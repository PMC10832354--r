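# Independent oracles and small builders shared across tests.

serRec <- function(rec) anchorlift:::.formatRecord(rec)

tinyGenome <- function(seq, name = "ctg") {
  Biostrings::DNAStringSet(stats::setNames(seq, name))
}

identityChain <- function(len, name = "ctg", id = 1L) {
  parseChainFile(sprintf("chain 100 %s %d + 0 %d %s %d + 0 %d %d\n%d\n\n",
                         name, len, len, name, len, len, id, len))[[1L]]
}

# Brute-force normalization oracle: enumerate every (pos, ref, alt)
# record on the contig that edits the genome into the same sequence, and
# return the left-most among those with minimal allele length.
bruteNormalize <- function(rec, genome) {
  G <- fetchSeq(genome, rec@contig, 1L, contigLength(genome, rec@contig))
  L <- nchar(G)
  stopifnot(length(rec@alt) == 1L)
  edited <- paste0(substr(G, 1L, rec@pos - 1L), rec@alt[1L],
                   substr(G, rec@pos + nchar(rec@ref), L))
  E <- edited
  best <- NULL
  for (pos in 1:L) {
    for (rl in 1:(L - pos + 1L)) {
      al <- nchar(E) - (L - rl)
      if (al < 1L) next
      if (pos + al - 1L > nchar(E)) next
      ref <- substr(G, pos, pos + rl - 1L)
      alt <- substr(E, pos, pos + al - 1L)
      if (ref == alt) next
      cand <- paste0(substr(G, 1L, pos - 1L), alt,
                     substr(G, pos + rl, L))
      if (cand != E) next
      if (is.null(best) || (rl + al < best$len) ||
          (rl + al == best$len && pos < best$pos))
        best <- list(pos = pos, ref = ref, alt = alt, len = rl + al)
    }
  }
  best
}

# Brute-force affine-gap global alignment score by exhaustive recursion
# over all alignments (feasible for lengths <= 6).
bruteAlignScore <- function(a, b, p) {
  n <- nchar(a); m <- nchar(b)
  ca <- strsplit(a, "")[[1L]]; cb <- strsplit(b, "")[[1L]]
  rec <- function(i, j, prev) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      s <- if (ca[i] == cb[j]) p@match else p@mismatch
      best <- max(best, s + rec(i + 1L, j + 1L, 0L))
    }
    if (i <= n) {
      cost <- if (prev == 1L) p@gapExtend else p@gapOpen
      best <- max(best, cost + rec(i + 1L, j, 1L))
    }
    if (j <= m) {
      cost <- if (prev == 2L) p@gapExtend else p@gapOpen
      best <- max(best, cost + rec(i, j + 1L, 2L))
    }
    best
  }
  rec(1L, 1L, 0L)
}

# Brute-force Number=G re-ordering: re-enumerate every diploid genotype
# (j, k), j <= k, and place its value at the index of the permuted pair.
bruteGReorder <- function(values, perm, novelRef = FALSE) {
  nOld <- length(perm)
  nNew <- nOld + as.integer(novelRef)
  idx <- function(j, k) (k * (k + 1L)) %/% 2L + j + 1L
  out <- rep(".", (nNew * (nNew + 1L)) %/% 2L)
  for (k in seq_len(nOld) - 1L) for (j in 0:k) {
    pj <- perm[j + 1L]; pk <- perm[k + 1L]
    lo <- min(pj, pk); hi <- max(pj, pk)
    out[idx(lo, hi)] <- values[idx(j, k)]
  }
  out
}

allSeqs <- function(alphabet, maxLen) {
  out <- character()
  for (l in seq_len(maxLen)) {
    g <- do.call(expand.grid, rep(list(alphabet), l))
    out <- c(out, apply(g, 1L, paste, collapse = ""))
  }
  out
}

# apply a REF->ALT substitution to a genome string
applyEdit <- function(G, pos, ref, alt) {
  stopifnot(substr(G, pos, pos + nchar(ref) - 1L) == ref)
  paste0(substr(G, 1L, pos - 1L), alt, substr(G, pos + nchar(ref), nchar(G)))
}
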