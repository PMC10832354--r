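#' Parse a UCSC chain file
#'
#' Reads a chain file (plain text or gzip, detected by magic bytes) into a
#' list of \linkS4class{Chain} objects. Each stanza is a header line
#' \code{chain score tName tSize tStrand tStart tEnd qName qSize qStrand
#' qStart qEnd id} followed by alignment lines \code{size [dt dq]} and a
#' terminal bare \code{size} line. Comment lines starting with \code{#} and
#' extra blank lines are tolerated. Malformed input raises an error naming
#' the offending line number.
#'
#' @param file path to a \code{.chain} or \code{.chain.gz} file, or a
#'   character vector of lines (when \code{length(file) > 1} or it contains
#'   a newline).
#' @return list of \linkS4class{Chain}, in file order; empty list for empty
#'   input.
#' @examples
#' ch <- parseChainFile(c("chain 100 src 20 + 0 20 dst 20 + 0 20 1", "20", ""))
#' chainBlocks(ch[[1]])
#' @export
parseChainFile <- function(file) {
  isText <- length(file) > 1L || !nzchar(file[1L]) ||
    grepl("\n", file[1L]) || grepl("^(chain|#)[ \t]", file[1L])
  if (isText) {
    lines <- unlist(strsplit(file, "\n", fixed = TRUE), use.names = FALSE)
  } else {
    if (!file.exists(file)) stop("no such chain file: ", file)
    con <- file(file, "rb")
    magic <- readBin(con, "raw", n = 2L)
    close(con)
    con <- if (length(magic) == 2L && identical(as.integer(magic), c(31L, 139L)))
      gzfile(file, "rt") else file(file, "rt")
    on.exit(close(con))
    lines <- readLines(con)
  }
  .parseChainLines(lines)
}

.parseChainLines <- function(lines) {
  chains <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "#")) { i <- i + 1L; next }
    if (!startsWith(line, "chain"))
      stop("line ", i, ": expected 'chain' header, got: ", line)
    f <- strsplit(line, "[ \t]+")[[1L]]
    if (length(f) != 13L)
      stop("line ", i, ": malformed chain header (", length(f),
           " fields, expected 13)")
    if (f[5L] != "+")
      stop("line ", i, ": source strand must be '+', got '", f[5L], "'")
    if (!f[10L] %in% c("+", "-"))
      stop("line ", i, ": unknown strand symbol '", f[10L], "'")
    hdr <- list(score = as.numeric(f[2L]),
                tName = f[3L], tSize = as.integer(f[4L]),
                tStart = as.integer(f[6L]), tEnd = as.integer(f[7L]),
                qName = f[8L], qSize = as.integer(f[9L]), qStrand = f[10L],
                qStart = as.integer(f[11L]), qEnd = as.integer(f[12L]),
                id = as.integer(f[13L]))
    if (anyNA(unlist(hdr[c("tSize", "tStart", "tEnd", "qSize",
                           "qStart", "qEnd", "id")])))
      stop("line ", i, ": non-numeric field in chain header")
    i <- i + 1L
    sizes <- integer(); dts <- integer(); dqs <- integer()
    done <- FALSE
    while (i <= n && !done) {
      bl <- trimws(lines[i])
      if (startsWith(bl, "#")) { i <- i + 1L; next }
      if (!nzchar(bl)) break
      g <- suppressWarnings(as.integer(strsplit(bl, "[ \t]+")[[1L]]))
      if (anyNA(g) || !length(g) %in% c(1L, 3L))
        stop("line ", i, ": malformed alignment line: ", bl)
      sizes <- c(sizes, g[1L])
      if (length(g) == 3L) {
        dts <- c(dts, g[2L]); dqs <- c(dqs, g[3L])
      } else {
        done <- TRUE
      }
      i <- i + 1L
    }
    if (!done)
      stop("line ", i, ": chain stanza not terminated by a bare size line")
    tStarts <- hdr$tStart + cumsum(c(0L, sizes[-length(sizes)] + dts))
    qStarts <- hdr$qStart + cumsum(c(0L, sizes[-length(sizes)] + dqs))
    if (tStarts[length(sizes)] + sizes[length(sizes)] != hdr$tEnd)
      stop("line ", i - 1L, ": block arithmetic does not match t span ",
           "of chain ", hdr$id)
    if (qStarts[length(sizes)] + sizes[length(sizes)] != hdr$qEnd)
      stop("line ", i - 1L, ": block arithmetic does not match q span ",
           "of chain ", hdr$id)
    chains[[length(chains) + 1L]] <- new("Chain",
      score = hdr$score, tName = hdr$tName, tSize = hdr$tSize,
      tStart = hdr$tStart, tEnd = hdr$tEnd,
      qName = hdr$qName, qSize = hdr$qSize, qStrand = hdr$qStrand,
      qStart = hdr$qStart, qEnd = hdr$qEnd, id = hdr$id,
      blocks = data.frame(tStart = tStarts, qStart = qStarts, size = sizes))
  }
  chains
}

#' Write chains in UCSC chain format
#'
#' Emits the same dialect \code{\link{parseChainFile}} reads; used by the
#' synthetic fixture generator.
#'
#' @param chains list of \linkS4class{Chain}.
#' @param file output path (gzip-compressed when it ends in \code{.gz}).
#' @return invisibly, the path.
#' @export
writeChainFile <- function(chains, file) {
  con <- if (grepl("\\.gz$", file)) gzfile(file, "wt") else file(file, "wt")
  on.exit(close(con))
  for (ch in chains) {
    writeLines(sprintf("chain %s %s %d + %d %d %s %d %s %d %d %d",
                       format(ch@score, scientific = FALSE),
                       ch@tName, ch@tSize, ch@tStart, ch@tEnd,
                       ch@qName, ch@qSize, ch@qStrand, ch@qStart, ch@qEnd,
                       ch@id), con)
    b <- ch@blocks
    k <- nrow(b)
    if (k > 1L) {
      dt <- b$tStart[-1L] - (b$tStart[-k] + b$size[-k])
      dq <- b$qStart[-1L] - (b$qStart[-k] + b$size[-k])
      writeLines(sprintf("%d %d %d", b$size[-k], dt, dq), con)
    }
    writeLines(c(sprintf("%d", b$size[k]), ""), con)
  }
  invisible(file)
}

#' Build an interval index over parsed chains
#'
#' Constructs a \linkS4class{ChainIndex} answering per-base
#' source-to-destination queries in logarithmic time. Source bases covered
#' by more than one block are recorded as ambiguous, not silently resolved.
#'
#' @param chains list of \linkS4class{Chain} from
#'   \code{\link{parseChainFile}}.
#' @return \linkS4class{ChainIndex}.
#' @export
buildChainIndex <- function(chains) {
  if (length(chains) == 0L) {
    gr <- GenomicRanges::GRanges()
    mcols(gr)$chain <- integer(); mcols(gr)$block <- integer()
    return(new("ChainIndex", chains = chains, blocks = gr,
               lookup = list()))
  }
  parts <- lapply(seq_along(chains), function(i) {
    b <- chains[[i]]@blocks
    gr <- GenomicRanges::GRanges(chains[[i]]@tName,
      IRanges::IRanges(start = b$tStart + 1L, end = b$tStart + b$size))
    mcols(gr)$chain <- i
    mcols(gr)$block <- seq_len(nrow(b))
    gr
  })
  gr <- suppressWarnings(do.call(c, parts))
  tab <- data.frame(
    contig = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    chain = mcols(gr)$chain, block = mcols(gr)$block,
    stringsAsFactors = FALSE)
  lookup <- lapply(split(tab, tab$contig), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    d$maxEnd <- cummax(d$end)
    d
  })
  new("ChainIndex", chains = chains, blocks = gr, lookup = lookup)
}

#' Map one source base to the destination assembly
#'
#' Point query through the chain index. Positions inside chain gaps, outside
#' every chain, or on unknown contigs answer \code{"unmapped"}; positions
#' covered by more than one block answer \code{"ambiguous"}. For a
#' \code{'-'} strand chain the returned position is converted to the
#' forward strand of the destination contig.
#'
#' @param index \linkS4class{ChainIndex}.
#' @param contig source contig name.
#' @param pos 1-based source position.
#' @return \linkS4class{BaseMapping}.
#' @export
mapBase <- function(index, contig, pos) {
  stopifnot(pos >= 1L)
  unmapped <- new("BaseMapping", status = "unmapped",
                  dstContig = NA_character_, dstPos = NA_integer_,
                  strand = NA_character_, chainId = NA_integer_)
  d <- index@lookup[[contig]]
  if (is.null(d)) return(unmapped)
  i <- findInterval(pos, d$start)
  hits <- integer()
  j <- i
  while (j >= 1L && d$maxEnd[j] >= pos) {
    if (d$end[j] >= pos) hits <- c(hits, j)
    j <- j - 1L
  }
  nh <- length(hits)
  if (nh == 0L) return(unmapped)
  if (nh > 1L)
    return(new("BaseMapping", status = "ambiguous",
               dstContig = NA_character_, dstPos = NA_integer_,
               strand = NA_character_, chainId = NA_integer_))
  ci <- d$chain[hits]
  bi <- d$block[hits]
  ch <- index@chains[[ci]]
  b <- ch@blocks[bi, ]
  off <- (pos - 1L) - b$tStart
  if (ch@qStrand == "+") {
    dstPos <- b$qStart + off + 1L
  } else {
    dstPos <- ch@qSize - (b$qStart + off)
  }
  new("BaseMapping", status = "mapped", dstContig = ch@qName,
      dstPos = as.integer(dstPos), strand = ch@qStrand, chainId = ch@id)
}

#' Report source regions covered by more than one chain block
#'
#' UCSC-style liftover chains cover every source base at most once; this
#' validation surfaces any violation as data rather than an error.
#'
#' @param chains list of \linkS4class{Chain}.
#' @return data.frame with columns \code{contig}, \code{start}, \code{end}
#'   (1-based inclusive) and \code{chainIds} (comma-joined ids covering the
#'   interval); zero rows when coverage is unique.
#' @export
validateUniqueCoverage <- function(chains) {
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer(), chainIds = character(),
                      stringsAsFactors = FALSE)
  idx <- buildChainIndex(chains)
  gr <- idx@blocks
  if (length(gr) < 2L) return(empty)
  cov <- GenomicRanges::coverage(gr)
  multi <- GenomicRanges::GRanges(IRanges::slice(cov, lower = 2L,
                                                 rangesOnly = TRUE))
  if (length(multi) == 0L) return(empty)
  out <- lapply(seq_along(multi), function(k) {
    hits <- GenomicRanges::findOverlaps(multi[k], gr)
    ids <- sort(unique(vapply(mcols(gr)$chain[S4Vectors::subjectHits(hits)],
      function(ci) idx@chains[[ci]]@id, integer(1))))
    data.frame(contig = as.character(GenomeInfoDb::seqnames(multi[k])),
               start = GenomicRanges::start(multi[k]),
               end = GenomicRanges::end(multi[k]),
               chainIds = paste(ids, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Invert a chain
#'
#' Produces the chain describing the same alignment in the opposite
#' direction (destination as source). Inverting twice recovers the original
#' chain. For a \code{'-'} strand chain the inverse is again \code{'-'}
#' stranded with offsets recomputed per the UCSC reverse-strand convention.
#'
#' @param chain a \linkS4class{Chain}.
#' @return the inverted \linkS4class{Chain}.
#' @export
invertChain <- function(chain) {
  b <- chain@blocks
  if (chain@qStrand == "+") {
    nb <- data.frame(tStart = b$qStart, qStart = b$tStart, size = b$size)
    new("Chain", score = chain@score,
        tName = chain@qName, tSize = chain@qSize,
        tStart = chain@qStart, tEnd = chain@qEnd,
        qName = chain@tName, qSize = chain@tSize, qStrand = "+",
        qStart = chain@tStart, qEnd = chain@tEnd, id = chain@id,
        blocks = nb)
  } else {
    nb <- data.frame(tStart = chain@qSize - (b$qStart + b$size),
                     qStart = chain@tSize - (b$tStart + b$size),
                     size = b$size)
    nb <- nb[order(nb$tStart), , drop = FALSE]
    rownames(nb) <- NULL
    new("Chain", score = chain@score,
        tName = chain@qName, tSize = chain@qSize,
        tStart = as.integer(chain@qSize - chain@qEnd),
        tEnd = as.integer(chain@qSize - chain@qStart),
        qName = chain@tName, qSize = chain@tSize, qStrand = "-",
        qStart = as.integer(chain@tSize - chain@tEnd),
        qEnd = as.integer(chain@tSize - chain@tStart), id = chain@id,
        blocks = nb)
  }
}

# Locate the chain gap (if any) containing source position pos; returns
# list(dt, dq, chain) of the enclosing gap, or NULL when pos is not inside
# any chain's span or sits inside a block.
.chainGapAt <- function(index, contig, pos) {
  p0 <- pos - 1L
  for (ci in seq_along(index@chains)) {
    ch <- index@chains[[ci]]
    if (ch@tName != contig) next
    if (p0 < ch@tStart || p0 >= ch@tEnd) next
    b <- ch@blocks
    tEnds <- b$tStart + b$size
    inBlock <- any(p0 >= b$tStart & p0 < tEnds)
    if (inBlock) next
    k <- findInterval(p0, b$tStart)  # gap between block k and k+1
    if (k >= 1L && k < nrow(b)) {
      dt <- b$tStart[k + 1L] - tEnds[k]
      dq <- b$qStart[k + 1L] - (b$qStart[k] + b$size[k])
      return(list(dt = dt, dq = dq, chain = ch))
    }
  }
  NULL
}

#' @describeIn Chain-class block table accessor (0-based offsets as stored).
#' @param object,x a \linkS4class{Chain}.
#' @export
chainBlocks <- function(x) x@blocks

#' @export
setMethod("show", "Chain", function(object) {
  cat(sprintf("Chain %d: %s:%d-%d (+) -> %s:%d-%d (%s), %d block(s), score %s\n",
              object@id, object@tName, object@tStart, object@tEnd,
              object@qName, object@qStart, object@qEnd, object@qStrand,
              nrow(object@blocks), format(object@score)))
})

#' @export
setMethod("show", "ChainIndex", function(object) {
  cat(sprintf("ChainIndex over %d chain(s), %d block(s), contigs: %s\n",
              length(object@chains), length(object@blocks),
              paste(unique(vapply(object@chains, function(c) c@tName,
                                  character(1))), collapse = ", ")))
})

#' @export
setMethod("show", "BaseMapping", function(object) {
  if (object@status == "mapped")
    cat(sprintf("BaseMapping: %s:%d (%s) via chain %d\n", object@dstContig,
                object@dstPos, object@strand, object@chainId))
  else cat("BaseMapping:", object@status, "\n")
})
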