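# Synthetic assembly pairs: paired genomes differing by planted edits, the
# exact chain describing their alignment, a VCF of planted variants and a
# truth table of expected lift outcomes. Every engine path (fast path,
# anchor path, strand flip, chain-gap realignment, drops) is exercised
# without external downloads.

.BASES <- c("A", "C", "G", "T")

.randBase <- function(exclude = character()) {
  sample(setdiff(.BASES, exclude), 1L)
}

.randSeq <- function(n) paste(sample(.BASES, n, replace = TRUE),
                              collapse = "")

#' Generate a synthetic assembly pair with planted variants
#'
#' Builds a random source genome, plants variants of all scenario kinds,
#' derives the destination genome by applying the planned edits, and
#' constructs the chain (and its inverse) exactly from the edit positions.
#' Deterministic under \code{seed}.
#'
#' Scenario kinds and their expected lift outcomes:
#' \itemize{
#'   \item \code{untouched_snv}, \code{untouched_str}: no destination edit;
#'     \code{REF_UNCHANGED}.
#'   \item \code{substitute_to_alt}: the destination carries the (planted)
#'     alternate allele; \code{REF_SWAPPED}. SNV payloads (some
#'     tri-allelic) and STR-indel payloads; in \code{"gap"} chain mode SNV
#'     substitutions are excluded from chain blocks as 1-bp double-sided
#'     gaps (BLAT-style), in \code{"mismatch"} mode they sit inside blocks.
#'   \item \code{substitute_to_third_allele}: the destination carries a
#'     base matching no allele; \code{REF_ADDED}.
#'   \item \code{str_resize}: the destination repeat count differs from
#'     both alleles; \code{REF_ADDED}. Some STR edits (option
#'     \code{gapShift}) place the chain gap over the 3' anchor base to
#'     force the realignment recovery path.
#'   \item \code{insert}: destination-only insertion near an unedited
#'     variant; \code{REF_UNCHANGED}.
#'   \item \code{delete}: the variant lies inside a source segment absent
#'     from the destination; \code{DROPPED}/unmapped_both_anchors.
#'   \item \code{invert_segment}: the variant lies inside a
#'     reverse-complemented segment mapped by a '-' strand chain;
#'     \code{REF_UNCHANGED} or \code{REF_SWAPPED}, strand-flipped.
#'   \item \code{translocate_gap}: the segment is replaced by unrelated
#'     sequence and excluded from the chain;
#'     \code{DROPPED}/unmapped_both_anchors.
#' }
#'
#' @param seed integer seed (mandatory; all randomness derives from it).
#' @param contigLen source contig length in bp (default 50000).
#' @param nVariants number of planted variants (default 200).
#' @param strUnitLens repeat-unit lengths sampled for STR loci (default
#'   2:4).
#' @param mode chain dialect, \code{"gap"} or \code{"mismatch"}.
#' @param contig contig name used for both assemblies.
#' @return \linkS4class{AssemblyPair}.
#' @export
generateAssemblyPair <- function(seed, contigLen = 50000L,
                                 nVariants = 200L,
                                 strUnitLens = 2:4,
                                 mode = c("gap", "mismatch"),
                                 contig = "chr1") {
  mode <- match.arg(mode)
  set.seed(seed)
  w <- contigLen %/% nVariants
  if (w < 120L)
    stop("infeasible plan: need at least 120 bp per variant window")

  counts <- round(nVariants * c(untouched_snv = 0.20, untouched_str = 0.10,
                                sub_alt_snv = 0.15, sub_alt_tri = 0.05,
                                sub_third = 0.10, sub_alt_str = 0.10,
                                str_resize = 0.10, insert = 0.05,
                                delete = 0.05, invert = 0.03,
                                invert_swap = 0.02, translocate = 0.05))
  counts["untouched_snv"] <- counts["untouched_snv"] +
    (nVariants - sum(counts))
  kinds <- sample(rep(names(counts), counts))

  srcBases <- sample(.BASES, contigLen, replace = TRUE)

  plans <- vector("list", nVariants)
  for (i in seq_len(nVariants)) {
    kind <- kinds[i]
    center <- (i - 1L) * w + w %/% 2L
    plan <- list(kind = kind, center = center)
    if (kind %in% c("untouched_str", "sub_alt_str", "str_resize")) {
      u <- sample(strUnitLens, 1L)
      a <- sample(4:7, 1L)
      unit <- .randSeq(u)
      rs <- center - (a * u) %/% 2L
      re <- rs + a * u - 1L
      srcBases[rs:re] <- strsplit(strrep(unit, a), "")[[1L]]
      # make the run maximal: boundary bases break unit periodicity
      srcBases[rs - 1L] <- .randBase(substr(unit, u, u))
      srcBases[re + 1L] <- .randBase(substr(unit, 1L, 1L))
      plan$u <- u; plan$a <- a; plan$unit <- unit
      plan$rs <- rs; plan$re <- re
      plan$gapShift <- kind != "untouched_str" && mode == "gap" &&
        stats::runif(1) < 0.3
    }
    plans[[i]] <- plan
  }
  src <- paste(srcBases, collapse = "")

  ops <- list()
  truthRows <- list()
  records <- list()
  addOp <- function(srcStart, srcLen, dstStr, type) {
    ops[[length(ops) + 1L]] <<- list(srcStart = srcStart, srcLen = srcLen,
                                     dstStr = dstStr, type = type)
  }
  at <- function(p) substr(src, p, p)

  for (i in seq_len(nVariants)) {
    p <- plans[[i]]
    kind <- p$kind
    center <- p$center
    expect <- list(status = "REF_UNCHANGED", reason = NA_character_,
                   strand = FALSE, gap = FALSE, promoted = NA_integer_)
    rec <- NULL
    if (kind == "untouched_snv") {
      ref <- at(center); alt <- .randBase(ref)
      rec <- list(pos = center, ref = ref, alt = alt)
    } else if (kind == "untouched_str") {
      rec <- .strRecord(src, p)
    } else if (kind %in% c("sub_alt_snv", "sub_alt_tri", "sub_third")) {
      ref <- at(center)
      alt1 <- .randBase(ref)
      if (kind == "sub_alt_tri") {
        alt2 <- .randBase(c(ref, alt1))
        rec <- list(pos = center, ref = ref, alt = c(alt1, alt2))
        dstBase <- alt2
        expect$status <- "REF_SWAPPED"; expect$promoted <- 2L
      } else if (kind == "sub_alt_snv") {
        rec <- list(pos = center, ref = ref, alt = alt1)
        dstBase <- alt1
        expect$status <- "REF_SWAPPED"; expect$promoted <- 1L
      } else {
        rec <- list(pos = center, ref = ref, alt = alt1)
        dstBase <- .randBase(c(ref, alt1))
        expect$status <- "REF_ADDED"
      }
      if (mode == "gap") {
        addOp(center, 1L, dstBase, "gap")
        expect$gap <- TRUE
      } else {
        addOp(center, 1L, dstBase, "block")
      }
    } else if (kind %in% c("sub_alt_str", "str_resize")) {
      rec <- .strRecord(src, p)
      cNew <- if (kind == "sub_alt_str") rec$bCount else {
        cand <- setdiff(max(1L, p$a - 3L):(p$a + 3L), c(p$a, rec$bCount))
        sample(cand, 1L)
      }
      expect$status <- if (kind == "sub_alt_str") "REF_SWAPPED"
                       else "REF_ADDED"
      if (kind == "sub_alt_str") expect$promoted <- 1L
      expect$gap <- TRUE
      u <- p$u; a <- p$a; rs <- p$rs; re <- p$re
      if (cNew < a) {
        d <- a - cNew
        if (isTRUE(p$gapShift))
          addOp(rs + cNew * u, d * u + 1L, at(re + 1L), "gap")
        else addOp(rs + cNew * u, d * u, "", "gap")
      } else if (cNew > a) {
        d <- cNew - a
        if (isTRUE(p$gapShift))
          addOp(re + 1L, 1L, paste0(strrep(p$unit, d), at(re + 1L)), "gap")
        else addOp(re + 1L, 0L, strrep(p$unit, d), "gap")
      }
    } else if (kind == "insert") {
      pos <- center - 40L
      ref <- at(pos); alt <- .randBase(ref)
      rec <- list(pos = pos, ref = ref, alt = alt)
      addOp(center, 0L, .randSeq(8L), "gap")
    } else if (kind == "delete") {
      ref <- at(center); alt <- .randBase(ref)
      rec <- list(pos = center, ref = ref, alt = alt)
      addOp(center - 20L, 40L, "", "gap")
      expect$status <- "DROPPED"
      expect$reason <- "unmapped_both_anchors"
      expect$gap <- TRUE
    } else if (kind %in% c("invert", "invert_swap")) {
      segFrom <- center - 30L; segLen <- 60L
      seg <- substr(src, segFrom, segFrom + segLen - 1L)
      ref <- at(center); alt <- .randBase(ref)
      rec <- list(pos = center, ref = ref, alt = alt)
      if (kind == "invert_swap") {
        substr(seg, center - segFrom + 1L, center - segFrom + 1L) <- alt
        expect$status <- "REF_SWAPPED"; expect$promoted <- 1L
      }
      addOp(segFrom, segLen, .revComp(seg), "invert")
      expect$strand <- TRUE
    } else if (kind == "translocate") {
      ref <- at(center); alt <- .randBase(ref)
      rec <- list(pos = center, ref = ref, alt = alt)
      addOp(center - 25L, 50L, .randSeq(50L), "gap")
      expect$status <- "DROPPED"
      expect$reason <- "unmapped_both_anchors"
      expect$gap <- TRUE
    }
    records[[i]] <- rec
    truthRows[[i]] <- data.frame(
      idx = i, kind = kind, pos = rec$pos, ref = rec$ref,
      alt = paste(rec$alt, collapse = ","),
      expectStatus = expect$status, expectReason = expect$reason,
      expectStrand = expect$strand, gap = expect$gap,
      promotedAlt = expect$promoted, stringsAsFactors = FALSE)
  }

  built <- .buildDstAndChains(src, ops, contig, contigLen)
  header <- .fixtureHeader(contig, contigLen)
  vrecs <- lapply(seq_len(nVariants), function(i)
    .decorateRecord(records[[i]], contig, i, header))
  truth <- do.call(rbind, truthRows)
  truth$key <- vapply(vrecs, function(r)
    paste(r@contig, r@pos, r@ref, paste(r@alt, collapse = ","), sep = ":"),
    character(1))

  new("AssemblyPair",
      src = Biostrings::DNAStringSet(stats::setNames(src, contig)),
      dst = Biostrings::DNAStringSet(stats::setNames(built$dst, contig)),
      chains = built$chains,
      invChains = lapply(built$chains, invertChain),
      header = header, records = vrecs, truth = truth, mode = mode)
}

# STR indel record on a maximal (unit)^a run: ref has a units, alt has
# bCount = a +/- d units, anchored one base left of the run.
.strRecord <- function(src, p) {
  d <- sample(1:2, 1L)
  del <- stats::runif(1) < 0.5 && p$a - d >= 1L
  anchor <- substr(src, p$rs - 1L, p$rs - 1L)
  if (del) {
    ref <- substr(src, p$rs - 1L, p$rs - 1L + d * p$u)
    alt <- anchor
    bCount <- p$a - d
  } else {
    ref <- anchor
    alt <- paste0(anchor, strrep(p$unit, d))
    bCount <- p$a + d
  }
  list(pos = p$rs - 1L, ref = ref, alt = alt, bCount = bCount)
}

# Apply the op plan: derive the destination sequence, the main '+' chain
# and one '-' chain per inverted segment, exactly from the edit positions.
.buildDstAndChains <- function(src, ops, contig, contigLen) {
  ord <- order(vapply(ops, function(o) o$srcStart, numeric(1)))
  ops <- ops[ord]
  parts <- character()
  blocks <- list()
  invs <- list()
  s <- 1L; d <- 1L
  curT <- NA_integer_; curD <- NA_integer_; curLen <- 0L
  flush <- function() {
    if (!is.na(curT) && curLen > 0L)
      blocks[[length(blocks) + 1L]] <<- c(tStart = curT - 1L,
                                          qStart = curD - 1L,
                                          size = curLen)
    curT <<- NA_integer_; curD <<- NA_integer_; curLen <<- 0L
  }
  emitAligned <- function(from, len, dstStr) {
    if (len == 0L) return()
    if (is.na(curT)) { curT <<- from; curD <<- d }
    curLen <<- curLen + len
    parts[[length(parts) + 1L]] <<- dstStr
    s <<- from + len
    d <<- d + len
  }
  for (op in ops) {
    lead <- op$srcStart - s
    if (lead < 0L) stop("infeasible plan: overlapping edits")
    if (lead > 0L) emitAligned(s, lead, substr(src, s, op$srcStart - 1L))
    if (op$type == "block") {
      emitAligned(op$srcStart, op$srcLen, op$dstStr)
    } else if (op$type == "gap") {
      flush()
      if (nzchar(op$dstStr)) {
        parts[[length(parts) + 1L]] <- op$dstStr
        d <- d + nchar(op$dstStr)
      }
      s <- op$srcStart + op$srcLen
    } else if (op$type == "invert") {
      flush()
      invs[[length(invs) + 1L]] <- c(srcStart = op$srcStart,
                                     len = op$srcLen, dstStart = d)
      parts[[length(parts) + 1L]] <- op$dstStr
      d <- d + op$srcLen
      s <- op$srcStart + op$srcLen
    }
  }
  if (s <= contigLen) emitAligned(s, contigLen - s + 1L,
                                  substr(src, s, contigLen))
  flush()
  dst <- paste(parts, collapse = "")
  dstLen <- nchar(dst)
  bdf <- as.data.frame(do.call(rbind, blocks))
  mainChain <- new("Chain", score = 1e6,
    tName = contig, tSize = as.integer(contigLen),
    tStart = as.integer(bdf$tStart[1L]),
    tEnd = as.integer(bdf$tStart[nrow(bdf)] + bdf$size[nrow(bdf)]),
    qName = contig, qSize = as.integer(dstLen), qStrand = "+",
    qStart = as.integer(bdf$qStart[1L]),
    qEnd = as.integer(bdf$qStart[nrow(bdf)] + bdf$size[nrow(bdf)]),
    id = 1L,
    blocks = data.frame(tStart = as.integer(bdf$tStart),
                        qStart = as.integer(bdf$qStart),
                        size = as.integer(bdf$size)))
  chains <- list(mainChain)
  for (k in seq_along(invs)) {
    iv <- invs[[k]]
    qs <- dstLen - (iv[["dstStart"]] - 1L) - iv[["len"]]
    chains[[length(chains) + 1L]] <- new("Chain", score = 1e4,
      tName = contig, tSize = as.integer(contigLen),
      tStart = as.integer(iv[["srcStart"]] - 1L),
      tEnd = as.integer(iv[["srcStart"]] - 1L + iv[["len"]]),
      qName = contig, qSize = as.integer(dstLen), qStrand = "-",
      qStart = as.integer(qs), qEnd = as.integer(qs + iv[["len"]]),
      id = as.integer(k + 1L),
      blocks = data.frame(tStart = as.integer(iv[["srcStart"]] - 1L),
                          qStart = as.integer(qs),
                          size = as.integer(iv[["len"]])))
  }
  list(dst = dst, chains = chains)
}

.fixtureHeader <- function(contig, contigLen) {
  lines <- c(
    "##fileformat=VCFv4.3",
    sprintf("##contig=<ID=%s,length=%d>", contig, contigLen),
    '##INFO=<ID=AF,Number=A,Type=Float,Description="Alternate allele frequency">',
    '##INFO=<ID=AC,Number=A,Type=Integer,Description="Alternate allele count in genotypes">',
    '##INFO=<ID=AN,Number=1,Type=Integer,Description="Total number of alleles in genotypes">',
    '##INFO=<ID=ES,Number=A,Type=Float,Description="Effect size estimate">',
    '##INFO=<ID=EZ,Number=A,Type=Float,Description="Z-score of effect size">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=PL,Number=G,Type=Integer,Description="Phred-scaled genotype likelihoods">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
  .parseVcfHeader(lines,
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3")
}

# Attach realistic annotations: genotypes for 3 samples (third phased),
# AD/PL/DP, AC/AN computed from the genotypes, AF, and GWAS-VCF ES/EZ on
# bi-allelic SNVs.
.decorateRecord <- function(rec, contig, idx, header) {
  nAlt <- length(rec$alt)
  n <- nAlt + 1L
  gts <- character(3L)
  acount <- integer(nAlt)
  anTot <- 0L
  for (s in 1:3) {
    pair <- sort(sample(0:nAlt, 2L, replace = TRUE,
                        prob = c(2, rep(1, nAlt))))
    sep <- if (s == 3L) "|" else "/"
    if (s == 3L && stats::runif(1) < 0.5) pair <- rev(pair)
    gts[s] <- paste(pair, collapse = sep)
    for (a in pair) if (a > 0L) acount[a] <- acount[a] + 1L
    anTot <- anTot + 2L
  }
  ad <- sample(5:20, n, replace = TRUE)
  nG <- (n * (n + 1L)) %/% 2L
  pl <- sample(0:99, nG, replace = TRUE)
  pl[sample(nG, 1L)] <- 0L
  af <- round(stats::runif(nAlt, 0.05, 0.9 / nAlt), 2L)
  info <- list(AF = .fmtNum(af), AC = as.character(acount),
               AN = as.character(anTot))
  if (nAlt == 1L && nchar(rec$ref) == 1L && nchar(rec$alt) == 1L) {
    info$ES <- .fmtNum(round(stats::rnorm(1, 0, 0.3), 4L))
    info$EZ <- .fmtNum(round(stats::rnorm(1, 0, 2), 4L))
  }
  geno <- list(GT = gts,
               AD = rep(paste(ad, collapse = ","), 3L),
               PL = rep(paste(pl, collapse = ","), 3L),
               DP = rep(as.character(sum(ad)), 3L))
  variantRecord(contig, rec$pos, rec$ref, rec$alt,
                id = sprintf("var%04d", idx), qual = 50,
                filter = "PASS", info = info, geno = geno)
}

#' Mirror an assembly pair to the opposite strand
#'
#' Returns the pair whose destination genome is the reverse complement of
#' the original destination; every '+' chain becomes a '-' chain (and vice
#' versa) with identical offsets, because UCSC reverse-strand offsets are
#' counted on the reverse-complemented destination contig. Expected
#' strand flips in the truth table are toggled. Used to verify that
#' mirrored '+'/'-' fixtures produce identical lift results up to reverse
#' complement.
#'
#' @param pair \linkS4class{AssemblyPair}.
#' @return the mirrored \linkS4class{AssemblyPair}.
#' @export
mirrorAssemblyPair <- function(pair) {
  dstName <- names(pair@dst)
  mirrored <- Biostrings::reverseComplement(pair@dst)
  names(mirrored) <- dstName
  chains <- lapply(pair@chains, function(ch) {
    ch@qStrand <- if (ch@qStrand == "+") "-" else "+"
    ch
  })
  truth <- pair@truth
  truth$expectStrand <- !truth$expectStrand
  initialize(pair, dst = mirrored, chains = chains,
             invChains = lapply(chains, invertChain), truth = truth)
}

#' Write an assembly pair to disk
#'
#' Emits standard text formats: \code{src.fa} / \code{dst.fa} with
#' \code{.fai} indexes, \code{pair.chain}, \code{planted.vcf} and a
#' tab-separated \code{truth.tsv}.
#'
#' @param pair \linkS4class{AssemblyPair}.
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the written paths.
#' @export
writeAssemblyPair <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(src = file.path(dir, "src.fa"),
                dst = file.path(dir, "dst.fa"),
                chain = file.path(dir, "pair.chain"),
                vcf = file.path(dir, "planted.vcf"),
                truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(pair@src, paths$src)
  Biostrings::writeXStringSet(pair@dst, paths$dst)
  Rsamtools::indexFa(paths$src)
  Rsamtools::indexFa(paths$dst)
  writeChainFile(pair@chains, paths$chain)
  writeVcfFile(pair@header, pair@records, paths$vcf)
  utils::write.table(pair@truth, paths$truth, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(paths)
}

#' Score lift results against a pair's truth table
#'
#' Compares each result with the expected outcome planted by the
#' generator: status (and, for drops, the reason), strand flip, the
#' promoted alternate for swaps, and -- for every converted record --
#' that the emitted reference allele matches the destination genome at
#' its coordinates.
#'
#' @param results list of \linkS4class{LiftResult} parallel to
#'   \code{plantedRecords(pair)}.
#' @param pair \linkS4class{AssemblyPair}.
#' @return list with \code{overall} and \code{nonGap} exact-match
#'   fractions, \code{refValid} (fraction of converted records whose ref
#'   matches the destination), \code{n}, \code{confusion} (expected vs
#'   observed status table) and per-variant \code{ok} flags.
#' @export
truthCheck <- function(results, pair) {
  truth <- pair@truth
  stopifnot(length(results) == nrow(truth))
  obs <- vapply(results, liftStatus, character(1))
  ok <- logical(length(results))
  refOk <- rep(NA, length(results))
  for (i in seq_along(results)) {
    r <- results[[i]]
    good <- r@status == truth$expectStatus[i]
    if (good && r@status == "DROPPED")
      good <- identical(r@reason, truth$expectReason[i])
    if (good && r@status != "DROPPED")
      good <- r@strandFlipped == truth$expectStrand[i]
    if (good && !is.na(truth$promotedAlt[i]) && r@status == "REF_SWAPPED")
      good <- r@permutation[truth$promotedAlt[i] + 1L] == 0L
    ok[i] <- good
    if (r@status != "DROPPED") {
      rec <- r@record
      refOk[i] <- fetchSeq(pair@dst, rec@contig, rec@pos,
                           rec@pos + nchar(rec@ref) - 1L) == rec@ref
    }
  }
  list(overall = mean(ok),
       nonGap = mean(ok[!truth$gap]),
       refValid = mean(refOk, na.rm = TRUE),
       n = length(results),
       confusion = table(expected = truth$expectStatus, observed = obs),
       ok = ok)
}

#' @describeIn AssemblyPair-class source genome accessor.
#' @param x an \linkS4class{AssemblyPair}.
#' @export
srcGenome <- function(x) x@src

#' @describeIn AssemblyPair-class destination genome accessor.
#' @export
dstGenome <- function(x) x@dst

#' @describeIn AssemblyPair-class chain list accessor.
#' @export
pairChains <- function(x) x@chains

#' @describeIn AssemblyPair-class inverse chain list accessor.
#' @export
pairInvChains <- function(x) x@invChains

#' @describeIn AssemblyPair-class planted record list accessor.
#' @export
plantedRecords <- function(x) x@records

#' @describeIn AssemblyPair-class truth table accessor.
#' @export
truthTable <- function(x) x@truth

#' @export
setMethod("show", "AssemblyPair", function(object) {
  cat(sprintf(paste0("AssemblyPair: %d bp source, %d bp destination, ",
                     "%d chain(s), %d planted variant(s), mode '%s'\n"),
              sum(Biostrings::width(object@src)),
              sum(Biostrings::width(object@dst)),
              length(object@chains), length(object@records), object@mode))
})

#' Generate equivalent representations of a variant
#'
#' Produces alternative VCF representations of the same variant by
#' right-padding with following reference bases, left-extending with
#' preceding reference bases, and combinations of both -- i.e. records
#' that are not parsimonious and/or not left-aligned but edit the genome
#' identically. Used to verify that every representation of a variant
#' maximally extends to the identical record.
#'
#' @param rec a \linkS4class{VariantRecord} (any representation).
#' @param genome sequence accessor.
#' @param n number of representations to produce.
#' @return list of \linkS4class{VariantRecord} (length <= n; bounded by
#'   the contig edges).
#' @export
equivalentRepresentations <- function(rec, genome, n = 5L) {
  clen <- contigLength(genome, rec@contig)
  out <- list()
  for (k in seq_len(n)) {
    r <- rec
    nl <- sample(0:3, 1L)  # left extensions
    nr <- sample(0:3, 1L)  # right paddings
    al <- alleles(r)
    pos <- r@pos
    while (nl > 0L && pos > 1L) {
      b <- fetchSeq(genome, r@contig, pos - 1L, pos - 1L)
      al <- paste0(b, al)
      pos <- pos - 1L
      nl <- nl - 1L
    }
    e <- pos + nchar(al[1L]) - 1L
    while (nr > 0L && e < clen) {
      b <- fetchSeq(genome, r@contig, e + 1L, e + 1L)
      al <- paste0(al, b)
      e <- e + 1L
      nr <- nr - 1L
    }
    out[[k]] <- .withAlleles(r, pos, al[1L], al[-1L])
  }
  out
}
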