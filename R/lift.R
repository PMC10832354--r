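#' Lift engine options
#'
#' @param flank bp of extra context on each side of the extended region
#'   when realigning to recover an anchor (default 100).
#' @param maxRegionLen cap on the anchor span and destination fetch in bp
#'   (default 10000).
#' @param params \linkS4class{AlignmentParams} for anchor recovery.
#' @param dropNonPrimitives drop converted records that are no longer
#'   allelic primitives (default FALSE: they are kept and flagged).
#' @param recordSource record the original contig/position/alleles in the
#'   INFO tags \code{SRC_CONTIG}, \code{SRC_POS}, \code{SRC_REF_ALT}
#'   (default TRUE).
#' @return \linkS4class{LiftOptions}.
#' @export
liftOptions <- function(flank = 100L, maxRegionLen = 10000L,
                        params = alignmentParams(),
                        dropNonPrimitives = FALSE, recordSource = TRUE) {
  new("LiftOptions", flank = as.integer(flank),
      maxRegionLen = as.integer(maxRegionLen), params = params,
      dropNonPrimitives = dropNonPrimitives, recordSource = recordSource)
}

.dropped <- function(reason) {
  new("LiftResult", status = "DROPPED", record = NULL, reason = reason,
      permutation = integer(), novelRef = FALSE, strandFlipped = FALSE,
      becameNonPrimitive = FALSE)
}

#' @describeIn LiftResult-class conversion status accessor.
#' @param x a \linkS4class{LiftResult}.
#' @export
liftStatus <- function(x) x@status

#' @describeIn LiftResult-class drop reason accessor (NA unless dropped).
#' @export
liftReason <- function(x) x@reason

#' @describeIn LiftResult-class converted record accessor (NULL if
#'   dropped).
#' @export
liftedRecord <- function(x) x@record

#' @describeIn LiftResult-class allele permutation accessor (0-based new
#'   index per old allele).
#' @export
allelePermutation <- function(x) x@permutation

#' @export
setMethod("show", "LiftResult", function(object) {
  if (object@status == "DROPPED") {
    cat("LiftResult: DROPPED (", object@reason, ")\n", sep = "")
  } else {
    r <- object@record
    cat(sprintf("LiftResult: %s%s -> %s:%d %s>%s\n", object@status,
                if (object@strandFlipped) " (strand flip)" else "",
                r@contig, r@pos, r@ref, paste(r@alt, collapse = ",")))
  }
})

#' Convert one VCF record to the destination assembly
#'
#' Orchestrates the conversion of a single record. Records whose allele
#' pairs are all single-base substitutions take the SNV fast path: the
#' polymorphic base is mapped directly and the destination base decides
#' the outcome. Any other record -- and any SNV whose base falls in a
#' chain gap -- takes the anchor path: the record is maximally extended,
#' the 5' and 3' anchor bases are mapped through the chain (an anchor
#' lost in a chain gap is recovered by affine-gap realignment when the
#' other anchor mapped), and the destination sequence between the mapped
#' anchors decides whether the reference allele is unchanged, swapped
#' with an alternate, or novel. Destination anchor bases are not required
#' to equal the source anchor bases. On success the returned record is
#' normalized (left-aligned, parsimonious) against the destination
#' genome, allele-indexed annotations are permuted, INFO/END is
#' recomputed, and the source coordinates are optionally recorded.
#' Failures never raise: they return status \code{DROPPED} with a reason
#' code.
#'
#' @param rec \linkS4class{VariantRecord}; its \code{ref} must match the
#'   source genome.
#' @param index \linkS4class{ChainIndex} from source to destination.
#' @param srcGenome,dstGenome sequence accessors (\code{DNAStringSet} or
#'   \code{FaFile}).
#' @param opts \linkS4class{LiftOptions}.
#' @param header optional \linkS4class{VcfHeader} driving annotation
#'   updates.
#' @return \linkS4class{LiftResult}.
#' @export
liftRecord <- function(rec, index, srcGenome, dstGenome,
                       opts = liftOptions(), header = NULL) {
  if (is.na(contigLength(srcGenome, rec@contig)))
    return(.dropped("unknown_contig"))
  al <- alleles(rec)
  if (any(.isSymbolicAllele(al)))
    return(.dropped("symbolic_unsupported"))
  .checkRefMatches(rec, srcGenome)
  wasPrimitive <- .isPrimitive(rec)

  if (all(nchar(al) == 1L)) {
    fast <- .liftSnvFastPath(rec, index, dstGenome, header, opts)
    if (!is.null(fast)) return(fast)
  }
  .liftAnchorPath(rec, index, srcGenome, dstGenome, opts, header,
                  wasPrimitive)
}

#' Batch conversion of records
#'
#' @param records list of \linkS4class{VariantRecord}.
#' @inheritParams liftRecord
#' @return list of \linkS4class{LiftResult}, in input order.
#' @export
liftRecords <- function(records, index, srcGenome, dstGenome,
                        opts = liftOptions(), header = NULL) {
  lapply(records, liftRecord, index = index, srcGenome = srcGenome,
         dstGenome = dstGenome, opts = opts, header = header)
}

# SNV fast path: convert the polymorphic base directly. Returns NULL to
# signal fallthrough to the anchor path when the base is not covered by
# the chain.
.liftSnvFastPath <- function(rec, index, dstGenome, header, opts) {
  m <- mapBase(index, rec@contig, rec@pos)
  if (m@status == "ambiguous") return(.dropped("ambiguous_mapping"))
  if (m@status == "unmapped") return(NULL)
  flipped <- m@strand == "-"
  al <- alleles(rec)
  if (flipped) al <- .complement(al)
  dstBase <- fetchSeq(dstGenome, m@dstContig, m@dstPos, m@dstPos)
  hit <- match(dstBase, al)
  if (is.na(hit)) {
    perm <- .novelRefPermutation(length(al))
    newAl <- c(dstBase, al[-1L], al[1L])
    novel <- TRUE
  } else if (hit == 1L) {
    perm <- seq_along(al) - 1L
    newAl <- al
    novel <- FALSE
  } else {
    perm <- .swapPermutation(length(al), hit - 1L)
    newAl <- al
    newAl[1L] <- al[hit]
    newAl[hit] <- al[1L]
    novel <- FALSE
  }
  out <- initialize(rec, contig = m@dstContig, pos = m@dstPos,
                    ref = newAl[1L], alt = newAl[-1L])
  .finalizeLift(out, rec, perm, novel, flipped, TRUE, dstGenome, header,
                opts)
}

# Map both anchors of the maximally extended record; recover one lost
# anchor by realignment; resolve the destination sequence against the
# extended alleles.
.liftAnchorPath <- function(rec, index, srcGenome, dstGenome, opts, header,
                            wasPrimitive) {
  ext <- tryCatch(maximallyExtend(rec, srcGenome), error = function(e) e)
  if (inherits(ext, "error")) return(.dropped("unanchorable_at_edge"))
  span <- ext@anchor3 - ext@anchor5 + 1L
  if (span > opts@maxRegionLen) return(.dropped("region_too_long"))

  m5 <- mapBase(index, ext@contig, ext@anchor5)
  m3 <- mapBase(index, ext@contig, ext@anchor3)
  anyAmb <- m5@status == "ambiguous" || m3@status == "ambiguous"
  ok5 <- m5@status == "mapped"; ok3 <- m3@status == "mapped"
  if (!ok5 && !ok3)
    return(.dropped(if (anyAmb) "ambiguous_mapping"
                    else "unmapped_both_anchors"))
  if (xor(ok5, ok3)) {
    known <- if (ok5) m5 else m3
    rescued <- .recoverAnchor(ext, mappedSide = if (ok5) "5" else "3",
                              mKnown = known, index = index,
                              srcGenome = srcGenome, dstGenome = dstGenome,
                              opts = opts)
    if (is.null(rescued)) return(.dropped("realign_failed"))
    if (ok5) m3 <- rescued else m5 <- rescued
  } else {
    if (m5@chainId != m3@chainId || m5@dstContig != m3@dstContig ||
        m5@strand != m3@strand)
      return(.dropped("anchors_discordant"))
  }
  flipped <- m5@strand == "-"
  if (!flipped) {
    lo <- m5@dstPos; hi <- m3@dstPos
  } else {
    lo <- m3@dstPos; hi <- m5@dstPos
  }
  if (is.na(lo) || is.na(hi) || lo >= hi)
    return(.dropped("anchors_discordant"))
  if (hi - lo + 1L > opts@maxRegionLen)
    return(.dropped("region_too_long"))

  dstSeq <- fetchSeq(dstGenome, m5@dstContig, lo, hi)
  res <- .resolveAlleles(ext@alleles, dstSeq, if (flipped) "-" else "+")
  out <- variantRecord(m5@dstContig, lo, res$alleles[1L],
                       res$alleles[-1L], id = rec@id, qual = rec@qual,
                       filter = rec@filter, info = rec@info,
                       geno = rec@geno)
  .finalizeLift(out, rec, res$perm, res$novel, flipped, wasPrimitive,
                dstGenome, header, opts)
}

# Extract windows around the extended region and infer the failed
# anchor's destination position by global realignment. Returns a
# BaseMapping or NULL.
.recoverAnchor <- function(ext, mappedSide, mKnown, index, srcGenome,
                           dstGenome, opts) {
  srcLen <- contigLength(srcGenome, ext@contig)
  dstLen <- contigLength(dstGenome, mKnown@dstContig)
  region <- ext@anchor3 - ext@anchor5 + 1L
  failedPos <- if (mappedSide == "5") ext@anchor3 else ext@anchor5
  gap <- .chainGapAt(index, ext@contig, failedPos)
  net <- if (is.null(gap)) 0L else max(0L, gap$dq - gap$dt)
  wanted <- region + opts@flank + net
  if (wanted > opts@maxRegionLen) return(NULL)
  flipped <- mKnown@strand == "-"

  if (mappedSide == "5") {
    srcFrom <- ext@anchor5
    srcTo <- min(ext@anchor3 + opts@flank, srcLen)
    anchorOff <- ext@anchor3 - srcFrom + 1L
  } else {
    srcFrom <- max(1L, ext@anchor5 - opts@flank)
    srcTo <- ext@anchor3
    anchorOff <- ext@anchor5 - srcFrom + 1L
  }
  srcWindow <- fetchSeq(srcGenome, ext@contig, srcFrom, srcTo)

  known <- mKnown@dstPos
  goRight <- (mappedSide == "5") != flipped  # dst-forward direction of the
                                             # failed side from the known
  if (goRight) {
    dFrom <- known; dTo <- min(known + wanted - 1L, dstLen)
  } else {
    dFrom <- max(1L, known - wanted + 1L); dTo <- known
  }
  if (dFrom > dTo) return(NULL)
  dstWindow <- fetchSeq(dstGenome, mKnown@dstContig, dFrom, dTo)
  if (flipped) dstWindow <- .revComp(dstWindow)

  inf <- tryCatch(
    inferMissingAnchor(srcWindow, dstWindow, anchorOff, opts@params,
                       maxLen = opts@maxRegionLen + opts@flank),
    error = function(e) NULL)
  if (is.null(inf) || inf$lowConfidence || inf$offset < 1L) return(NULL)
  # map the window offset back to a forward-strand destination position;
  # the window was oriented so position 1 corresponds to its source side
  o <- inf$offset
  dstPos <- if (!flipped) {
    if (mappedSide == "5") dFrom + o - 1L else dTo - (nchar(dstWindow) - o)
  } else {
    # window reverse-complemented: position o counts from the high end
    if (mappedSide == "5") dTo - o + 1L else dFrom + (nchar(dstWindow) - o)
  }
  if (dstPos < 1L || dstPos > dstLen) return(NULL)
  new("BaseMapping", status = "mapped", dstContig = mKnown@dstContig,
      dstPos = as.integer(dstPos), strand = mKnown@strand,
      chainId = mKnown@chainId)
}

# Compare the destination sequence between the mapped anchors against the
# (strand-oriented) extended alleles. Alleles are pairwise distinct, so at
# most one can match.
.resolveAlleles <- function(extAlleles, dstSeq, strand) {
  oriented <- if (strand == "-") .revComp(extAlleles) else extAlleles
  n <- length(oriented)
  hit <- match(dstSeq, oriented)
  if (is.na(hit)) {
    list(alleles = c(dstSeq, oriented[-1L], oriented[1L]),
         perm = .novelRefPermutation(n), novel = TRUE)
  } else if (hit == 1L) {
    list(alleles = oriented, perm = seq_len(n) - 1L, novel = FALSE)
  } else {
    newAl <- oriented
    newAl[1L] <- oriented[hit]
    newAl[hit] <- oriented[1L]
    list(alleles = newAl, perm = .swapPermutation(n, hit - 1L),
         novel = FALSE)
  }
}

# Permute annotations, normalize against the destination, recompute END,
# record source coordinates, and assemble the LiftResult.
.finalizeLift <- function(out, orig, perm, novel, flipped, wasPrimitive,
                          dstGenome, header, opts) {
  out <- .applyPermutationToAnnotations(out, perm, novel, header)
  out <- normalizeRecord(out, dstGenome)
  out <- updateEnd(out)
  if (opts@recordSource) {
    out@info[["SRC_CONTIG"]] <- orig@contig
    out@info[["SRC_POS"]] <- as.character(orig@pos)
    out@info[["SRC_REF_ALT"]] <-
      paste(c(orig@ref, orig@alt), collapse = ",")
  }
  became <- wasPrimitive && !.isPrimitive(out)
  if (became && opts@dropNonPrimitives)
    return(.dropped("became_non_primitive"))
  status <- if (novel) "REF_ADDED"
    else if (perm[1L] != 0L) "REF_SWAPPED"
    else "REF_UNCHANGED"
  new("LiftResult", status = status, record = out,
      reason = NA_character_, permutation = as.integer(perm),
      novelRef = novel, strandFlipped = flipped,
      becameNonPrimitive = became)
}
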