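#' Construct a VariantRecord
#'
#' @param contig contig name.
#' @param pos 1-based position.
#' @param ref reference allele.
#' @param alt character vector of alternate alleles.
#' @param id record identifier (default ".").
#' @param qual quality (default NA).
#' @param filter filter column (default ".").
#' @param info named list of INFO values: character token vectors, or TRUE
#'   for flags.
#' @param geno named list of FORMAT tag -> per-sample character vector.
#' @return \linkS4class{VariantRecord}.
#' @examples
#' variantRecord("chr1", 11, "CAC", "C")
#' @export
variantRecord <- function(contig, pos, ref, alt, id = ".", qual = NA_real_,
                          filter = ".", info = list(), geno = list()) {
  new("VariantRecord", contig = as.character(contig), pos = as.integer(pos),
      id = as.character(id), ref = toupper(ref), alt = toupper(alt),
      qual = as.numeric(qual), filter = as.character(filter),
      info = info, geno = geno)
}

#' @describeIn VariantRecord-class allele vector (reference first).
#' @param x a \linkS4class{VariantRecord}.
#' @export
alleles <- function(x) c(x@ref, x@alt)

#' @export
setMethod("show", "VariantRecord", function(object) {
  cat(sprintf("VariantRecord: %s:%d %s %s>%s\n", object@contig, object@pos,
              object@id, object@ref, paste(object@alt, collapse = ",")))
})

# shared helpers ------------------------------------------------------------

.checkRefMatches <- function(rec, genome) {
  obs <- fetchSeq(genome, rec@contig, rec@pos,
                  rec@pos + nchar(rec@ref) - 1L)
  if (obs != rec@ref)
    stop("REF allele '", rec@ref, "' does not match the genome ('", obs,
         "') at ", rec@contig, ":", rec@pos)
  invisible(TRUE)
}

.withAlleles <- function(rec, pos, ref, alt) {
  initialize(rec, pos = as.integer(pos), ref = ref, alt = alt)
}

#' Normalize a variant record (left-align and make parsimonious)
#'
#' A record is left-aligned when its position is the smallest among all
#' equal-length representations of the same variant, parsimonious when its
#' alleles are the shortest possible, and normalized when both hold.
#' Implemented by iteratively right-trimming shared terminal bases, left
#' extending with the preceding reference base whenever an allele would
#' become empty, and finally left-trimming shared leading bases while every
#' allele keeps length >= 1. Idempotent. When left extension is required at
#' the contig start, normalization stops there and the record is kept.
#'
#' Annotations, genotypes and the identifier are untouched; only
#' \code{pos}, \code{ref} and \code{alt} change.
#'
#' @param rec \linkS4class{VariantRecord}; \code{ref} must match the genome.
#' @param genome sequence accessor (see \code{\link{fetchSeq}}).
#' @return the normalized \linkS4class{VariantRecord}.
#' @examples
#' g <- Biostrings::DNAStringSet(c(ctg = "GGGCACACACAGGG"))
#' normalizeRecord(variantRecord("ctg", 5, "ACA", "A"), g)  # -> pos 3 GCA/G
#' @export
normalizeRecord <- function(rec, genome) {
  .checkRefMatches(rec, genome)
  al <- alleles(rec)
  if (any(.isSymbolicAllele(al))) return(rec)
  pos <- rec@pos
  repeat {
    lens <- nchar(al)
    last <- substr(al, lens, lens)
    if (length(unique(last)) != 1L) break
    if (any(lens == 1L)) {
      if (pos == 1L) break  # cannot left-extend past the contig start
      b <- fetchSeq(genome, rec@contig, pos - 1L, pos - 1L)
      al <- paste0(b, substr(al, 1L, lens - 1L))
      pos <- pos - 1L
    } else {
      al <- substr(al, 1L, lens - 1L)
    }
  }
  repeat {
    lens <- nchar(al)
    if (any(lens == 1L)) break
    first <- substr(al, 1L, 1L)
    if (length(unique(first)) != 1L) break
    al <- substr(al, 2L, lens)
    pos <- pos + 1L
  }
  .withAlleles(rec, pos, al[1L], al[-1L])
}

#' Maximally extend a variant record
#'
#' Computes the unique maximally extended representation: normalize, extend
#' one base left if the alleles do not all share their first base, one base
#' right if they do not all share their last base, then, for each pair of
#' alleles (including alt-alt pairs), extend right while the shorter allele
#' equals a prefix or a suffix of the longer. The result's shared left-most
#' and right-most bases are the 5' and 3' anchors. Every representation of
#' the same variant yields the identical extended record, and normalizing
#' the extended record recovers the normalized record.
#'
#' @inheritParams normalizeRecord
#' @return \linkS4class{ExtendedRecord}.
#' @examples
#' g <- Biostrings::DNAStringSet(c(ctg = "GGGCACACACAGGG"))
#' maximallyExtend(variantRecord("ctg", 3, "GCA", "G"), g)
#' @export
maximallyExtend <- function(rec, genome) {
  norm <- normalizeRecord(rec, genome)
  al <- alleles(norm)
  if (any(.isSymbolicAllele(al)))
    stop("symbolic alleles cannot be maximally extended")
  pos <- norm@pos
  clen <- contigLength(genome, norm@contig)
  endPos <- function() pos + nchar(al[1L]) - 1L
  extendLeft <- function() {
    if (pos == 1L)
      stop("unanchorable at contig edge: cannot extend left of position 1")
    b <- fetchSeq(genome, norm@contig, pos - 1L, pos - 1L)
    al <<- paste0(b, al)
    pos <<- pos - 1L
  }
  extendRight <- function() {
    e <- endPos()
    if (e + 1L > clen)
      stop("unanchorable at contig edge: cannot extend beyond contig end")
    b <- fetchSeq(genome, norm@contig, e + 1L, e + 1L)
    al <<- paste0(al, b)
  }
  if (length(unique(substr(al, 1L, 1L))) != 1L) extendLeft()
  if (length(unique(substr(al, nchar(al), nchar(al)))) != 1L) extendRight()
  repeat {
    again <- FALSE
    np <- length(al)
    for (i in seq_len(np - 1L)) {
      for (j in seq.int(i + 1L, np)) {
        while (.isPrefixOrSuffix(al[i], al[j])) {
          extendRight()
          again <- TRUE
        }
      }
    }
    if (!again) break
  }
  new("ExtendedRecord", contig = norm@contig, pos = as.integer(pos),
      alleles = al, anchor5 = as.integer(pos),
      anchor3 = as.integer(pos + nchar(al[1L]) - 1L))
}

#' @export
setMethod("show", "ExtendedRecord", function(object) {
  cat(sprintf("ExtendedRecord: %s:%d %s  anchors [%d, %d]\n", object@contig,
              object@pos, paste(object@alleles, collapse = "/"),
              object@anchor5, object@anchor3))
})

#' Classify a variant record
#'
#' Classifies each REF/ALT allele pair and the record overall. A pair is
#' classified after trimming its shared terminal then leading bases:
#' both remaining alleles of length 1 make an SNV, one side empty makes an
#' indel, equal lengths above 1 make an MNV, anything else is complex.
#' SNVs and indels are the allelic primitives. The overall class is SNV
#' when all pairs are SNVs, INDEL when all pairs are primitive but not all
#' SNVs, MNV when all pairs are MNVs, SYMBOLIC when any allele is symbolic,
#' and COMPLEX otherwise.
#'
#' @param rec \linkS4class{VariantRecord}.
#' @return list with \code{pairs} (character vector, one class per ALT) and
#'   \code{overall}.
#' @examples
#' classifyVariant(variantRecord("c", 5, "A", "G"))$overall       # SNV
#' classifyVariant(variantRecord("c", 5, "G", "GCA"))$overall     # INDEL
#' @export
classifyVariant <- function(rec) {
  al <- alleles(rec)
  if (any(.isSymbolicAllele(al)))
    return(list(pairs = rep("SYMBOLIC", length(rec@alt)),
                overall = "SYMBOLIC"))
  pairs <- vapply(rec@alt, function(a) .classifyPair(rec@ref, a),
                  character(1), USE.NAMES = FALSE)
  overall <- if (all(pairs == "SNV")) "SNV"
    else if (all(pairs %in% c("SNV", "INDEL"))) "INDEL"
    else if (all(pairs == "MNV")) "MNV"
    else "COMPLEX"
  list(pairs = pairs, overall = overall)
}

.classifyPair <- function(r, a) {
  # trim shared suffix then shared prefix (mirrors normalization order)
  while (nchar(r) > 0L && nchar(a) > 0L &&
         substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
    r <- substr(r, 1L, nchar(r) - 1L)
    a <- substr(a, 1L, nchar(a) - 1L)
  }
  while (nchar(r) > 0L && nchar(a) > 0L &&
         substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
    r <- substr(r, 2L, nchar(r))
    a <- substr(a, 2L, nchar(a))
  }
  nr <- nchar(r); na <- nchar(a)
  if (nr == 1L && na == 1L) "SNV"
  else if (nr == 0L || na == 0L) "INDEL"
  else if (nr == na) "MNV"
  else "COMPLEX"
}

.isPrimitive <- function(rec) {
  classifyVariant(rec)$overall %in% c("SNV", "INDEL")
}

#' Merge co-located bi-allelic records into one multi-allelic record
#'
#' Joins records sharing contig and position into a single multi-allelic
#' record, the representation used when converting multi-allelic indels.
#' Reference alleles are padded to the longest by right-extension with
#' reference bases, alternate alleles are concatenated in record order, and
#' genotypes are re-indexed. Number=A INFO fields are concatenated,
#' Number=R fields take the first record's reference value plus each
#' record's alternate values, and Number=G fields are set to missing (a
#' joint-genotype likelihood across records is not defined). When a
#' sample's non-reference alleles across the records exceed its ploidy the
#' merge is refused for that site and the input records are returned
#' unchanged.
#'
#' @param records list of \linkS4class{VariantRecord} on the same contig
#'   and position, each with identical sample sets.
#' @param header optional \linkS4class{VcfHeader} for Number declarations.
#' @return a single merged \linkS4class{VariantRecord}, or the input list
#'   unchanged when the merge is refused.
#' @export
mergeBiallelic <- function(records, header = NULL) {
  if (length(records) == 1L) return(records[[1L]])
  stopifnot(length(unique(vapply(records, function(r) r@contig,
                                 character(1)))) == 1L,
            length(unique(vapply(records, function(r) r@pos,
                                 integer(1)))) == 1L)
  refs <- vapply(records, function(r) r@ref, character(1))
  longRef <- refs[which.max(nchar(refs))]
  if (!all(vapply(refs, function(r)
        substr(longRef, 1L, nchar(r)) == r, logical(1))))
    stop("records at the same position have inconsistent reference alleles")
  padded <- lapply(records, function(r) {
    padLen <- nchar(longRef) - nchar(r@ref)
    if (padLen == 0L) return(r)
    pad <- substr(longRef, nchar(r@ref) + 1L, nchar(longRef))
    .withAlleles(r, r@pos, longRef, paste0(r@alt, pad))
  })
  altList <- lapply(padded, function(r) r@alt)
  newAlt <- unlist(altList, use.names = FALSE)
  if (anyDuplicated(c(longRef, newAlt)))
    stop("merged alleles are not pairwise distinct")
  # per-record offset of its alt indices in the merged record
  offs <- cumsum(c(0L, lengths(altList)[-length(altList)]))

  gtTags <- unique(unlist(lapply(records, function(r) names(r@geno))))
  nS <- if (length(gtTags)) length(records[[1L]]@geno[[1L]]) else 0L
  newGeno <- list()
  if ("GT" %in% gtTags) {
    gts <- character(nS)
    for (s in seq_len(nS)) {
      parsed <- lapply(seq_along(padded), function(k)
        .parseGT(padded[[k]]@geno[["GT"]][s]))
      ploidy <- max(vapply(parsed, function(p) length(p$idx), integer(1)))
      phased <- any(vapply(parsed, function(p) p$phased, logical(1)))
      slots <- rep(0L, ploidy)
      for (k in seq_along(parsed)) {
        nonref <- parsed[[k]]$idx[!is.na(parsed[[k]]$idx) &
                                  parsed[[k]]$idx > 0L]
        for (a in nonref) {
          free <- which(slots == 0L)
          if (length(free) == 0L) return(records)  # merge refused
          slots[free[1L]] <- offs[k] + a
        }
      }
      if (!phased) slots <- sort(slots)
      gts[s] <- paste(slots, collapse = if (phased) "|" else "/")
    }
    newGeno[["GT"]] <- gts
  }
  numberOf <- function(tag, where) .tagNumber(tag, header, where)
  for (tag in setdiff(gtTags, "GT")) {
    num <- numberOf(tag, "format")
    vals <- lapply(records, function(r)
      if (tag %in% names(r@geno)) r@geno[[tag]] else rep(".", nS))
    newGeno[[tag]] <- vapply(seq_len(nS), function(s) {
      toks <- lapply(vals, function(v) strsplit(v[s], ",", fixed = TRUE)[[1L]])
      if (identical(num, "A")) paste(unlist(toks), collapse = ",")
      else if (identical(num, "R")) paste(c(toks[[1L]][1L],
        unlist(lapply(toks, function(t) t[-1L]))), collapse = ",")
      else if (identical(num, "G")) "."
      else vals[[1L]][s]
    }, character(1))
  }

  infoTags <- unique(unlist(lapply(records, function(r) names(r@info))))
  newInfo <- list()
  for (tag in infoTags) {
    num <- numberOf(tag, "info")
    vals <- lapply(records, function(r) r@info[[tag]])
    first <- Filter(Negate(is.null), vals)[[1L]]
    if (isTRUE(first)) { newInfo[[tag]] <- TRUE; next }
    toks <- lapply(vals, function(v) if (is.null(v)) "." else v)
    if (identical(num, "A")) newInfo[[tag]] <- unlist(toks)
    else if (identical(num, "R")) newInfo[[tag]] <-
        c(toks[[1L]][1L], unlist(lapply(toks, function(t) t[-1L])))
    else if (identical(num, "G")) newInfo[[tag]] <- "."
    else newInfo[[tag]] <- first
  }
  qual <- suppressWarnings(max(vapply(records, function(r) r@qual,
                                      numeric(1)), na.rm = TRUE))
  if (!is.finite(qual)) qual <- NA_real_
  filt <- unique(unlist(lapply(records, function(r) r@filter)))
  filt <- paste(setdiff(filt, "."), collapse = ";")
  if (!nzchar(filt)) filt <- "."
  ids <- setdiff(unique(unlist(lapply(records, function(r) r@id))), ".")
  new("VariantRecord", contig = records[[1L]]@contig,
      pos = records[[1L]]@pos,
      id = if (length(ids)) paste(ids, collapse = ";") else ".",
      ref = longRef, alt = newAlt, qual = qual, filter = filt,
      info = newInfo, geno = newGeno)
}

#' Split a multi-allelic record into bi-allelic records
#'
#' The inverse view of \code{\link{mergeBiallelic}}: one record per
#' alternate allele, each normalized against the genome when one is given.
#' Number=A INFO values are distributed; other fields are copied.
#'
#' @param rec multi-allelic \linkS4class{VariantRecord}.
#' @param genome optional sequence accessor for normalization.
#' @param header optional \linkS4class{VcfHeader}.
#' @return list of bi-allelic \linkS4class{VariantRecord}.
#' @export
splitMultiallelic <- function(rec, genome = NULL, header = NULL) {
  lapply(seq_along(rec@alt), function(i) {
    info <- rec@info
    for (tag in names(info)) {
      if (identical(.tagNumber(tag, header, "info"), "A") &&
          length(info[[tag]]) == length(rec@alt))
        info[[tag]] <- info[[tag]][i]
    }
    out <- variantRecord(rec@contig, rec@pos, rec@ref, rec@alt[i],
                         id = rec@id, qual = rec@qual, filter = rec@filter,
                         info = info, geno = list())
    if (!is.null(genome)) normalizeRecord(out, genome) else out
  })
}

.parseGT <- function(gt) {
  phased <- grepl("|", gt, fixed = TRUE)
  parts <- strsplit(gt, "[/|]")[[1L]]
  idx <- suppressWarnings(as.integer(parts))
  list(idx = idx, phased = phased)
}
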