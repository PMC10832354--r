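#' Fetch a reference subsequence
#'
#' Random access to genome sequence, 1-based inclusive coordinates. Methods
#' exist for in-memory \code{DNAStringSet} genomes and for indexed FASTA
#' files opened as \code{Rsamtools::FaFile}.
#'
#' @param genome a \code{DNAStringSet} or \code{FaFile}.
#' @param contig contig name.
#' @param start,end 1-based inclusive coordinates.
#' @return Uppercase character scalar of bases.
#' @export
setGeneric("fetchSeq", function(genome, contig, start, end)
  standardGeneric("fetchSeq"))

#' @rdname fetchSeq
setMethod("fetchSeq", "DNAStringSet", function(genome, contig, start, end) {
  if (!contig %in% names(genome))
    stop("unknown contig '", contig, "'")
  if (start < 1L || end > length(genome[[contig]]) || start > end)
    stop("coordinates [", start, ",", end, "] outside contig '", contig, "'")
  toupper(as.character(Biostrings::subseq(genome[[contig]], start, end)))
})

#' @rdname fetchSeq
setMethod("fetchSeq", "FaFile", function(genome, contig, start, end) {
  gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(start, end))
  toupper(as.character(Rsamtools::scanFa(genome, gr)[[1L]]))
})

#' Contig length lookup
#'
#' @inheritParams fetchSeq
#' @return Integer length of the contig, or NA if absent.
#' @export
setGeneric("contigLength", function(genome, contig)
  standardGeneric("contigLength"))

#' @rdname contigLength
setMethod("contigLength", "DNAStringSet", function(genome, contig) {
  if (!contig %in% names(genome)) return(NA_integer_)
  length(genome[[contig]])
})

#' @rdname contigLength
setMethod("contigLength", "FaFile", function(genome, contig) {
  idx <- Rsamtools::scanFaIndex(genome)
  i <- match(contig, as.character(GenomicRanges::seqnames(idx)))
  if (is.na(i)) return(NA_integer_)
  GenomicRanges::width(idx)[i]
})

#' Contig names of a genome
#' @inheritParams fetchSeq
#' @return Character vector of contig names.
#' @export
setGeneric("contigNames", function(genome) standardGeneric("contigNames"))

#' @rdname contigNames
setMethod("contigNames", "DNAStringSet", function(genome) names(genome))

#' @rdname contigNames
setMethod("contigNames", "FaFile", function(genome) {
  as.character(GenomicRanges::seqnames(Rsamtools::scanFaIndex(genome)))
})
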