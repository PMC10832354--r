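#' @import methods
#' @importFrom S4Vectors mcols mcols<-
NULL

#' Chain: one pairwise-alignment chain between two assemblies
#'
#' Represents one stanza of a UCSC chain file: a gapped alignment between a
#' source ("target" in UCSC speak) contig and a destination ("query") contig.
#' Block coordinates are stored 0-based half-open exactly as in the file;
#' all public query operations of the package speak 1-based inclusive
#' coordinates (VCF convention) and convert internally.
#'
#' @slot score numeric chain score (parsed, preserved, never used for
#'   tie-breaking).
#' @slot tName,tSize,tStart,tEnd source contig name, length and aligned span.
#' @slot qName,qSize,qStrand,qStart,qEnd destination contig name, length,
#'   strand and aligned span. For \code{qStrand == "-"} the q offsets are on
#'   the reverse-complemented destination contig (UCSC convention).
#' @slot id integer chain id.
#' @slot blocks data.frame with columns \code{tStart}, \code{qStart} (0-based
#'   offsets) and \code{size} (block length in bp), strictly increasing and
#'   non-overlapping in both coordinates.
#' @export
setClass("Chain", representation(
  score = "numeric",
  tName = "character", tSize = "integer", tStart = "integer", tEnd = "integer",
  qName = "character", qSize = "integer", qStrand = "character",
  qStart = "integer", qEnd = "integer",
  id = "integer",
  blocks = "data.frame"
))

setValidity("Chain", function(object) {
  b <- object@blocks
  msg <- character()
  if (!all(c("tStart", "qStart", "size") %in% names(b)))
    return("blocks must have columns tStart, qStart, size")
  if (nrow(b) == 0L) return("chain must contain at least one block")
  if (any(b$size < 1L)) msg <- c(msg, "block sizes must be >= 1")
  if (nrow(b) > 1L) {
    tEnds <- b$tStart + b$size
    qEnds <- b$qStart + b$size
    if (any(diff(b$tStart) <= 0) || any(b$tStart[-1L] < tEnds[-nrow(b)]))
      msg <- c(msg, "blocks overlap or are unordered in t coordinates")
    if (any(diff(b$qStart) <= 0) || any(b$qStart[-1L] < qEnds[-nrow(b)]))
      msg <- c(msg, "blocks overlap or are unordered in q coordinates")
  }
  if (!object@qStrand %in% c("+", "-"))
    msg <- c(msg, "qStrand must be '+' or '-'")
  if (b$tStart[1L] != object@tStart ||
      b$tStart[nrow(b)] + b$size[nrow(b)] != object@tEnd)
    msg <- c(msg, "block t span does not reconstruct tStart/tEnd")
  if (b$qStart[1L] != object@qStart ||
      b$qStart[nrow(b)] + b$size[nrow(b)] != object@qEnd)
    msg <- c(msg, "block q span does not reconstruct qStart/qEnd")
  if (length(msg)) msg else TRUE
})

#' ChainIndex: per-base source-to-destination lookup over a set of chains
#'
#' Wraps the parsed chains in a \code{GRanges}-backed interval index keyed by
#' source coordinates. Source bases covered by more than one block are
#' answered as \code{"ambiguous"} rather than silently resolved.
#'
#' @slot chains list of \linkS4class{Chain}.
#' @slot blocks \code{GRanges} of block source intervals (1-based) with
#'   metadata columns \code{chain} (index into \code{chains}) and
#'   \code{block} (row in that chain's block table).
#' @slot lookup per-contig sorted interval tables (start, end, chain,
#'   block, running max end) for stabbing queries without per-call
#'   GRanges construction.
#' @export
setClass("ChainIndex", representation(
  chains = "list",
  blocks = "ANY",
  lookup = "list"
))

#' BaseMapping: the destination location of one source base
#'
#' @slot status one of \code{"mapped"}, \code{"unmapped"}, \code{"ambiguous"}.
#' @slot dstContig destination contig name (mapped only).
#' @slot dstPos 1-based destination position on the forward strand.
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot chainId id of the chain providing the mapping.
#' @export
setClass("BaseMapping", representation(
  status = "character",
  dstContig = "character",
  dstPos = "integer",
  strand = "character",
  chainId = "integer"
))

setValidity("BaseMapping", function(object) {
  if (!object@status %in% c("mapped", "unmapped", "ambiguous"))
    return("status must be mapped/unmapped/ambiguous")
  if (object@status == "mapped" && (is.na(object@dstPos) || object@dstPos < 1L))
    return("mapped BaseMapping requires dstPos >= 1")
  TRUE
})

#' VcfHeader: VCF header metadata
#'
#' @slot lines the raw \code{##} meta lines in file order.
#' @slot info data.frame of INFO declarations (ID, Number, Type, Description).
#' @slot format data.frame of FORMAT declarations.
#' @slot contigs data.frame of contig declarations (ID, length; length may
#'   be NA when the input header carries none).
#' @slot samples sample names from the \code{#CHROM} line.
#' @export
setClass("VcfHeader", representation(
  lines = "character",
  info = "data.frame",
  format = "data.frame",
  contigs = "data.frame",
  samples = "character"
))

#' VariantRecord: one VCF data line
#'
#' Positions are 1-based. INFO values are stored as named list entries whose
#' values are character token vectors (already split on comma) or
#' \code{TRUE} for flags. Genotype fields are stored per FORMAT tag as a
#' character vector with one raw string per sample.
#'
#' @slot contig,pos,id,ref,alt,qual,filter the fixed VCF columns; \code{alt}
#'   is the ordered vector of alternate alleles.
#' @slot info named list of INFO values.
#' @slot geno named list of FORMAT tag -> per-sample character vector.
#' @export
setClass("VariantRecord", representation(
  contig = "character", pos = "integer", id = "character",
  ref = "character", alt = "character",
  qual = "numeric", filter = "character",
  info = "list", geno = "list"
))

setValidity("VariantRecord", function(object) {
  msg <- character()
  if (!nzchar(object@ref)) msg <- c(msg, "ref allele must be non-empty")
  al <- c(object@ref, object@alt)
  if (anyDuplicated(al)) msg <- c(msg, "alleles must be pairwise distinct")
  seqlike <- !grepl("[][<>*.]", al)
  if (any(grepl("[^ACGTN]", al[seqlike])))
    msg <- c(msg, "sequence alleles must be uppercase over {A,C,G,T,N}")
  if (is.na(object@pos) || object@pos < 1L) msg <- c(msg, "pos must be >= 1")
  if (length(msg)) msg else TRUE
})

#' ExtendedRecord: the maximally extended representation of a variant
#'
#' The unique representation in which (i) no allele is a prefix or suffix of
#' another, (ii) all alleles share their first and their last base, and
#' (iii) no shorter representation satisfies both. The shared left-most base
#' is the 5' anchor, the shared right-most base the 3' anchor; these are the
#' only two positions that must be mapped across assemblies.
#'
#' @slot contig contig name.
#' @slot pos 1-based position of the 5' anchor (== \code{anchor5}).
#' @slot alleles ordered allele texts; index 1 is the reference.
#' @slot anchor5,anchor3 1-based anchor positions;
#'   \code{anchor3 == pos + nchar(alleles[1]) - 1}.
#' @export
setClass("ExtendedRecord", representation(
  contig = "character", pos = "integer", alleles = "character",
  anchor5 = "integer", anchor3 = "integer"
))

setValidity("ExtendedRecord", function(object) {
  al <- object@alleles
  msg <- character()
  if (length(al) < 2L) return("need at least two alleles")
  if (object@anchor5 != object@pos)
    msg <- c(msg, "anchor5 must equal pos")
  if (object@anchor3 != object@pos + nchar(al[1L]) - 1L)
    msg <- c(msg, "anchor3 must equal pos + nchar(ref) - 1")
  first <- substr(al, 1L, 1L)
  last <- substr(al, nchar(al), nchar(al))
  if (length(unique(first)) != 1L || length(unique(last)) != 1L)
    msg <- c(msg, "alleles must share first and last base")
  for (i in seq_along(al)) for (j in seq_along(al)) {
    if (i >= j) next
    if (.isPrefixOrSuffix(al[i], al[j]))
      msg <- c(msg, "no allele may be a prefix or suffix of another")
  }
  if (length(msg)) unique(msg) else TRUE
})

#' AlignmentParams: affine-gap scoring parameters
#'
#' @slot match score for a matching column (>= 0).
#' @slot mismatch penalty for a mismatching column (<= 0).
#' @slot gapOpen penalty charged for the first column of each gap (<= 0).
#' @slot gapExtend penalty for each further column of a gap (<= 0);
#'   \code{gapOpen <= gapExtend} so opening costs at least as much as
#'   extending.
#' @export
setClass("AlignmentParams", representation(
  match = "numeric", mismatch = "numeric",
  gapOpen = "numeric", gapExtend = "numeric"
))

setValidity("AlignmentParams", function(object) {
  msg <- character()
  if (object@match < 0) msg <- c(msg, "match score must be >= 0")
  if (object@mismatch > 0) msg <- c(msg, "mismatch penalty must be <= 0")
  if (!(object@gapOpen <= object@gapExtend && object@gapExtend <= 0))
    msg <- c(msg, "need gapOpen <= gapExtend <= 0")
  if (length(msg)) msg else TRUE
})

#' Alignment: a global pairwise alignment
#'
#' Columns are stored as two parallel integer vectors giving, per column,
#' the 1-based position in sequence A (or NA for a gap) and in sequence B.
#'
#' @slot score optimal global score under the parameters used.
#' @slot aPos,bPos per-column positions (NA marks a gap on that side).
#' @export
setClass("Alignment", representation(
  score = "numeric", aPos = "integer", bPos = "integer"
))

setValidity("Alignment", function(object) {
  if (length(object@aPos) != length(object@bPos))
    return("aPos and bPos must be parallel")
  if (any(is.na(object@aPos) & is.na(object@bPos)))
    return("a column cannot be gap on both sides")
  a <- object@aPos[!is.na(object@aPos)]
  b <- object@bPos[!is.na(object@bPos)]
  if (length(a) && !identical(a, seq_along(a)))
    return("A-side positions must spell 1..len(A)")
  if (length(b) && !identical(b, seq_along(b)))
    return("B-side positions must spell 1..len(B)")
  TRUE
})

#' LiftOptions: tunables of the lift engine
#'
#' @slot flank bp of extra sequence taken on each side of the extended
#'   region when realigning to recover an anchor (default 100).
#' @slot maxRegionLen cap in bp on the anchor span / destination fetch
#'   (default 10000); longer records are dropped with
#'   \code{region_too_long}.
#' @slot params \linkS4class{AlignmentParams} for anchor recovery.
#' @slot dropNonPrimitives drop records whose converted form is no longer an
#'   allelic primitive (SNV or indel).
#' @slot recordSource record original contig/pos/alleles in INFO tags
#'   \code{SRC_CONTIG}, \code{SRC_POS}, \code{SRC_REF_ALT}.
#' @export
setClass("LiftOptions", representation(
  flank = "integer", maxRegionLen = "integer",
  params = "AlignmentParams",
  dropNonPrimitives = "logical", recordSource = "logical"
))

setValidity("LiftOptions", function(object) {
  msg <- character()
  if (object@flank < 1L) msg <- c(msg, "flank must be >= 1")
  if (object@maxRegionLen < 1L) msg <- c(msg, "maxRegionLen must be >= 1")
  if (length(msg)) msg else TRUE
})

#' LiftResult: outcome of converting one record
#'
#' @slot status one of \code{REF_UNCHANGED}, \code{REF_SWAPPED},
#'   \code{REF_ADDED}, \code{DROPPED}.
#' @slot record the converted \linkS4class{VariantRecord}, or NULL when
#'   dropped.
#' @slot reason drop reason code (NA unless dropped).
#' @slot permutation integer vector mapping old allele index to new allele
#'   index (0-based values; element i corresponds to old allele i-1).
#' @slot novelRef TRUE when a novel reference allele was inserted.
#' @slot strandFlipped TRUE when the record crossed a '-' strand chain.
#' @slot becameNonPrimitive TRUE when a primitive input became
#'   non-primitive on conversion.
#' @export
setClass("LiftResult", representation(
  status = "character",
  record = "ANY",
  reason = "character",
  permutation = "integer",
  novelRef = "logical",
  strandFlipped = "logical",
  becameNonPrimitive = "logical"
))

.liftStatuses <- c("REF_UNCHANGED", "REF_SWAPPED", "REF_ADDED", "DROPPED")
.dropReasons <- c("unmapped_both_anchors", "anchors_discordant",
                  "ambiguous_mapping", "unanchorable_at_edge",
                  "realign_failed", "region_too_long",
                  "symbolic_unsupported", "became_non_primitive",
                  "unknown_contig")

setValidity("LiftResult", function(object) {
  msg <- character()
  if (!object@status %in% .liftStatuses)
    msg <- c(msg, "unknown status")
  if (object@status == "DROPPED") {
    if (!is.null(object@record)) msg <- c(msg, "dropped result carries no record")
    if (is.na(object@reason) || !object@reason %in% .dropReasons)
      msg <- c(msg, "dropped result requires a known reason")
  } else {
    if (is.null(object@record)) msg <- c(msg, "non-dropped result needs a record")
    if (object@novelRef &&
        length(object@permutation) + 1L !=
          length(c(object@record@ref, object@record@alt)))
      msg <- c(msg, "novel ref implies new allele count = old + 1")
  }
  if (length(msg)) msg else TRUE
})

#' AssemblyPair: a synthetic source/destination assembly pair
#'
#' Generated fixture holding two genomes differing by planted edits, the
#' exact chain describing their alignment, the inverse chain, a VCF of
#' planted variants on the source, and a truth table of expected lift
#' outcomes.
#'
#' @slot src,dst \code{DNAStringSet} genomes.
#' @slot chains,invChains lists of \linkS4class{Chain} (source->destination
#'   and destination->source).
#' @slot header \linkS4class{VcfHeader} for the planted VCF.
#' @slot records list of planted \linkS4class{VariantRecord}.
#' @slot truth data.frame keyed by variant with expected status, reason,
#'   strand flip and chain-gap intersection.
#' @slot mode chain dialect: \code{"gap"} (substitutions excluded from
#'   blocks, BLAT-style) or \code{"mismatch"} (substitutions inside blocks).
#' @export
setClass("AssemblyPair", representation(
  src = "ANY", dst = "ANY",
  chains = "list", invChains = "list",
  header = "VcfHeader", records = "list",
  truth = "data.frame", mode = "character"
))
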