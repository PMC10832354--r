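#' @useDynLib anchorlift, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Affine-gap alignment parameters
#'
#' Scoring used when recovering an anchor that failed chain mapping by
#' realignment. Defaults: match 1, mismatch -1, gap open -2 (charged for
#' the first column of each gap), gap extend -1. Anchor inference depends
#' on the optimum's location more than its scale, so standard values are
#' used; all four are exposed on the command line.
#'
#' @param match,mismatch,gapOpen,gapExtend see
#'   \linkS4class{AlignmentParams}.
#' @return \linkS4class{AlignmentParams}.
#' @export
alignmentParams <- function(match = 1, mismatch = -1, gapOpen = -2,
                            gapExtend = -1) {
  new("AlignmentParams", match = as.numeric(match),
      mismatch = as.numeric(mismatch), gapOpen = as.numeric(gapOpen),
      gapExtend = as.numeric(gapExtend))
}

#' Global pairwise alignment with affine gap costs
#'
#' Needleman-Wunsch over the three-state (match / gap-in-B / gap-in-A)
#' affine recursion with deterministic traceback: ties prefer a
#' match/mismatch column, then a gap in the destination sequence B, then a
#' gap in the source sequence A, evaluated from the terminal cell. The
#' leftward bias of this order is consistent with left-alignment applied
#' downstream.
#'
#' @param a,b non-empty nucleotide strings.
#' @param params \linkS4class{AlignmentParams}.
#' @param maxLen refuse alignment when either sequence exceeds this length
#'   (default 10000); the refusal is a condition of class
#'   \code{anchorlift_align_refused}.
#' @return \linkS4class{Alignment}.
#' @examples
#' alignGlobalAffine("ACGT", "AGT")
#' @export
alignGlobalAffine <- function(a, b, params = alignmentParams(),
                              maxLen = 10000L) {
  stopifnot(nzchar(a), nzchar(b))
  if (nchar(a) > maxLen || nchar(b) > maxLen)
    stop(structure(
      list(message = sprintf(
             "alignment refused: sequence length exceeds cap %d", maxLen),
           call = sys.call()),
      class = c("anchorlift_align_refused", "error", "condition")))
  res <- .affineNW(a, b, params@match, params@mismatch, params@gapOpen,
                   params@gapExtend)
  new("Alignment", score = res$score, aPos = res$aPos, bPos = res$bPos)
}

#' @export
setMethod("show", "Alignment", function(object) {
  cat(sprintf("Alignment: score %s over %d columns (%d A-gaps, %d B-gaps)\n",
              format(object@score), length(object@aPos),
              sum(is.na(object@aPos)), sum(is.na(object@bPos))))
})

#' Project a position through an alignment
#'
#' Returns the B coordinate aligned to position \code{aPos} of A. When that
#' position lies in a B-side gap, the nearest preceding aligned B
#' coordinate is returned with \code{inGap = TRUE} (0 when no aligned
#' column precedes).
#'
#' @param aln \linkS4class{Alignment}.
#' @param aPos 1-based position in sequence A.
#' @return list with \code{bPos} and \code{inGap}.
#' @export
projectPosition <- function(aln, aPos) {
  stopifnot(aPos >= 1L, aPos <= max(aln@aPos, na.rm = TRUE))
  col <- which(!is.na(aln@aPos) & aln@aPos == aPos)
  if (!is.na(aln@bPos[col]))
    return(list(bPos = aln@bPos[col], inGap = FALSE))
  prior <- aln@bPos[seq_len(col)]
  prior <- prior[!is.na(prior)]
  list(bPos = if (length(prior)) prior[length(prior)] else 0L, inGap = TRUE)
}

#' Infer the destination offset of an anchor that failed chain mapping
#'
#' Aligns the source window against the destination window (both extracted
#' by the lift engine so that the successfully mapped anchor sits at a
#' known corresponding offset) and projects the failed anchor's offset.
#' The result is flagged low-confidence when the projected column falls
#' inside a gap.
#'
#' @param srcWindow,dstWindow nucleotide strings.
#' @param srcAnchorOffset 1-based offset of the failed anchor within
#'   \code{srcWindow}.
#' @param params \linkS4class{AlignmentParams}.
#' @param maxLen passed to \code{\link{alignGlobalAffine}}.
#' @return list with \code{offset} (1-based offset in \code{dstWindow}) and
#'   \code{lowConfidence}.
#' @export
inferMissingAnchor <- function(srcWindow, dstWindow, srcAnchorOffset,
                               params = alignmentParams(),
                               maxLen = 10000L) {
  aln <- alignGlobalAffine(srcWindow, dstWindow, params, maxLen)
  proj <- projectPosition(aln, srcAnchorOffset)
  list(offset = proj$bPos, lowConfidence = proj$inGap)
}
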