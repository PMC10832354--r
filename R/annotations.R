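# Allele-indexed annotation updates applied when the allele order changes
# (reference/alternate swap or novel reference allele insertion).
#
# A permutation is an integer vector over old allele indices: element i
# holds the 0-based new index of old allele i-1 (the reference is allele
# 0). With a novel reference the new allele count is the old count + 1 and
# index 0 (the new reference) receives no old allele; its R/G slots are
# filled with the missing-value sentinel ".".

.swapPermutation <- function(nAlleles, altIdx) {
  # transposition exchanging old ref (0) with old allele altIdx (1-based
  # position among alleles incl. ref is altIdx + 1)
  p <- seq_len(nAlleles) - 1L
  p[1L] <- altIdx
  p[altIdx + 1L] <- 0L
  p
}

.novelRefPermutation <- function(nAlleles) {
  # old ref appended as the LAST alternate of the new record; old alts
  # keep their indices so existing Number=A positions are preserved
  c(nAlleles, seq_len(nAlleles - 1L))
}

.invertPermutation <- function(perm) {
  inv <- integer(length(perm))
  inv[perm + 1L] <- seq_along(perm) - 1L
  inv
}

.genoIndex <- function(j, k) {
  # VCF ordering of diploid genotype (j,k), j <= k, 0-based alleles
  (k * (k + 1L)) %/% 2L + j + 1L
}

#' Re-order a Number=R value vector under an allele permutation
#'
#' Fields with one value per allele (reference included) follow the allele
#' order; the value of old allele i moves to its new index. With a novel
#' reference allele the new reference slot is filled with the missing
#' sentinel \code{"."}.
#'
#' @param values character (or coercible) vector, one value per old allele.
#' @param perm permutation vector (see above).
#' @param novelRef TRUE when a novel reference allele was inserted.
#' @return re-ordered character vector, one value per new allele. A length
#'   mismatch returns the input untouched with a warning.
#' @examples
#' permuteR(c("12", "7"), c(1L, 0L))            # swap -> 7,12
#' @export
permuteR <- function(values, perm, novelRef = FALSE) {
  values <- as.character(values)
  if (length(values) != length(perm)) {
    warning("Number=R length mismatch; field left untouched")
    return(values)
  }
  nNew <- length(perm) + as.integer(novelRef)
  out <- rep(.missing1, nNew)
  out[perm + 1L] <- values
  out
}

#' Re-order a Number=G value vector under an allele permutation
#'
#' Fields with one value per genotype use the VCF genotype ordering
#' \code{idx(j,k) = k(k+1)/2 + j} for diploid calls (one value per allele
#' for haploid calls). The value of old genotype (j,k) moves to the index
#' of (perm(j), perm(k)). Genotypes involving a novel reference allele get
#' the missing sentinel.
#'
#' @inheritParams permuteR
#' @param ploidy 1 or 2 (default 2).
#' @return re-ordered character vector; length mismatches return the input
#'   untouched with a warning.
#' @examples
#' permuteG(c("0", "30", "45"), c(1L, 0L))      # biallelic PL swap
#' @export
permuteG <- function(values, perm, novelRef = FALSE, ploidy = 2L) {
  values <- as.character(values)
  nOld <- length(perm)
  nNew <- nOld + as.integer(novelRef)
  if (ploidy == 1L) {
    if (length(values) != nOld) {
      warning("Number=G length mismatch; field left untouched")
      return(values)
    }
    return(permuteR(values, perm, novelRef))
  }
  if (length(values) != (nOld * (nOld + 1L)) %/% 2L) {
    warning("Number=G length mismatch; field left untouched")
    return(values)
  }
  out <- rep(.missing1, (nNew * (nNew + 1L)) %/% 2L)
  for (k in seq_len(nOld) - 1L) {
    for (j in 0:k) {
      j2 <- perm[j + 1L]; k2 <- perm[k + 1L]
      if (j2 > k2) { tmp <- j2; j2 <- k2; k2 <- tmp }
      out[.genoIndex(j2, k2)] <- values[.genoIndex(j, k)]
    }
  }
  out
}

#' Update an allele-frequency-like Number=A field
#'
#' Re-ordered under the assumption that the values over all alleles,
#' including the implicit reference allele, sum to 1: the reference
#' frequency is computed as 1 - sum(values), the full per-allele vector is
#' permuted, and the new per-alternate vector is emitted. A novel
#' reference allele carries implicit frequency 0.
#'
#' @param values numeric (or character) vector, one frequency per old
#'   alternate allele.
#' @inheritParams permuteR
#' @param tol tolerance on sum(values) <= 1 (default 1e-6); fields summing
#'   beyond it are left untouched with a warning.
#' @return character vector of frequencies for the new alternate alleles.
#' @examples
#' updateAFLike("0.3", c(1L, 0L))   # biallelic swap -> 0.7
#' @export
updateAFLike <- function(values, perm, novelRef = FALSE, tol = 1e-6) {
  num <- suppressWarnings(as.numeric(values))
  if (anyNA(num) || length(num) != length(perm) - 1L) {
    warning("AF-like field not updatable; left untouched")
    return(as.character(values))
  }
  if (sum(num) > 1 + tol) {
    warning("AF-like values sum beyond 1; field left untouched")
    return(as.character(values))
  }
  full <- c(1 - sum(num), num)
  nNew <- length(perm) + as.integer(novelRef)
  newFull <- rep(NA_real_, nNew)
  newFull[perm + 1L] <- full
  if (novelRef) newFull[1L] <- 0
  .fmtNum(newFull[-1L])
}

#' Update an allele-count-like Number=A field
#'
#' Re-ordered under the assumption that the values over all alleles sum to
#' the total number of alleles in called genotypes (AN): the reference
#' count is AN - sum(values), the full vector is permuted, and the new
#' per-alternate vector is emitted. A novel reference allele carries
#' implicit count 0.
#'
#' @param values numeric (or character) vector, one count per old
#'   alternate allele.
#' @param an total allele number (INFO/AN); when missing the field is left
#'   untouched with a warning.
#' @inheritParams permuteR
#' @return character vector of counts for the new alternate alleles.
#' @examples
#' updateACLike("30", 100, c(1L, 0L))  # swap -> 70
#' @export
updateACLike <- function(values, an, perm, novelRef = FALSE) {
  num <- suppressWarnings(as.numeric(values))
  anv <- suppressWarnings(as.numeric(an[1L]))
  if (is.na(anv) || anyNA(num) || length(num) != length(perm) - 1L ||
      anv < sum(num)) {
    warning("AC-like field requires AN >= sum(AC); left untouched")
    return(as.character(values))
  }
  full <- c(anv - sum(num), num)
  nNew <- length(perm) + as.integer(novelRef)
  newFull <- rep(NA_real_, nNew)
  newFull[perm + 1L] <- full
  if (novelRef) newFull[1L] <- 0
  .fmtNum(newFull[-1L])
}

#' Update GWAS-VCF effect-size fields on a reference/alternate swap
#'
#' When the reference allele is swapped with an alternate allele, the sign
#' of the effect size (ES) and Z-score (EZ) value of the swapped pair is
#' reversed: the value lands in the slot of the new alternate (the old
#' reference) negated. Other per-alternate values, and the SE/LP fields,
#' are untouched. With a novel reference allele the appended old-reference
#' slot gets the missing sentinel (no effect versus an allele never
#' observed is defined).
#'
#' @inheritParams permuteR
#' @param values character/numeric vector, one value per old alternate.
#' @return character vector for the new alternate alleles.
#' @examples
#' updateESLike("0.5", c(1L, 0L))   # swap -> -0.5
#' @export
updateESLike <- function(values, perm, novelRef = FALSE) {
  num <- suppressWarnings(as.numeric(values))
  if (length(num) != length(perm) - 1L) {
    warning("ES/EZ field length mismatch; left untouched")
    return(as.character(values))
  }
  if (novelRef) return(c(as.character(values), .missing1))
  j <- perm[1L]  # new index of the old reference = slot of the swapped alt
  if (j == 0L) return(as.character(values))  # no swap
  out <- as.character(values)
  out[j] <- .fmtNum(-num[j])
  out
}

#' Recompute the INFO/END field
#'
#' Sets END to \code{pos + nchar(ref) - 1} on the destination assembly;
#' records without an END tag are returned unchanged.
#'
#' @param rec \linkS4class{VariantRecord}.
#' @return the updated record.
#' @export
updateEnd <- function(rec) {
  if (!"END" %in% names(rec@info)) return(rec)
  rec@info[["END"]] <- as.character(rec@pos + nchar(rec@ref) - 1L)
  rec
}

#' Recode genotype allele indices under an allele permutation
#'
#' Each allele index i becomes perm(i); missing alleles stay missing.
#' Unphased genotypes are re-sorted ascending (canonical VCF style);
#' phased genotypes keep their order. Out-of-range indices are set missing
#' with a warning.
#'
#' @param gt character vector of genotype strings (one per sample).
#' @inheritParams permuteR
#' @return recoded character vector.
#' @examples
#' recodeGenotypes(c("0/0", "0|1"), c(1L, 0L))  # -> "1/1", "1|0"
#' @export
recodeGenotypes <- function(gt, perm, novelRef = FALSE) {
  vapply(gt, function(g) {
    if (g == "." || !nzchar(g)) return(g)
    phased <- grepl("|", g, fixed = TRUE)
    sep <- if (phased) "|" else "/"
    parts <- strsplit(g, "[/|]")[[1L]]
    idx <- suppressWarnings(as.integer(parts))
    out <- vapply(seq_along(parts), function(k) {
      if (parts[k] == ".") return(".")
      if (is.na(idx[k]) || idx[k] >= length(perm)) {
        warning("genotype allele index out of range; set missing")
        return(".")
      }
      as.character(perm[idx[k] + 1L])
    }, character(1))
    if (!phased) {
      nums <- suppressWarnings(as.integer(out))
      out <- out[order(!is.na(nums), nums)]  # missing first, then ascending
    }
    paste(out, collapse = sep)
  }, character(1), USE.NAMES = FALSE)
}

# header-driven tag semantics ----------------------------------------------

.afLikeNames <- function() c("AF", "MAF")
.acLikeNames <- function() c("AC")

.tagNumber <- function(tag, header, where = c("info", "format")) {
  where <- match.arg(where)
  if (is.null(header)) return(NA_character_)
  d <- if (where == "info") header@info else header@format
  i <- match(tag, d$ID)
  if (is.na(i)) NA_character_ else d$Number[i]
}

# Resolve the semantic class of a tag: one of R, G, A, AF, AC, ES, EZ,
# END, plain. AF-like / AC-like / ES / EZ / END are recognized by name on
# top of the header Number declaration; unknown tags with Number=A/R/G are
# still permuted positionally.
.tagClass <- function(tag, header, where = c("info", "format")) {
  num <- .tagNumber(tag, header, where)
  if (tag == "END") return("END")
  if (tag == "ES") return("ES")
  if (tag == "EZ") return("EZ")
  if (identical(num, "R")) return("R")
  if (identical(num, "G")) return("G")
  if (identical(num, "A")) {
    if (tag %in% .afLikeNames() || grepl("_AF$", tag)) return("AF")
    if (tag %in% .acLikeNames() || grepl("_AC$", tag)) return("AC")
    return("A")
  }
  "plain"
}

# Positional re-ordering of an unknown Number=A vector: values follow
# their allele; an alternate promoted to reference loses its slot and the
# slot of the demoted reference (or of a novel reference's appended old
# reference) becomes missing unless an old alternate lands there.
.permuteAPlain <- function(values, perm, novelRef = FALSE) {
  values <- as.character(values)
  nOld <- length(perm)
  if (length(values) != nOld - 1L) {
    warning("Number=A length mismatch; field left untouched")
    return(values)
  }
  nNew <- nOld + as.integer(novelRef)
  out <- rep(.missing1, nNew - 1L)
  for (i in seq_len(nOld - 1L)) {       # old alt allele index i
    ni <- perm[i + 1L]
    if (ni >= 1L) out[ni] <- values[i]  # ni == 0 -> became ref, dropped
  }
  out
}

# Apply an allele permutation to every annotation of a record (INFO and
# FORMAT), given the header declarations. Returns the updated record.
.applyPermutationToAnnotations <- function(rec, perm, novelRef, header,
                                           ploidies = NULL) {
  if (length(perm) && all(perm == seq_along(perm) - 1L) && !novelRef)
    return(rec)
  if (is.null(ploidies) && "GT" %in% names(rec@geno))
    ploidies <- vapply(rec@geno[["GT"]], function(g)
      max(1L, length(strsplit(g, "[/|]")[[1L]])), integer(1),
      USE.NAMES = FALSE)
  an <- if ("AN" %in% names(rec@info)) rec@info[["AN"]] else NA_character_
  for (tag in names(rec@info)) {
    v <- rec@info[[tag]]
    if (isTRUE(v)) next
    cls <- .tagClass(tag, header, "info")
    rec@info[[tag]] <- switch(cls,
      R = permuteR(v, perm, novelRef),
      G = permuteG(v, perm, novelRef),
      AF = updateAFLike(v, perm, novelRef),
      AC = updateACLike(v, an, perm, novelRef),
      ES = ,
      EZ = updateESLike(.permuteESInput(v, perm), perm, novelRef),
      A = .permuteAPlain(v, perm, novelRef),
      v)
  }
  for (tag in names(rec@geno)) {
    vals <- rec@geno[[tag]]
    if (tag == "GT") {
      rec@geno[[tag]] <- recodeGenotypes(vals, perm, novelRef)
      next
    }
    cls <- .tagClass(tag, header, "format")
    if (cls == "plain" || cls == "END") next
    rec@geno[[tag]] <- vapply(seq_along(vals), function(s) {
      toks <- strsplit(vals[s], ",", fixed = TRUE)[[1L]]
      if (identical(toks, ".")) return(".")
      upd <- switch(cls,
        R = permuteR(toks, perm, novelRef),
        G = permuteG(toks, perm, novelRef,
                     ploidy = if (is.null(ploidies)) 2L else ploidies[s]),
        AF = updateAFLike(toks, perm, novelRef),
        AC = updateACLike(toks, an, perm, novelRef),
        ES = ,
        EZ = updateESLike(toks, perm, novelRef),
        A = .permuteAPlain(toks, perm, novelRef),
        toks)
      paste(upd, collapse = ",")
    }, character(1))
  }
  rec
}

# ES/EZ values stay in place (their alleles other than the swapped pair
# keep their slots); no positional pre-permutation is needed.
.permuteESInput <- function(v, perm) v
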