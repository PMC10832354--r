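swap2 <- c(1L, 0L)                       # bi-allelic ref<->alt
novel2 <- c(2L, 1L)                      # bi-allelic novel ref

test_that("Number=R values follow the allele permutation", {
  expect_identical(permuteR(c("12", "7"), swap2), c("7", "12"))
  # tri-allelic swap of ref with alt2 reverses the outer values
  expect_identical(permuteR(c("a", "b", "c"), c(2L, 1L, 0L)),
                   c("c", "b", "a"))
  # novel ref: new reference slot gets the missing sentinel
  expect_identical(permuteR(c("12", "7"), novel2, novelRef = TRUE),
                   c(".", "7", "12"))
  expect_warning(out <- permuteR(c("1", "2", "3"), swap2),
                 "length mismatch")
  expect_identical(out, c("1", "2", "3"))
})

test_that("Number=G values follow the genotype-index permutation", {
  expect_identical(permuteG(c("0", "30", "45"), swap2),
                   c("45", "30", "0"))
  expect_identical(permuteG(c("0", "30", "45"), c(0L, 1L)),
                   c("0", "30", "45"))
  # haploid G fields carry one value per allele
  expect_identical(permuteG(c("0", "30"), swap2, ploidy = 1L),
                   c("30", "0"))
  # novel ref introduces missing slots for genotypes with the new ref
  nv <- permuteG(c("0", "30", "45"), novel2, novelRef = TRUE)
  expect_identical(nv, c(".", ".", "45", ".", "30", "0"))
})

test_that("G permutation agrees with brute-force re-enumeration", {
  for (n in 2:4) {
    vals <- as.character(seq_len((n * (n + 1L)) %/% 2L))
    for (alt in seq_len(n - 1L)) {
      perm <- seq_len(n) - 1L
      perm[1L] <- alt; perm[alt + 1L] <- 0L
      expect_identical(permuteG(vals, perm), bruteGReorder(vals, perm),
                       info = paste(n, alt))
      nperm <- c(n, seq_len(n - 1L))
      expect_identical(permuteG(vals, nperm, novelRef = TRUE),
                       bruteGReorder(vals, nperm, novelRef = TRUE))
    }
  }
})

test_that("AF-like fields keep the unit-sum assumption", {
  expect_identical(updateAFLike("0.3", swap2), "0.7")
  # tri-allelic swap of ref with alt1: implicit ref 0.7 moves to slot 1
  expect_identical(updateAFLike(c("0.2", "0.1"), c(1L, 0L, 2L)),
                   c("0.7", "0.1"))
  # novel ref: old alleles keep their mass, old ref appended
  expect_identical(updateAFLike("0.3", novel2, novelRef = TRUE),
                   c("0.3", "0.7"))
  expect_warning(updateAFLike(c("0.9", "0.8"), c(1L, 0L, 2L)),
                 "sum beyond 1")
})

test_that("AC-like fields keep the AN-sum assumption", {
  expect_identical(updateACLike("30", 100, swap2), "70")
  expect_identical(updateACLike(c("20", "10"), 200, c(1L, 0L, 2L)),
                   c("170", "10"))
  expect_identical(updateACLike("30", 100, novel2, novelRef = TRUE),
                   c("30", "70"))
  expect_warning(updateACLike("30", NA, swap2), "AN")
})

test_that("GWAS effect-size signs flip only on a reference swap", {
  expect_identical(updateESLike("0.5", swap2), "-0.5")
  expect_identical(updateESLike("-2.1", swap2), "2.1")
  expect_identical(updateESLike("0.5", c(0L, 1L)), "0.5")   # no swap
  # multi-allelic: only the swapped pair's value is negated
  expect_identical(updateESLike(c("0.5", "0.2"), c(2L, 1L, 0L)),
                   c("0.5", "-0.2"))
  expect_identical(updateESLike("0.5", novel2, novelRef = TRUE),
                   c("0.5", "."))
})

test_that("INFO/END is recomputed from the final position and ref", {
  r <- variantRecord("c", 100, "GCA", "G", info = list(END = "999"))
  expect_identical(updateEnd(r)@info$END, "102")
  r2 <- variantRecord("c", 100, "GCA", "G")
  expect_false("END" %in% names(updateEnd(r2)@info))
})

test_that("genotypes are recoded, re-sorted when unphased only", {
  expect_identical(recodeGenotypes(c("0/0", "0|1", "./1", "."), swap2),
                   c("1/1", "1|0", "./0", "."))
  # novel ref: old ref index 0 -> appended index, re-sorted ascending
  expect_identical(recodeGenotypes("0/1", novel2, novelRef = TRUE), "1/2")
  expect_warning(out <- recodeGenotypes("0/5", swap2), "out of range")
  expect_identical(out, "./1")
})

test_that("double swap is an involution on all allele-indexed fields", {
  set.seed(13)
  for (n in 2:4) {
    nA <- n - 1L
    nG <- (n * (n + 1L)) %/% 2L
    rvals <- as.character(sample(0:99, n))
    gvals <- as.character(sample(0:99, nG))
    avals <- as.character(sample(0:99, nA))
    gt <- c("0/1", "0|1", sprintf("%d/%d", nA, nA))
    for (alt in seq_len(nA)) {
      perm <- seq_len(n) - 1L
      perm[1L] <- alt; perm[alt + 1L] <- 0L
      expect_identical(permuteR(permuteR(rvals, perm), perm), rvals)
      expect_identical(permuteG(permuteG(gvals, perm), perm), gvals)
      af <- as.character(round(runif(nA, 0, 1 / n), 4))
      expect_equal(as.numeric(updateAFLike(updateAFLike(af, perm), perm)),
                   as.numeric(af), tolerance = 1e-9)
      expect_identical(updateESLike(updateESLike(avals, perm), perm), avals)
      expect_identical(recodeGenotypes(recodeGenotypes(gt, perm), perm), gt)
    }
  }
})

test_that("AF and AC mass is conserved under any permutation", {
  set.seed(14)
  for (n in 2:4) {
    af <- round(runif(n - 1L, 0, 1 / n), 6)
    an <- 200L
    ac <- sample(0:50, n - 1L)
    for (alt in seq_len(n - 1L)) {
      perm <- seq_len(n) - 1L
      perm[1L] <- alt; perm[alt + 1L] <- 0L
      newAf <- as.numeric(updateAFLike(as.character(af), perm))
      # the per-allele frequency multiset (implicit ref included) is
      # preserved, so total mass stays exactly 1
      expect_equal(sort(c(1 - sum(af), af)),
                   sort(c(1 - sum(newAf), newAf)), tolerance = 1e-9)
      expect_equal(sum(newAf) + (1 - sum(newAf)), 1, tolerance = 1e-9)
      newAc <- as.numeric(updateACLike(as.character(ac), an, perm))
      # counts over all alleles still sum to AN
      expect_equal(sort(c(an - sum(ac), ac)),
                   sort(c(an - sum(newAc), newAc)))
    }
  }
})

test_that("header-driven tag classes drive whole-record updates", {
  h <- anchorlift:::.parseVcfHeader(
    c("##fileformat=VCFv4.3",
      '##INFO=<ID=AF,Number=A,Type=Float,Description="f">',
      '##INFO=<ID=AC,Number=A,Type=Integer,Description="c">',
      '##INFO=<ID=AN,Number=1,Type=Integer,Description="n">',
      '##INFO=<ID=XX,Number=A,Type=Float,Description="unknown A tag">',
      '##INFO=<ID=DP,Number=1,Type=Integer,Description="depth">',
      '##FORMAT=<ID=GT,Number=1,Type=String,Description="g">',
      '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="d">'),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1")
  rec <- variantRecord("c", 5, "A", "G",
    info = list(AF = "0.25", AC = "30", AN = "120", XX = "7.5", DP = "99"),
    geno = list(GT = "0/0", AD = "11,22"))
  out <- anchorlift:::.applyPermutationToAnnotations(rec, swap2, FALSE, h)
  expect_identical(out@info$AF, "0.75")
  expect_identical(out@info$AC, "90")
  expect_identical(out@info$AN, "120")       # plain tags untouched
  expect_identical(out@info$DP, "99")
  # unknown Number=A tags are positionally permuted: the promoted alt's
  # value is dropped and the demoted ref's slot has no value
  expect_identical(out@info$XX, ".")
  expect_identical(out@geno$GT, "1/1")
  expect_identical(out@geno$AD, "22,11")
})
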