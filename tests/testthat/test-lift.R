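noSrc <- liftOptions(recordSource = FALSE)

# two-contig helper: same sequence on both sides with chosen edits applied
# to the destination, aligned by a single mismatch-tolerant chain
mismatchPair <- function(G, edits = list()) {
  D <- G
  for (e in edits) substr(D, e[[1]], e[[1]] + nchar(e[[2]]) - 1L) <- e[[2]]
  list(src = tinyGenome(G), dst = tinyGenome(D),
       idx = buildChainIndex(list(identityChain(nchar(G)))))
}

test_that("the identity chain returns every record byte-identical", {
  pair <- generateAssemblyPair(seed = 41, contigLen = 5000L,
                               nVariants = 20L)
  g <- srcGenome(pair)
  idx <- buildChainIndex(list(identityChain(5000L, "chr1")))
  for (rec in plantedRecords(pair)) {
    res <- liftRecord(rec, idx, g, g, noSrc, pair@header)
    expect_identical(liftStatus(res), "REF_UNCHANGED")
    expect_false(res@strandFlipped)
    expect_identical(serRec(liftedRecord(res)),
                     serRec(normalizeRecord(rec, g)))
  }
})

test_that("SNV fast path reads the destination base to decide the outcome", {
  G <- paste(rep("ACGTGATTAG", 6), collapse = "")
  p <- mismatchPair(G, list(list(25, "C")))  # src base at 25 is G
  ref <- substr(G, 25, 25)

  unchanged <- liftRecord(variantRecord("ctg", 24, substr(G, 24, 24), "C"),
                          p$idx, p$src, p$dst, noSrc)
  expect_identical(liftStatus(unchanged), "REF_UNCHANGED")

  swap <- liftRecord(variantRecord("ctg", 25, ref, "C"),
                     p$idx, p$src, p$dst, noSrc)
  expect_identical(liftStatus(swap), "REF_SWAPPED")
  expect_identical(liftedRecord(swap)@ref, "C")
  expect_identical(liftedRecord(swap)@alt, ref)
  expect_identical(allelePermutation(swap), c(1L, 0L))

  added <- liftRecord(variantRecord("ctg", 25, ref, "T"),
                      p$idx, p$src, p$dst, noSrc)
  expect_identical(liftStatus(added), "REF_ADDED")
  expect_true(added@novelRef)
  expect_identical(liftedRecord(added)@ref, "C")
  # old ref appended as the last alternate
  expect_identical(liftedRecord(added)@alt, c("T", ref))
  expect_identical(allelePermutation(added), c(2L, 1L))
})

test_that("records inside chain gaps are recovered through the anchors", {
  # a 1-bp double-sided gap at the variant site (BLAT-style): the fast
  # path falls through and the anchor path swaps via the extended alleles
  pair <- generateAssemblyPair(seed = 42, mode = "gap")
  idx <- buildChainIndex(pairChains(pair))
  t <- truthTable(pair)
  snvGap <- which(t$kind == "sub_alt_snv")
  expect_true(length(snvGap) > 0)
  for (i in snvGap) {
    res <- liftRecord(plantedRecords(pair)[[i]], idx, srcGenome(pair),
                      dstGenome(pair), noSrc, pair@header)
    expect_identical(liftStatus(res), "REF_SWAPPED")
  }
  # engineered STR gaps over the 3' anchor exercise realignment recovery
  shifted <- which(t$kind %in% c("sub_alt_str", "str_resize"))
  for (i in shifted) {
    res <- liftRecord(plantedRecords(pair)[[i]], idx, srcGenome(pair),
                      dstGenome(pair), noSrc, pair@header)
    expect_identical(liftStatus(res), t$expectStatus[i])
  }
})

test_that("an STR locus with a third repeat length gains a novel ref", {
  # src run (CA)x5, alt drops one unit, dst run (CA)x7
  G <- paste0(strrep("GATTAC", 5), "G", strrep("CA", 5),
              "T", strrep("TAGGAC", 5))
  runStart <- 32L
  D <- paste0(substr(G, 1, runStart - 1L), strrep("CA", 7),
              substr(G, runStart + 10L, nchar(G)))
  chain <- sprintf(
    "chain 1000 ctg %d + 0 %d ctg %d + 0 %d 1\n%d 0 4\n%d\n\n",
    nchar(G), nchar(G), nchar(D), nchar(D),
    runStart + 10L - 1L, nchar(G) - (runStart + 10L - 1L))
  idx <- buildChainIndex(parseChainFile(chain))
  src <- tinyGenome(G); dst <- tinyGenome(D)
  rec <- variantRecord("ctg", runStart - 1L,
                       substr(G, runStart - 1L, runStart + 1L),
                       substr(G, runStart - 1L, runStart - 1L))
  res <- liftRecord(rec, idx, src, dst, noSrc)
  expect_identical(liftStatus(res), "REF_ADDED")
  out <- liftedRecord(res)
  # emitted ref matches the destination and the record stays multi-allelic
  expect_identical(fetchSeq(dst, "ctg", out@pos,
                            out@pos + nchar(out@ref) - 1L), out@ref)
  expect_identical(length(out@alt), 2L)
  expect_false(res@becameNonPrimitive)
})

test_that("anchors on different chains or spans over the cap drop records", {
  G <- strrep("ACGTGATTAG", 6)
  half <- paste0(
    sprintf("chain 10 ctg 60 + 0 28 ctg 60 + 0 28 1\n28\n\n"),
    sprintf("chain 10 ctg 60 + 32 60 ctg 60 + 32 60 2\n28\n\n"))
  idx <- buildChainIndex(parseChainFile(half))
  src <- tinyGenome(G)
  # an MNV whose extension anchors at 25 (chain 1) and 37 (chain 2)
  ref <- substr(G, 26, 36)
  rec <- variantRecord("ctg", 26, ref, chartr("ACGT", "TGCA", ref))
  res <- liftRecord(rec, idx, src, src, noSrc)
  expect_identical(liftStatus(res), "DROPPED")
  expect_identical(liftReason(res), "anchors_discordant")

  idFull <- buildChainIndex(list(identityChain(60L)))
  capped <- liftOptions(maxRegionLen = 3L, recordSource = FALSE)
  res2 <- liftRecord(variantRecord("ctg", 12, substr(G, 12, 17),
                                   substr(G, 12, 12)),
                     idFull, src, src, capped)
  expect_identical(liftReason(res2), "region_too_long")
})

test_that("symbolic, edge and unknown-contig records drop with reasons", {
  G <- strrep("ACGTGATTAG", 3)
  src <- tinyGenome(G)
  idx <- buildChainIndex(list(identityChain(30L)))
  sym <- liftRecord(variantRecord("ctg", 5, "G", "<DEL>"), idx, src, src,
                    noSrc)
  expect_identical(liftReason(sym), "symbolic_unsupported")

  other <- liftRecord(variantRecord("nope", 5, "G", "A"), idx, src, src,
                      noSrc)
  expect_identical(liftReason(other), "unknown_contig")

  edge <- liftRecord(variantRecord("ctg", 1, "CAC", "C"),
                     buildChainIndex(list(identityChain(6L))),
                     tinyGenome("CACACA"), tinyGenome("CACACA"), noSrc)
  expect_identical(liftReason(edge), "unanchorable_at_edge")
})

test_that("ambiguous coverage drops records with reason ambiguous_mapping", {
  one <- "chain 100 ctg 30 + 0 30 ctg 30 + 0 30 1\n30\n\n"
  idx <- buildChainIndex(parseChainFile(paste0(one, one)))
  src <- tinyGenome(strrep("ACGTGATTAG", 3))
  res <- liftRecord(variantRecord("ctg", 5, "G", "A"), idx, src, src, noSrc)
  expect_identical(liftReason(res), "ambiguous_mapping")
})

test_that("a conversion that breaks primitiveness is flagged or dropped", {
  # SNV inside a chain gap whose destination span is two bases: the novel
  # ref makes a pair that is neither SNV nor indel
  G <- strrep("ACGTGATTAG", 6)
  D <- paste0(substr(G, 1, 24), "TT", substr(G, 26, 60))
  chain <- sprintf(
    "chain 100 ctg 60 + 0 60 ctg %d + 0 %d 1\n24 1 2\n35\n\n",
    nchar(D), nchar(D))
  idx <- buildChainIndex(parseChainFile(chain))
  src <- tinyGenome(G); dst <- tinyGenome(D)
  rec <- variantRecord("ctg", 25, substr(G, 25, 25), "C")
  res <- liftRecord(rec, idx, src, dst, noSrc)
  expect_identical(liftStatus(res), "REF_ADDED")
  expect_true(res@becameNonPrimitive)

  dropOpts <- liftOptions(recordSource = FALSE, dropNonPrimitives = TRUE)
  res2 <- liftRecord(rec, idx, src, dst, dropOpts)
  expect_identical(liftStatus(res2), "DROPPED")
  expect_identical(liftReason(res2), "became_non_primitive")
})

test_that("inverted segments reverse-complement alleles and positions", {
  pair <- generateAssemblyPair(seed = 43)
  idx <- buildChainIndex(pairChains(pair))
  t <- truthTable(pair)
  for (i in which(t$kind %in% c("invert", "invert_swap"))) {
    rec <- plantedRecords(pair)[[i]]
    res <- liftRecord(rec, idx, srcGenome(pair), dstGenome(pair), noSrc,
                      pair@header)
    expect_true(res@strandFlipped)
    expect_identical(liftStatus(res), t$expectStatus[i])
    out <- liftedRecord(res)
    expect_identical(fetchSeq(dstGenome(pair), "chr1", out@pos,
                              out@pos + nchar(out@ref) - 1L), out@ref)
    # for the unchanged case the lifted alleles are the complements
    if (t$kind[i] == "invert")
      expect_identical(sort(alleles(out)),
                       sort(anchorlift:::.revComp(alleles(rec))))
  }
})

test_that("the full truth table is recovered in both chain dialects", {
  for (mode in c("gap", "mismatch")) {
    pair <- generateAssemblyPair(seed = 44, contigLen = 20000L,
                                 nVariants = 80L, mode = mode)
    idx <- buildChainIndex(pairChains(pair))
    res <- liftRecords(plantedRecords(pair), idx, srcGenome(pair),
                       dstGenome(pair), noSrc, pair@header)
    tc <- truthCheck(res, pair)
    expect_identical(tc$nonGap, 1)
    expect_gte(tc$overall, 0.99)
    expect_identical(tc$refValid, 1)
    expect_identical(sum(tc$confusion), 80L)
  }
})
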