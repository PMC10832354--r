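test_that("normalization left-aligns and trims, matching brute force", {
  g <- tinyGenome("GGGCACACACAGGG")
  # shifting an STR deletion to the left-most anchored representation
  r <- normalizeRecord(variantRecord("ctg", 5, "ACA", "A"), g)
  expect_identical(c(r@pos, r@ref, r@alt), c("3", "GCA", "G"))
  r2 <- normalizeRecord(variantRecord("ctg", 6, "CAC", "C"), g)
  expect_identical(serRec(r2), serRec(r))
  # already-normalized SNV is untouched
  snv <- variantRecord("ctg", 7, "A", "T")
  expect_identical(serRec(normalizeRecord(snv, g)), serRec(snv))

  # brute-force oracle on random small contigs and random indel records
  set.seed(101)
  for (k in 1:40) {
    G <- paste(sample(c("A", "C"), 30, replace = TRUE), collapse = "")
    gen <- tinyGenome(G)
    pos <- sample(5:20, 1)
    rl <- sample(1:4, 1)
    ref <- substr(G, pos, pos + rl - 1)
    alt <- paste(sample(c("A", "C"), sample(1:4, 1), replace = TRUE),
                 collapse = "")
    if (alt == ref) next
    rec <- variantRecord("ctg", pos, ref, alt)
    norm <- normalizeRecord(rec, gen)
    truth <- bruteNormalize(rec, gen)
    expect_identical(norm@pos, truth$pos)
    expect_identical(norm@ref, truth$ref)
    expect_identical(norm@alt, truth$alt)
    # idempotence
    expect_identical(serRec(normalizeRecord(norm, gen)), serRec(norm))
  }
})

test_that("normalization stops at the contig start instead of failing", {
  g <- tinyGenome("AATG")
  r <- normalizeRecord(variantRecord("ctg", 1, "AA", "A"), g)
  expect_identical(r@pos, 1L)
  expect_true(nchar(r@ref) >= 1L && nchar(r@alt) >= 1L)
})

test_that("normalization agrees with bcftools norm", {
  dir <- tempfile("norm")
  dir.create(dir)
  G <- "GGATTTTTTCAGCACACACACAGTCGGA"
  gen <- tinyGenome(G, "ctg")
  Biostrings::writeXStringSet(gen, file.path(dir, "g.fa"))
  Rsamtools::indexFa(file.path(dir, "g.fa"))
  recs <- list(variantRecord("ctg", 8, "TTC", "T"),
               variantRecord("ctg", 14, "ACA", "A"),
               variantRecord("ctg", 16, "A", "ACA"),
               variantRecord("ctg", 12, "GCA", "G"))
  hdr <- anchorlift:::.parseVcfHeader(
    c("##fileformat=VCFv4.3",
      sprintf("##contig=<ID=ctg,length=%d>", nchar(G))),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeVcfFile(hdr, recs, file.path(dir, "in.vcf"))
  out <- system2("bcftools",
                 c("norm", "-f", file.path(dir, "g.fa"),
                   file.path(dir, "in.vcf")),
                 stdout = TRUE, stderr = FALSE)
  body <- out[!startsWith(out, "#")]
  got <- lapply(recs, function(r) normalizeRecord(r, gen))
  for (i in seq_along(recs)) {
    f <- strsplit(body[i], "\t")[[1]]
    expect_identical(got[[i]]@pos, as.integer(f[2]))
    expect_identical(got[[i]]@ref, f[4])
    expect_identical(paste(got[[i]]@alt, collapse = ","), f[5])
  }
})

test_that("maximal extension reproduces the STR and SNV anchor examples", {
  g <- tinyGenome("GGGCACACACAGGG")
  e <- maximallyExtend(variantRecord("ctg", 3, "GCA", "G"), g)
  expect_identical(e@alleles, c("GCACACACAG", "GCACACAG"))
  expect_identical(c(e@anchor5, e@anchor3), c(3L, 12L))

  # an SNV in context TAGT extends one base each way
  g2 <- tinyGenome("ATAGTC")
  e2 <- maximallyExtend(variantRecord("ctg", 4, "G", "C"), g2)
  expect_identical(e2@alleles, c("AGT", "ACT"))
  expect_identical(c(e2@anchor5, e2@anchor3), c(3L, 5L))

  # minimality: every shorter sub-representation violates a condition
  al <- e@alleles
  for (cutL in 0:1) for (cutR in 0:1) {
    if (cutL == 0 && cutR == 0) next
    sub <- substr(al, 1 + cutL, nchar(al) - cutR)
    first <- substr(sub, 1, 1); last <- substr(sub, nchar(sub), nchar(sub))
    shareEnds <- length(unique(first)) == 1 && length(unique(last)) == 1
    noFix <- !anchorlift:::.isPrefixOrSuffix(sub[1], sub[2])
    expect_false(shareEnds && noFix)
  }
})

test_that("every equivalent representation extends to the same record", {
  pair <- generateAssemblyPair(seed = 5, contigLen = 10000L,
                               nVariants = 40L)
  g <- srcGenome(pair)
  set.seed(99)
  for (rec in plantedRecords(pair)) {
    ext0 <- maximallyExtend(rec, g)
    norm0 <- normalizeRecord(rec, g)
    for (eq in equivalentRepresentations(rec, g, n = 4L)) {
      ext <- maximallyExtend(eq, g)
      expect_identical(ext@alleles, ext0@alleles)
      expect_identical(ext@pos, ext0@pos)
      # normalize(extend(x)) == normalize(x)
      extRec <- variantRecord(rec@contig, ext@pos, ext@alleles[1],
                              ext@alleles[-1])
      nx <- normalizeRecord(extRec, g)
      expect_identical(c(nx@pos, nx@ref, nx@alt),
                       c(norm0@pos, norm0@ref, norm0@alt))
    }
  }
})

test_that("extension never changes the edited sequence", {
  pair <- generateAssemblyPair(seed = 6, contigLen = 5000L,
                               nVariants = 20L)
  g <- srcGenome(pair)
  G <- fetchSeq(g, "chr1", 1, 5000)
  for (rec in plantedRecords(pair)) {
    if (length(rec@alt) != 1) next
    norm <- normalizeRecord(rec, g)
    ext <- maximallyExtend(rec, g)
    e1 <- applyEdit(G, norm@pos, norm@ref, norm@alt[1])
    e2 <- applyEdit(G, ext@pos, ext@alleles[1], ext@alleles[2])
    expect_identical(e1, e2)
  }
})

test_that("extension fails cleanly at contig edges", {
  g <- tinyGenome("CACACA")
  expect_error(maximallyExtend(variantRecord("ctg", 1, "CAC", "C"), g),
               "unanchorable")
})

test_that("classification separates primitives from complex records", {
  expect_identical(classifyVariant(variantRecord("c", 5, "A", "G"))$overall,
                   "SNV")
  expect_identical(classifyVariant(variantRecord("c", 5, "G", "GCA"))$overall,
                   "INDEL")
  expect_identical(classifyVariant(variantRecord("c", 5, "AT", "GC"))$overall,
                   "MNV")
  # one complex REF/ALT pair makes the whole record complex
  cl <- classifyVariant(variantRecord("c", 5, "AC", c("AT", "G")))
  expect_identical(cl$pairs, c("SNV", "COMPLEX"))
  expect_identical(cl$overall, "COMPLEX")
  # a mixed SNV/indel multi-allelic is still primitive overall
  cl2 <- classifyVariant(variantRecord("c", 5, "TTC", c("T", "TTCTC")))
  expect_true(all(cl2$pairs == "INDEL"))
  expect_identical(cl2$overall, "INDEL")
  expect_identical(
    classifyVariant(variantRecord("c", 5, "A", "<DEL>"))$overall,
    "SYMBOLIC")
})

test_that("bi-allelic records merge with reference padding and re-split", {
  h <- anchorlift:::.parseVcfHeader(
    c("##fileformat=VCFv4.3",
      '##INFO=<ID=AF,Number=A,Type=Float,Description="f">'),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1")
  r1 <- variantRecord("c", 10, "A", "AT", info = list(AF = "0.2"),
                      geno = list(GT = "0/1"))
  r2 <- variantRecord("c", 10, "A", "AG", info = list(AF = "0.3"),
                      geno = list(GT = "0/0"))
  m <- mergeBiallelic(list(r1, r2), h)
  expect_identical(m@ref, "A")
  expect_identical(m@alt, c("AT", "AG"))
  expect_identical(m@info$AF, c("0.2", "0.3"))
  expect_identical(m@geno$GT, "0/1")

  # refs padded to the longest by right-extension with reference bases
  r3 <- variantRecord("c", 10, "AT", "A", geno = list(GT = "0/1"))
  r4 <- variantRecord("c", 10, "A", "AG", geno = list(GT = "0/1"))
  m2 <- mergeBiallelic(list(r3, r4))
  expect_identical(m2@ref, "AT")
  expect_identical(m2@alt, c("A", "AGT"))
  expect_identical(m2@geno$GT, "1/2")

  # merge then split recovers the originals up to normalization
  g <- tinyGenome("GGGGGGGGGATCGGGGGGGG", "c")
  back <- splitMultiallelic(m2, g)
  n3 <- normalizeRecord(r3, g); n4 <- normalizeRecord(r4, g)
  expect_identical(back[[1]]@pos, n3@pos)
  expect_identical(back[[1]]@ref, n3@ref)
  expect_identical(back[[1]]@alt, n3@alt)
  expect_identical(back[[2]]@ref, n4@ref)
  expect_identical(back[[2]]@alt, n4@alt)

  # conflicting genotypes refuse the merge (records passed through)
  r5 <- variantRecord("c", 10, "A", "AT", geno = list(GT = "1/1"))
  r6 <- variantRecord("c", 10, "A", "AG", geno = list(GT = "0/1"))
  out <- mergeBiallelic(list(r5, r6))
  expect_true(is.list(out) && length(out) == 2L)
})
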