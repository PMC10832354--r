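#' Read a VCF file into a header and a list of records
#'
#' Light streaming reader for VCF 4.x text, plain or gzip-compressed
#' (detected by magic bytes), or an open connection (e.g.
#' \code{file("stdin")}). Records are returned in file order. A header
#' without contig lines is accepted; contigs are then known only from the
#' records. Unknown INFO/FORMAT tags are carried opaquely.
#'
#' @param file path, \code{"-"} for standard input, or a connection.
#' @return list with \code{header} (\linkS4class{VcfHeader}) and
#'   \code{records} (list of \linkS4class{VariantRecord}).
#' @export
readVcfFile <- function(file) {
  if (inherits(file, "connection")) {
    lines <- readLines(file)
  } else if (identical(file, "-")) {
    lines <- readLines(file("stdin"))
  } else {
    if (!file.exists(file)) stop("no such VCF file: ", file)
    con <- file(file, "rb")
    magic <- readBin(con, "raw", n = 2L)
    close(con)
    con <- if (length(magic) == 2L && identical(as.integer(magic), c(31L, 139L)))
      gzfile(file, "rt") else file(file, "rt")
    on.exit(close(con))
    lines <- readLines(con)
  }
  isMeta <- startsWith(lines, "##")
  chromLine <- which(startsWith(lines, "#CHROM"))
  if (length(chromLine) != 1L)
    stop("VCF lacks a single #CHROM header line")
  header <- .parseVcfHeader(lines[isMeta], lines[chromLine])
  body <- lines[!isMeta & !startsWith(lines, "#") & nzchar(lines)]
  records <- vector("list", length(body))
  for (i in seq_along(body)) {
    records[[i]] <- tryCatch(.parseVcfLine(body[i], header),
      error = function(e) stop("VCF data line ", i, ": ",
                               conditionMessage(e), call. = FALSE))
  }
  list(header = header, records = records)
}

.parseStructuredMeta <- function(lines, what) {
  pat <- paste0("^##", what, "=<")
  sel <- grep(pat, lines, value = TRUE)
  if (!length(sel))
    return(data.frame(ID = character(), Number = character(),
                      Type = character(), Description = character(),
                      stringsAsFactors = FALSE))
  pull <- function(line, key) {
    m <- regmatches(line, regexec(paste0(key, "=([^,>\"]+|\"[^\"]*\")"),
                                  line))[[1L]]
    if (length(m) < 2L) NA_character_ else gsub("^\"|\"$", "", m[2L])
  }
  data.frame(ID = vapply(sel, pull, character(1), key = "ID"),
             Number = vapply(sel, pull, character(1), key = "Number"),
             Type = vapply(sel, pull, character(1), key = "Type"),
             Description = vapply(sel, pull, character(1),
                                  key = "Description"),
             row.names = NULL, stringsAsFactors = FALSE)
}

.parseVcfHeader <- function(metaLines, chromLine) {
  cols <- strsplit(chromLine, "\t", fixed = TRUE)[[1L]]
  samples <- if (length(cols) > 9L) cols[-(1:9)] else character()
  contigs <- .parseStructuredMeta(metaLines, "contig")
  lengths <- vapply(grep("^##contig=<", metaLines, value = TRUE),
    function(l) {
      m <- regmatches(l, regexec("length=([0-9]+)", l))[[1L]]
      if (length(m) < 2L) NA_integer_ else as.integer(m[2L])
    }, integer(1))
  contigDf <- data.frame(ID = contigs$ID,
                         length = if (nrow(contigs)) unname(lengths)
                                  else integer(),
                         stringsAsFactors = FALSE)
  new("VcfHeader", lines = metaLines,
      info = .parseStructuredMeta(metaLines, "INFO"),
      format = .parseStructuredMeta(metaLines, "FORMAT"),
      contigs = contigDf, samples = samples)
}

.parseVcfLine <- function(line, header) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (length(f) < 8L)
    stop("fewer than 8 tab-separated fields")
  pos <- suppressWarnings(as.integer(f[2L]))
  if (is.na(pos)) stop("non-numeric POS '", f[2L], "'")
  info <- list()
  if (f[8L] != ".") {
    for (kv in strsplit(f[8L], ";", fixed = TRUE)[[1L]]) {
      eq <- regexpr("=", kv, fixed = TRUE)
      if (eq == -1L) info[[kv]] <- TRUE
      else info[[substr(kv, 1L, eq - 1L)]] <-
        strsplit(substr(kv, eq + 1L, nchar(kv)), ",", fixed = TRUE)[[1L]]
    }
  }
  geno <- list()
  if (length(f) >= 10L) {
    keys <- strsplit(f[9L], ":", fixed = TRUE)[[1L]]
    cells <- strsplit(f[-(1:9)], ":", fixed = TRUE)
    for (k in seq_along(keys)) {
      geno[[keys[k]]] <- vapply(cells, function(cc)
        if (k <= length(cc)) cc[k] else ".", character(1))
    }
  }
  variantRecord(contig = f[1L], pos = pos, ref = f[4L],
                alt = strsplit(f[5L], ",", fixed = TRUE)[[1L]],
                id = f[3L],
                qual = if (f[6L] == ".") NA_real_
                       else suppressWarnings(as.numeric(f[6L])),
                filter = f[7L], info = info, geno = geno)
}

.formatInfo <- function(info) {
  if (!length(info)) return(".")
  paste(vapply(names(info), function(k) {
    v <- info[[k]]
    if (isTRUE(v)) k else paste0(k, "=", paste(v, collapse = ","))
  }, character(1)), collapse = ";")
}

.formatRecord <- function(rec) {
  fields <- c(rec@contig, rec@pos, rec@id, rec@ref,
              paste(rec@alt, collapse = ","),
              if (is.na(rec@qual)) "." else .fmtNum(rec@qual),
              rec@filter, .formatInfo(rec@info))
  if (length(rec@geno)) {
    keys <- names(rec@geno)
    nS <- length(rec@geno[[1L]])
    cells <- vapply(seq_len(nS), function(s)
      paste(vapply(keys, function(k) rec@geno[[k]][s], character(1)),
            collapse = ":"), character(1))
    fields <- c(fields, paste(keys, collapse = ":"), cells)
  }
  paste(fields, collapse = "\t")
}

#' Write a VCF file
#'
#' Emits the header meta lines, the \code{#CHROM} line and the records in
#' the given order (records are never sorted; run an external sorter when
#' coordinate order is required downstream). Gzip-compressed when the path
#' ends in \code{.gz}.
#'
#' @param header \linkS4class{VcfHeader}.
#' @param records list of \linkS4class{VariantRecord}.
#' @param file output path or connection.
#' @return invisibly, the path or connection.
#' @export
writeVcfFile <- function(header, records, file) {
  con <- if (inherits(file, "connection")) file
    else if (grepl("\\.gz$", file)) gzfile(file, "wt")
    else file(file, "wt")
  if (!inherits(file, "connection")) on.exit(close(con))
  chrom <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO",
                   if (length(header@samples)) c("FORMAT", header@samples)),
                 collapse = "\t")
  writeLines(c(header@lines, chrom), con)
  for (r in records) writeLines(.formatRecord(r), con)
  invisible(file)
}

#' Reconcile a contig name against a set of known names
#'
#' Tries an exact match, then toggling the \code{"chr"} prefix, then the
#' \code{"MT"} / \code{"chrM"} special case.
#'
#' @param name contig name as seen in the input.
#' @param known character vector of names known to the chain or FASTA.
#' @return the resolved known name, or \code{NA_character_}.
#' @examples
#' reconcileContigNames("22", c("chr22", "chrX"))   # "chr22"
#' @export
reconcileContigNames <- function(name, known) {
  if (name %in% known) return(name)
  alt <- if (startsWith(name, "chr")) sub("^chr", "", name)
         else paste0("chr", name)
  if (alt %in% known) return(alt)
  special <- c(MT = "chrM", chrM = "MT", M = "chrM")
  if (name %in% names(special) && special[[name]] %in% known)
    return(special[[name]])
  NA_character_
}

# header rewrite for the destination assembly: contig lines from the
# destination genome; declarations for source-position and reject tags
.rewriteHeader <- function(header, dstGenome, opts, reject = FALSE) {
  keep <- header@lines[!grepl("^##contig=", header@lines)]
  ctg <- vapply(contigNames(dstGenome), function(nm)
    sprintf("##contig=<ID=%s,length=%d>", nm,
            contigLength(dstGenome, nm)), character(1))
  extra <- character()
  if (opts@recordSource && !reject) {
    extra <- c(
      '##INFO=<ID=SRC_CONTIG,Number=1,Type=String,Description="Source assembly contig">',
      '##INFO=<ID=SRC_POS,Number=1,Type=Integer,Description="Source assembly position">',
      '##INFO=<ID=SRC_REF_ALT,Number=.,Type=String,Description="Source assembly alleles">')
  }
  if (reject) {
    extra <- '##INFO=<ID=REJECT_REASON,Number=1,Type=String,Description="Reason the record could not be converted">'
    ctg <- header@lines[grepl("^##contig=", header@lines)]
  }
  lines <- c(keep, ctg, extra)
  h <- .parseVcfHeader(lines, paste(c("#CHROM", "POS", "ID", "REF", "ALT",
    "QUAL", "FILTER", "INFO",
    if (length(header@samples)) c("FORMAT", header@samples)),
    collapse = "\t"))
  h
}

#' Lift a VCF file across assemblies
#'
#' File-level driver: reads the input VCF, parses the chain file, builds
#' the index, converts every record in input order, and writes the
#' converted VCF (and optionally a reject VCF whose records carry their
#' drop reason in \code{INFO/REJECT_REASON}). The output header carries
#' contig lines from the destination FASTA. Output records are written
#' unsorted in input order.
#'
#' @param input path to the input VCF (or \code{"-"} for stdin).
#' @param srcFasta,dstFasta paths to indexed FASTA files (a missing
#'   \code{.fai} is created).
#' @param chainFile path to the UCSC chain file (.chain or .chain.gz).
#' @param output path for the converted VCF.
#' @param reject optional path for rejected records.
#' @param opts \linkS4class{LiftOptions}.
#' @param flexibleNames reconcile contig names across VCF, chain and
#'   FASTA by toggling the \code{"chr"} prefix (default TRUE).
#' @return invisibly, a named integer vector of per-status/reason counts;
#'   also reported via \code{message()}.
#' @export
liftVcf <- function(input, srcFasta, dstFasta, chainFile, output,
                    reject = NULL, opts = liftOptions(),
                    flexibleNames = TRUE) {
  srcGenome <- .openFasta(srcFasta)
  dstGenome <- .openFasta(dstFasta)
  chains <- parseChainFile(chainFile)
  index <- buildChainIndex(chains)
  vcf <- readVcfFile(input)
  knownNames <- unique(c(vapply(chains, function(c) c@tName, character(1)),
                         contigNames(srcGenome)))
  results <- vector("list", length(vcf$records))
  for (i in seq_along(vcf$records)) {
    rec <- vcf$records[[i]]
    if (flexibleNames && !rec@contig %in% knownNames) {
      nm <- reconcileContigNames(rec@contig, knownNames)
      if (!is.na(nm)) rec@contig <- nm
    }
    results[[i]] <- liftRecord(rec, index, srcGenome, dstGenome, opts,
                               vcf$header)
  }
  keep <- vapply(results, function(r) r@status != "DROPPED", logical(1))
  outHeader <- .rewriteHeader(vcf$header, dstGenome, opts)
  writeVcfFile(outHeader, lapply(results[keep], liftedRecord), output)
  if (!is.null(reject)) {
    rejHeader <- .rewriteHeader(vcf$header, dstGenome, opts, reject = TRUE)
    rejRecords <- lapply(which(!keep), function(i) {
      r <- vcf$records[[i]]
      r@info[["REJECT_REASON"]] <- results[[i]]@reason
      r
    })
    writeVcfFile(rejHeader, rejRecords, reject)
  }
  statuses <- vapply(results, liftStatus, character(1))
  reasons <- vapply(results, liftReason, character(1))
  summary <- c(table(statuses),
               table(reasons[!is.na(reasons)]))
  message("converted ", sum(keep), "/", length(results), " records (",
          paste(names(summary), summary, sep = "=", collapse = ", "), ")")
  invisible(summary)
}

.openFasta <- function(path) {
  if (!file.exists(paste0(path, ".fai"))) Rsamtools::indexFa(path)
  Rsamtools::FaFile(path)
}
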