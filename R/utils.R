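# internal string helpers shared across modules

.isPrefixOrSuffix <- function(x, y) {
  # TRUE when the shorter of x,y equals a prefix or a suffix of the longer;
  # N compares literally (N==N true, N==A false)
  if (nchar(x) > nchar(y)) { tmp <- x; x <- y; y <- tmp }
  nx <- nchar(x); ny <- nchar(y)
  substr(y, 1L, nx) == x || substr(y, ny - nx + 1L, ny) == x
}

.revComp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

.complement <- function(x) {
  chartr("ACGTNacgtn", "TGCANtgcan", x)
}

.isSymbolicAllele <- function(al) {
  grepl("[][<>]", al) | al == "*" | al == "."
}

.missing1 <- "."

.fmtNum <- function(x) {
  # stable numeric formatting for recomputed annotation values
  ifelse(is.na(x), ".", vapply(x, function(v) {
    if (is.na(v)) return(".")
    if (v == round(v) && abs(v) < 1e15) format(v, scientific = FALSE)
    else format(signif(v, 8), scientific = FALSE, trim = TRUE)
  }, character(1)))
}
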