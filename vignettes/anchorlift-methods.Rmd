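---
title: "Anchor-based liftover of VCF records: model, parameters and limits"
author: "anchorlift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchor-based liftover of VCF records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchorlift)
```

## The representation problem

A VCF record is one of many equivalent encodings of a variant: it can be
shifted (not left-aligned), padded (not parsimonious), or both. The
*normalized* record — left-aligned and parsimonious — is unique, and so
is the opposite canonical form used here, the *maximally extended*
record: the shortest representation in which (i) no allele is a prefix
or suffix of another, (ii) all alleles share their first and their last
base. Normalization answers "where does the variant start"; maximal
extension answers "which stretch of the genome is recognizably affected
by the variant". For an STR indel the extended alleles span the whole
repeat run plus one anchoring base on each side:

```{r}
g <- Biostrings::DNAStringSet(c(chr1 = "GGGCACACACAGGG"))
maximallyExtend(variantRecord("chr1", 5, "ACA", "A"), g)
```

The shared first base (the 5' anchor) and shared last base (the 3'
anchor) are the only positions the liftover must map. This is what
makes STR loci convertible: if the destination assembly carries a repeat
count different from both alleles, the sequence *between the mapped
anchors* still identifies the locus, and that sequence simply becomes a
novel reference allele.

Extension is computed as: normalize; extend one base left if the
alleles do not all share their first base; one base right if they do not
all share their last base; then, for each pair of alleles (alternate
pairs included), extend right while the shorter equals a prefix or
suffix of the longer. Each step is forced, which is why the result is
unique — a property the test suite verifies on thousands of randomly
perturbed representations. Because a right extension appends the same
base to every allele, the shared-first-base and shared-last-base
conditions cannot break once established, and a pair that has failed
both the prefix and the suffix test keeps failing after further
extension, so the pair loop terminates without re-checking earlier
pairs. `N` bases compare literally (N equals N, N differs from A):
deterministic, and consistent with byte comparison.

## Conversion outcomes

For a record whose allele pairs are all single-base substitutions, the
engine maps the one polymorphic base and reads the destination base:
equal to REF converts unchanged, equal to an ALT swaps reference and
alternate, equal to neither adds the destination base as a novel
reference. If the base is not covered by the chain — same-species
chains routinely contain 1-bp double-sided gaps exactly at polymorphic
positions, because the assemblies differ there — the record falls back
to the anchor path, which usually recovers it.

The anchor path maps the 5' and 3' anchors of the extended record. Both
must resolve to the same chain, contig and strand, in consistent order,
within the region cap; otherwise the record drops with
`anchors_discordant` or `region_too_long`. The destination anchor bases
are deliberately *not* required to match the source anchor bases — the
anchors locate the region, the sequence between them decides the
alleles. On a `-` strand chain the alleles are reverse-complemented
before comparison and the emitted record is left-aligned on the
destination forward strand.

When exactly one anchor maps and the other falls in a chain gap, the
missing anchor is recovered by realignment (next section). When both
anchors fail, no realignment is attempted — there is no anchored window
to realign within — and the record drops with `unmapped_both_anchors`.
Symbolic alleles (`<DEL>`, breakends, `*`) drop with
`symbolic_unsupported`: the method is sequence-based and has nothing to
compare. All failures are data (`DROPPED` plus a reason code), never
exceptions, so one bad record cannot abort a stream.

A conversion can turn an allelic primitive (SNV or indel) into a record
that is neither — e.g. a novel reference combined with an old alternate
forming a multi-base substitution. Such records are flagged
(`becameNonPrimitive`) and kept by default; `dropNonPrimitives = TRUE`
moves them to the reject stream, since they cannot match variants
natively called on the destination assembly.

## Anchor recovery by realignment

The recovery window on the source side is the extended region plus
`flank` bases beyond the failed side; on the destination side it starts
at the mapped anchor and extends the region length plus `flank` plus the
net size of the enclosing chain gap. The two windows are aligned
globally (Needleman–Wunsch, affine gaps) and the failed anchor's offset
is projected through the alignment; a projection landing inside a gap is
low-confidence and the record drops with `realign_failed` rather than
guessing.

Scoring defaults are match `1`, mismatch `-1`, gap open `-2` (charged on
the first column of each gap), gap extend `-1`, all exposed on the
command line. The anchor position depends on where the optimum lies,
not on the score scale, so standard values suffice; the suite checks the
kernel against exhaustive enumeration over short sequence pairs for
three parameter sets, and against an independent implementation
(`Biostrings::pairwiseAlignment`) on longer random pairs. Traceback
ties prefer a match column, then a gap in the destination, then a gap in
the source, evaluated from the terminal cell — a fixed order chosen for
determinism, with a leftward bias consistent with the left-alignment
applied afterwards. Alignment is global over the extracted windows, not
local: one end is anchored by the chain and the other bounded by the
window, so both ends are constrained by construction.

## Annotation updates

When allele order changes, header declarations drive the update:
Number=R and Number=G fields are re-ordered by the allele and
genotype-index permutation (the diploid index of genotype `(j,k)` being
`k(k+1)/2 + j`); AF-like fields (`AF`, `MAF`, `*_AF`) are re-ordered
under the assumption that frequencies over all alleles including the
implicit reference sum to 1; AC-like fields (`AC`, `*_AC`) under the
assumption that counts sum to `AN`; the GWAS-VCF effect size `ES` and
Z-score `EZ` flip sign for the swapped allele pair only; `INFO/END` is
recomputed from the final position and reference length; genotypes are
re-indexed, with unphased calls re-sorted ascending (missing first) and
phased calls keeping their order, preserving phase semantics.

Unknown tags declared Number=A/R/G are still permuted positionally; for
a plain Number=A tag the alternate promoted to reference loses its value
(there is no slot for a reference value) and the demoted reference's
slot becomes missing — honest but lossy, which is why only AF-like,
AC-like and ES/EZ fields get semantic recomputation. With a novel
reference allele the old reference is appended as the *last* alternate,
so existing Number=A positions are preserved and one value is appended;
R/G slots that involve the never-observed new reference are filled with
the missing sentinel `.`. QUAL, GQ and likelihood-coherent PL rescaling
beyond re-ordering are out of scope.

Merging co-located bi-allelic records into multi-allelic ones
(`mergeBiallelic`) pads references to the longest by right-extension,
concatenates Number=A values in record order, takes Number=R reference
values from the first record, and sets Number=G fields to missing — a
joint likelihood across independently-called records is not defined. A
sample whose non-reference alleles across records exceed its ploidy
refuses the merge for that site.

## The synthetic assembly pairs

`generateAssemblyPair()` builds a random source contig (default 50 kb),
plants 200 variants across scenario classes, derives the destination
genome by applying the planned edits, and writes the chain *exactly*
from the edit positions — so the chain, both genomes and the truth table
are mutually consistent by construction, which the suite verifies
base-by-base. The classes cover: untouched SNV and STR loci;
substitutions where the destination carries the alternate (bi- and
tri-allelic) or a third allele; STR runs (units of 2–4 bp, 4–7 copies)
resized to the alternate's or to a third repeat count; destination-only
insertions; deletions and translocated segments that remove the variant
from the destination; and inverted segments mapped by `-` strand chains.
Chains come in two dialects, because real same-species chains exhibit
both: `"gap"` mode excludes substituted bases from blocks as 1-bp
double-sided gaps (the BLAT behavior that breaks naive SNV liftover) and
`"mismatch"` mode keeps them inside blocks. A third of the STR edits in
gap mode additionally shift the chain gap over the 3' anchor base,
forcing the realignment recovery path. The defaults (window of ~250 bp
per variant, 8 bp insertions, 40–60 bp deleted/inverted segments) are
sized so that scenario windows do not interact; they are the study
conditions of the package, fixed once.

What the pairs do *not* emulate: sequencing error, realistic
allele-frequency spectra, nested or overlapping variation, large
structural differences between assemblies, multi-contig genomes, and
low-complexity regions beyond the planted STR runs. Passing the truth
table therefore demonstrates the coordinate/allele algebra and gap
handling, not robustness to pathological real-world chains; the drop
reasons and the ambiguity surfacing are the safety net for those.

## Numerical and design choices

* Chain files are 0-based half-open internally (UCSC convention); every
  public operation speaks 1-based inclusive VCF coordinates, converted
  in one place to prevent off-by-one drift.
* Source bases covered by more than one chain block answer
  `ambiguous` at query time and drop records with `ambiguous_mapping`;
  properly filtered liftover chains never trigger this, toy inputs may.
  Chain scores are parsed and preserved but never used to break ties.
* `flank` defaults to 100 bp: realignment windows must contain the
  anchor context plus any plausible small gap; STR runs and near-gap
  indels are an order of magnitude smaller.
* `maxRegionLen` defaults to 10 kb and bounds both the anchor span and
  destination fetches; anchors straddling enormous gaps are pathological
  under the anchor model and drop with `region_too_long`.
* AF-like updates tolerate `sum(AF) <= 1 + 1e-6`; beyond that the field
  is left untouched with a warning rather than inventing mass.
* Normalization at position 1 stops at the contig start and keeps the
  record; maximal extension that runs past either contig edge drops the
  record with `unanchorable_at_edge`.
* Output order is input order, never sorted; sorting is the caller's
  step and keeping it external makes streaming possible.

Problem sizes used by the checks: the acceptance suite and
`scripts/acceptance.R` run one 50 kb / 200-variant pair per property
(forward, inverse and mirrored), ~1200 perturbed representations for the
uniqueness property, exhaustive alignment enumeration for all `{A,C}`
pairs up to length 3 plus 150 random `{A,C,G,T}` pairs up to length 6
for three parameter sets; unit tests use 3–20 kb pairs. These sizes
exercise every code path; the per-record algebra is
length-independent.

## Known limitations

* Regions absent from the destination assembly are unconvertible in
  principle; they surface as `unmapped_both_anchors`.
* Variants whose both anchors fall in chain gaps are dropped even when
  flanking realignment might have located them; recovery is only
  attempted from one mapped anchor.
* BCF (binary) containers are not read or written; inputs and outputs
  are VCF text, optionally gzip-compressed.
* Haplotype-aware decomposition of complex records into primitives is
  out of scope; complex inputs are converted as-is when their anchors
  map.
* Homozygous-reference variants absent from the callset are not
  recovered; conversion is restricted to the records present in the
  input.
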