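# anchorlift

Allele-aware liftover of VCF records across genome assemblies.

## The problem

Coordinates of genetic variants are tied to a specific genome assembly.
Converting a callset or a set of GWAS summary statistics from one
assembly to another (GRCh37 to GRCh38, GRCh38 to a telomere-to-telomere
assembly, or to a closely related species) is routinely done through a
UCSC chain file that maps intervals between the two sequences. For SNVs
this is nearly trivial; for indels and short tandem repeats (STRs) it is
not, because the two assemblies need not carry the same allele at a
polymorphic locus: the destination may carry what the source called an
alternate allele, or an STR length matching neither allele. Naive
interval liftover then drops or silently corrupts those records, and
allele-indexed annotations (allele frequencies, counts, genotype
likelihoods, GWAS effect sizes) become wrong whenever the reference
allele changes.

`anchorlift` converts full VCF records, not intervals, for users who
need to harmonize legacy callsets or summary statistics with a newer
coordinate system without access to the raw reads.

## The method

Every variant has exactly one **maximally extended** representation: the
shortest representation in which no allele is a prefix or suffix of
another and all alleles share their first and their last base. It is
computed by normalizing (left-aligning and trimming) the record, then
extending the alleles with reference bases until the conditions hold.
The shared left-most and right-most bases are the **5' and 3' anchors**
— the only two positions that must be mapped through the chain:

```
REF(chr1:3) GCACACACAG        anchors at positions 3 and 12
ALT         GCACACAG          (a CA-unit deletion inside an STR run)
```

The engine maps both anchor bases through the chain index; the
destination sequence between the mapped anchors then decides the
outcome:

* it equals the reference allele — the record is converted unchanged
  (`REF_UNCHANGED`);
* it equals an alternate allele — reference and alternate swap roles
  (`REF_SWAPPED`) and every allele-indexed annotation is permuted:
  Number=R and Number=G fields are re-ordered, AF-like fields keep the
  unit-sum assumption (the implicit reference frequency is
  `1 - sum(AF)`), AC-like fields keep the AN-sum assumption, GWAS-VCF
  `ES`/`EZ` values flip sign, genotypes are re-indexed;
* it matches no allele — the destination sequence is inserted as a
  **novel reference allele** (`REF_ADDED`) and the record becomes
  multi-allelic, the common situation at STR loci whose repeat count
  differs between assemblies.

SNV records take a fast path (map the one polymorphic base, read the
destination base); when that base falls inside a chain gap they fall
back to the anchor path, which recovers variants other tools reject.
When exactly one anchor fails to map — typically at the edge of a chain
gap caused by the indel itself — the missing anchor is placed by global
Needleman–Wunsch realignment with affine gap costs of the flanking
sequence. Records on `-` strand chains are reverse-complemented.
Converted records are re-normalized against the destination genome;
failures are never exceptions but `DROPPED` results with a reason code.

## Worked example

```r
library(anchorlift)

# normalization and maximal extension
g <- Biostrings::DNAStringSet(c(chr1 = "GGGCACACACAGGG"))
rec <- variantRecord("chr1", 5, "ACA", "A")
normalizeRecord(rec, g)
#> VariantRecord: chr1:3 . GCA>G
maximallyExtend(rec, g)
#> ExtendedRecord: chr1:3 GCACACACAG/GCACACAG  anchors [3, 12]

# a synthetic assembly pair: 50 kb, 200 planted variants, exact chain
pair <- generateAssemblyPair(seed = 1)
idx  <- buildChainIndex(pairChains(pair))
res  <- liftRecords(plantedRecords(pair), idx, srcGenome(pair),
                    dstGenome(pair), header = pair@header)
tc <- truthCheck(res, pair)
tc$overall; tc$nonGap; tc$refValid
#> [1] 1      # every planted outcome reproduced
#> [1] 1      # including 100% of variants away from chain gaps
#> [1] 1      # every emitted REF matches the destination FASTA
tc$confusion
#>                observed
#> expected        DROPPED REF_ADDED REF_SWAPPED REF_UNCHANGED
#>   DROPPED            20         0           0             0
#>   REF_ADDED           0        40           0             0
#>   REF_SWAPPED         0         0          64             0
#>   REF_UNCHANGED       0         0           0            76

# one STR indel whose alternate allele is the destination reference
plantedRecords(pair)[[3]]
#> VariantRecord: chr1:619 var0003 A>ATG
res[[3]]
#> LiftResult: REF_SWAPPED -> chr1:627 ATG>A
```

The confusion table reads: 20 variants planted inside deleted or
replaced segments drop with a reason code, 40 STR/third-allele loci gain
a novel reference, 64 loci where the destination carries the alternate
swap alleles, and 76 untouched loci convert unchanged.

File-level conversion, including contig-name reconciliation, a reject
stream carrying `INFO/REJECT_REASON`, and unsorted input-order output:

```r
liftVcf("in.vcf", "src.fa", "dst.fa", "src_to_dst.over.chain",
        "out.vcf", reject = "rej.vcf")
```

or from the shell via the bundled script:

```sh
Rscript exec/anchorlift --input in.vcf --src-fasta src.fa \
  --dst-fasta dst.fa --chain src_to_dst.over.chain \
  --output out.vcf --reject rej.vcf --record-src --flexible-names
```

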