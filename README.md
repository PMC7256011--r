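# guidecraft

Design of CRISPR/Cas9 single guide RNAs (sgRNAs) in R, for any organism the
user can supply a FASTA genome and GTF annotation for. The package is aimed
at experimentalists and bioinformaticians who need *all* candidate guides in
a target region together with the sequence features that determine whether a
guide will actually work — not just a ranked shortlist.

For a query sequence, `sgrna_design()`:

- enumerates every 20-mer protospacer adjacent to a PAM (default 5'-NGG-3';
  any IUPAC pattern up to 6 bp) on both strands;
- reports per-guide **GC content** (over the 20-mer, PAM excluded),
  **homopolymer runs** (≥ 4 identical bases; TTTT additionally terminates
  RNA Pol III transcription), and **self-complementarity** (4-nt windows
  reverse-complementary to the guide itself or to the sgRNA backbone, which
  promote hairpins);
- predicts **on-target efficiency** in [0, 1] with a gradient-boosted
  regression model over the Rule Set 2 feature scheme: one-hot
  position-dependent single/dinucleotides, nucleotide counts, GC features,
  the PAM-bookend dinucleotide (positions 25/28 of the 30-mer context), and
  four nearest-neighbor melting temperatures (whole 30-mer and positions
  20–24, 12–19, 7–11), 627 features in all;
- scans an **un-indexed genome** for off-target loci within ≤ 4 mismatches
  of the 20-mer whose PAM matches the pattern or a listed variant
  (4-mismatch loci must match the PAM directly), scoring each hit with the
  multiplicative **CFD** scheme: score = Π(per-mismatch penalty) × PAM
  penalty; and
- annotates each locus against a GTF as exon / CDS / intron / intergenic
  with gene ID, gene name and exon number.

Mismatches are counted over the 20-mer only — a hit with 3 protospacer
mismatches behind a non-canonical PAM variant is a 3-mismatch hit, never 5.
The on-target locus itself is reported so its position can be verified.

The model is trainable: `train_efficiency_model()` fits any user table of
30-mer contexts with activity scores in [0, 1] (e.g. rank-normalized screen
read counts); the bundled `demo_model()` is trained on clearly-labeled
synthetic data and demonstrates the pipeline only. The shipped CFD table is
likewise a complete-coverage toy; load the published penalties with
`load_cfd_tables()` for real specificity work.

## Worked example

`generate_fixture()` builds a seeded random 10-kb genome with copies of one
guide planted at Hamming distances 0–4 (alternating strands), a query
containing exactly that guide, and a GTF placing one plant in an exon and
one in an intron:

```r
library(guidecraft)
fx  <- generate_fixture(42)
res <- sgrna_design(fx$query, genome = fx$genome, gtf = fx$gtf)

res$guides[, c(1:6, 8:9)]
#>         sgRNA_sequence PAM direction start end GC_content self_complementarity
#> 1 AAAACGCATGTTAACGCTGA TGG         +     5  24         40                    4
#>   efficiency_score
#> 1        0.3955041

res$offtargets[, c("chromosome","start","end","mismatches","strand",
                   "CFD_score","sequence_type","gene_name")]
#>   chromosome start  end mismatches strand CFD_score sequence_type gene_name
#> 1       chr1  1666 1685          0      +    1.0000    intergenic
#> 2       chr1  3335 3354          1      -    0.4000          exon     GENE1
#> 3       chr1  4998 5017          2      +    0.3200        intron     GENE2
#> 4       chr1  6667 6686          3      -    0.0720    intergenic
#> 5       chr1  8330 8349          4      +    0.0144    intergenic
```

One guide is found (start/end are 1-based protospacer coordinates on the
query's forward strand; GC 40%, four self-complementary 4-mers, efficiency
from the synthetic demo model). All five planted loci are recovered: the
perfect on-target match (CFD 1.0), then progressively mismatched sites with
multiplicatively shrinking CFD, annotated from the GTF. The guide table's
MM0–MM4 columns tally these hits (here 1 each); `write_guide_table()` /
`write_offtarget_table()` serialize both tables as CSV.

A thin command-line wrapper is installed under `exec/`:

```sh
guidecraft design --seq query.fa --genome genome.fa --gtf annot.gtf --out run1
guidecraft train --data activity.csv --out model.rds
guidecraft fixture --seed 7 --out fixdir
guidecraft score --seq query.fa
```

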