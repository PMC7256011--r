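---
title: "Guide RNA design with guidecraft: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guide RNA design with guidecraft}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guidecraft)
```

## What the package computes

CRISPR/Cas9 cleaves a genomic site when a 20-nt protospacer complementary to
the guide RNA spacer sits immediately 5' of a protospacer adjacent motif
(PAM; 5'-NGG-3' for SpCas9). Given a query sequence, `sgrna_design()`:

1. enumerates every 20-mer/PAM candidate on both strands (`find_guides()`),
2. reports per-guide sequence flags — GC content, homopolymer runs, 4-nt
   self-complementarity (`gc_content()`, `find_homopolymers()`,
   `self_complementarity()`),
3. scores expected on-target activity with a gradient-boosted regression
   model over the Rule Set 2 feature scheme (`featurize()`,
   `predict_efficiency()`),
4. optionally scans a genome for off-target loci within four mismatches and
   scores them with the multiplicative CFD scheme (`find_offtargets()`,
   `cfd_score()`), and
5. optionally annotates each locus against a GTF (`annotate_hits()`).

The result is two tables: one row per candidate guide, and one row per
off-target locus.

## Guide discovery and the 30-mer scoring context

A candidate guide is a 23-bp window (20-mer + 3-bp PAM for NGG) on either
strand. For scoring, a 30-mer context is extracted in guide orientation: 4 nt
of 5' flank, the 20-mer (positions 5–24), the PAM slot (25–27 for a 3-bp
PAM), and the sequence out to 6 nt past the protospacer (28–30). The 3'
flank is defined as the 6 nt immediately 3' of the protospacer rather than
"PAM + 3 nt", so the window layout does not change when a custom PAM of a
different length is used and the same scoring model can be applied (with a
low-confidence caveat recorded in the `notes` column). Candidates whose
30-mer would run past the query ends are dropped, not padded: every feature
column below is defined on a full window, and padding would fabricate
sequence. Windows containing non-ACGT bases (N runs in real assemblies) are
likewise skipped. Duplicate protospacers at different positions are all
reported; duplicate *perfect genomic matches* are instead surfaced in the
notes so that cloning against a multi-copy site is visible.

PAM patterns are IUPAC strings of at most 6 bp (`compile_pam()`); the
default is NGG. One PAM per run: users wanting several alternate PAMs run
the design once per PAM.

## Sequence flags

* **GC content** is computed over the 20-mer only — the PAM's composition
  does not contribute to guide/target pairing — and reported as a
  percentage.
* **Homopolymers** are maximal runs of ≥ 4 identical bases. Any such run
  reduces cutting activity; runs of T are additionally flagged because four
  consecutive T's terminate RNA polymerase III transcription, truncating the
  sgRNA in the common U6/H1 expression systems.
* **Self-complementarity** counts 4-nt windows of the protospacer whose
  reverse complement occurs elsewhere in the protospacer or anywhere in the
  sgRNA backbone; both kinds of match promote hairpins and are weighted
  equally, and each window is counted at most once. A palindromic window is
  not allowed to match itself (a fold partner must be a *different* region).
  The default backbone (`default_backbones()`, shipped as
  `inst/extdata/backbone.txt`) is the hairpin-prone tracrRNA-proximal region
  of the standard SpCas9 scaffold; it is a configuration default, not a
  measured constant — replace the file or pass `backbones=` for other
  scaffolds. No free-energy folding is attempted; the count is a cheap,
  conservative screen, and whether a GC-content requirement should be added
  to the 4-mer match is deliberately left to the user's backbone
  configuration.

## Rule Set 2 featurization

`featurize()` maps a 30-mer to 627 named features:

| group | count |
|---|---|
| position-dependent single nucleotides (one-hot, positions 1–30) | 120 |
| position-dependent dinucleotides (one-hot, positions 1–29) | 464 |
| single-nucleotide counts over the 30-mer | 4 |
| dinucleotide counts over the 30-mer | 16 |
| protospacer GC count + above-10 / below-10 flags | 3 |
| PAM-bookend dinucleotide (positions 25 and 28, one-hot) | 16 |
| melting temperatures | 4 |

The bookend positions 25 and 28 are the bases flanking the "GG" of an NGG
PAM in 1-based 30-mer coordinates. The cut-site-in-protein feature of the
original scheme is intentionally absent — not every target lies in a coding
region. Feature names are fixed in `feature_registry()`; serialized models
embed the registry and refuse to load against a different one.

### Melting temperatures

`melting_temperature()` implements the unified nearest-neighbor model with
Allawi & SantaLucia stacked-pair ΔH/ΔS increments and terminal initiation
corrections:

Tm = 1000·ΔH / (ΔS + R·ln(C/4)) − 273.15 + 16.6·log10([Na+])

with R = 1.987 cal K⁻¹ mol⁻¹, strand concentration C = 50 nM (the C/4 term
assumes a non-self-complementary duplex) and [Na+] = 50 mM. These constants
are pinned as function defaults so any dialect of the formula can be matched
explicitly; the terminal A/T–G/C initiation terms can be disabled via
`terminal_correction = FALSE`. The four features are the Tm of the whole
30-mer and of positions 20–24 (PAM-proximal 5-mer), 12–19 (8-mer) and 7–11
(distal 5-mer). The implementation agrees with an independently coded
nearest-neighbor reference to < 1e-5 °C on frozen test fixtures.

## The efficiency model

`train_efficiency_model()` fits gradient-boosted regression trees (xgboost,
squared-error objective, exact single-threaded tree construction for
determinism) to a table of 30-mers with activity scores in [0, 1] — the
form produced by rank-normalizing read counts from a pooled screen.
Zero-variance columns are pruned first (`prune_features()`): a restrictive
PAM forces identical bases at the PAM-slot positions of every training
sequence, so those one-hots carry no information. Defaults are a few hundred
shallow trees (`nrounds = 300`, `max_depth = 3`, `eta = 0.08`,
`min_child_weight = 2`, no subsampling), chosen as ordinary
boosted-regression settings for ~600 sparse features and a few thousand
rows; all are overridable per call. Predictions are clamped to [0, 1].

The package does **not** ship weights fitted to the published FC/RES
screens; those data are external. Instead:

* `demo_model()` trains (and caches) a small model on
  `synthetic_training_set()` data — random 30-mers whose latent activity is
  `clamp01(gc_count/20 + 0.2·[G at position 24]) + N(0, 0.05)`, re-clamped.
  It is labeled synthetic everywhere and demonstrates the pipeline, not
  biology.
* `train_efficiency_model()` + `save_model()`/`load_model()` provide the
  documented path to a production model from any user-supplied
  30-mer/score table (CSV columns `context30`, `score`).

The synthetic generator emulates the *shape* of activity data (bounded
scores, position- and composition-dependent signal, modest noise). It does
not emulate screen-specific biases, guide-abundance effects, or the
covariance structure of real nucleotide preferences, so a high held-out
correlation here demonstrates that training recovers planted signal — not
that scores are experimentally calibrated. Validation is accordingly a
signal-recovery experiment: training on 1,600 of 2,000 synthetic rows and
scoring the 400 held out recovers Spearman ρ ≈ 0.94 (the acceptance
threshold is ρ ≥ 0.6), and feature importance concentrates on the GC count
and position-24 features that generated the signal.

## Off-target search and CFD scoring

`find_offtargets()` slides the guide over every window of every chromosome
on both strands — an un-indexed rolling comparison with per-position
vectorized counting. No genome preprocessing or index is needed, which is
the point: custom genomes work immediately, at the price of scan time
proportional to genome size per guide (a logged advisory suggests keeping
queries under 250 bp when searching billion-base genomes).

A locus is reported when

* its 20-mer is within 4 Hamming mismatches of the guide (indels are not
  considered), **and**
* its adjacent PAM either matches the run's PAM pattern or appears in the
  PAM-variant penalty table, **except** that loci with exactly 4 mismatches
  must match the PAM pattern directly — a 4-mismatch site behind a
  non-canonical PAM is very unlikely to cut and is suppressed.

Mismatches are counted over the 20-mer only; PAM differences are *never*
added to the mismatch count. A site differing by 3 protospacer bases behind
a penalized PAM variant is a 3-mismatch hit, not a 5-mismatch one — the two
kinds of tolerance are biologically distinct and are handled by separate
penalty maps. Perfect matches, including the on-target locus itself, are
reported so the user can verify the target's position. Mismatch positions
are reported as a 1–20 list (position 1 PAM-distal) in a dedicated column.

`cfd_score()` multiplies one penalty per mismatched position — keyed by
(position, guide base, off-target base) — by a PAM-variant penalty. The
package ships a *toy* table (`toy_cfd_table()`): complete key coverage,
round values in {0.2, …, 0.8}, canonical NGG variants at 1.0, NAG/NGA-style
variants penalized. It exercises every code path deterministically; it is
not the published empirical table, which users load from the original
supplementary data via `load_cfd_tables()` (RNA `U` in guide bases is
converted to DNA `T` on load).

## Annotation

`annotate_hits()` joins hits against GTF records by strand-agnostic overlap
— a double-strand break affects a feature from either strand, and a single
shared base counts. Classification: overlapping exon → `exon` (with that
exon's gene and number); else CDS; else any other non-gene feature type,
passed through verbatim; else inside a gene/transcript body → `intron`;
else `intergenic`. Where several records of the winning type overlap, the
smallest start wins, ties broken by gene_id, making the join a pure function
of the record *set*. A hit chromosome absent from the GTF is simply
intergenic.

## The fixture generator

`generate_fixture()` builds the package's own ground truth: a seeded random
genome with copies of one guide planted at requested Hamming distances
(0–4) and PAM variants, alternating strands; a 30-bp query containing
exactly that guide (its padding is an A/T alternation and the guide is
generated without GG/CC dinucleotides, so no second PAM can occur on either
strand); a GTF placing one plant in an exon and one in an intron; and a
manifest of every planted truth. Because the construction *is* the oracle,
scanner, annotation and pipeline outputs can be checked row-for-row. Random
10-kb sequence can in principle contain accidental ≤4-mismatch loci
(probability per genome well under 1%); tests therefore use fixed seeds and
the manifest as the reference.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere, matching GTF.
* Ordering: guides by forward-strand start then `+` before `-`; hits by
  chromosome, start, strand. All runs are deterministic given inputs and
  seeds; repeated runs produce byte-identical CSVs.
* Boosting uses exact greedy splits with one thread; permuting training
  rows changes float accumulation order for tied feature values, so
  row-order invariance holds to ~1e-6, not bit-exactly.
* Degenerate inputs: queries shorter than 20 + PAM error; an all-identical
  feature matrix errors at pruning ("no informative features"); a truncated
  or registry-mismatched model file errors at load.
* Test and validation problem sizes (10-kb genomes, 50 guides × 20 seeds
  for oracle equivalence, 2,000 training rows) were chosen to exercise all
  code paths at interactive runtimes.

## Limitations

* Shipped CFD values and the demo efficiency model are synthetic; real
  scoring requires the published penalty tables and a user-trained model.
* Cpf1/Cas12a-style 5' PAMs, variable-length spacers, bulge/indel
  off-targets, aggregate specificity scores and RNA secondary-structure
  prediction are out of scope.
* The scanner's un-indexed design trades speed on large genomes for zero
  preprocessing; for genome-scale screens an indexed tool is the better
  fit.
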