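---
title: "Evaluating upstream ORFs as candidate novel first coding exons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating upstream ORFs as candidate novel first coding exons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uorfexonizer)
```

## The question

Ribosome profiling and comparative genomics have nominated thousands of
short upstream open reading frames (uORFs) in the 5' untranslated regions
of human genes as candidate novel protein-coding genes. Taken at face
value, each of these would create a bicistronic transcript — one mRNA
encoding two proteins — which is a vanishingly rare arrangement in the
human annotation. `uorfexonizer` implements an alternative reading of the
same evidence: a uORF may instead be an unannotated *first coding exon* of
the downstream gene, joined to it by a splice donor inside the uORF and an
acceptor in the known CDS. Under that model the Ribo-seq signal drop at
the end of the uORF marks a splice donor, not a stop codon.

The package provides four analysis stages and a synthetic-data generator
that plants ground truth for all of them, so the entire inference chain is
testable end to end without genome-scale inputs.

## Conservation scoring

Each uORF is aligned to every target genome twice: against the genomic
sequence, and against the annotated transcript sequences (the
transcriptome alignment is what recovers uORFs spanning two 5'UTR exons,
whose genomic footprint is interrupted by an intron). Each hit is scored
on three weighted criteria:

| criterion                                   | weight |
|---------------------------------------------|-------|
| full-length, 100%-identical sequence match  | 4     |
| containment in a transcript's 5'UTR         | 2     |
| gene-locus match (expected downstream gene) | 1     |

yielding a 0–7 level. A uORF scoring above 3 is conserved in that genome,
with two refinements taken from curation practice:

* **distance exception** — a sequence match more than 1,000 bp from the
  expected gene is not conserved regardless of score;
* **curation bump** — assessments at the no-locus levels (0, 4, 6) whose
  alignment lies strictly within 100 bp of the expected gene gain the
  locus weight.

When the nucleotide identity test fails, a *protein-level fallback*
translates the aligned span in all six frames and accepts the hit if any
translation equals the query ORF's protein — this is what keeps a uORF
with a synonymous substitution at level 7 rather than dropping it to 3.
Genomic and transcriptomic assessments are reconciled by maximum level,
with ties going to the genomic record (its coordinates need no
projection). When several hits exist, the one maximising
(sequence match, then score, then smallest locus distance) is retained.

Two readings of the rules were genuinely open and are fixed here as
package decisions: the distance exception is applied whenever the
recorded locus distance exceeds the bound, at any level, and the curation
bump set is `{0, w_seq, w_seq + w_utr}` (the published triple 0/4/6),
deliberately excluding the UTR-only level 2, which lacks the sequence
evidence that motivates the bump.

## Constructing uORF-connected transcripts

Construction runs on the **full** catalogue, including uORFs that failed
conservation — the conservation gate is applied to the final list only.
Two evidence routes produce candidate junctions:

* **experimental** junctions (read-coverage-supported), filtered to
  canonical motifs (donor GT or GC, acceptor AG, read strand-oriented
  from the genome), whose donor falls strictly inside the uORF coding
  span and whose acceptor falls inside the reference CDS (a mid-exon
  acceptor trims the 5' part of that exon);
* **predicted** junctions: every GT dinucleotide inside the uORF is a
  donor candidate, paired with annotated acceptor sites of MANE reference
  CDS exons, scored by a pluggable splice-site scorer, and retained when
  the donor/acceptor mean score is at least 0.9. Pairs already present in
  the experimental set are excluded, so the two evidence sets are
  disjoint by construction. Predicted donors are restricted to GT; GC
  donors are admitted only with experimental support.

The novel CDS is the uORF from its start codon up to the donor,
concatenated with the reference CDS from the acceptor through the stop,
honouring all downstream introns. A donor must retain at least the start
codon (3 bases) and sit strictly before the uORF stop codon — both
boundaries the published procedure leaves implicit; they are fixed here
and tested. Translation is literal (standard code, no forced initiator
methionine — a construct starting ATA begins with isoleucine and is
flagged `non_AUG`), and each construct is validated against three discard
rules: a premature stop codon, a length not divisible by three, or a CDS
shorter than 90% of the reference CDS (the rule is read as *CDS* length,
not transcript length, following the wording "encoded a CDS whose
length"; the boundary value 0.9 passes). Constructs encoding exactly the
reference protein (uORF/CDS duplications) are flagged, not dropped, and
constructs are deduplicated to distinct (uORF, protein, reference)
triples, keeping the highest-support representative with ties broken by
smallest construct id.

## Structure-confidence comparison

Folding sits behind a backend interface `(protein_id, protein) ->
confidence_profile`; the shipped mock backend returns a deterministic
per-residue profile with an exactly requested mean. Proteins longer than
2,000 residues are not folded (the boundary is strict: 2,000 folds, 2,001
is skipped). For each validated construct the mean per-residue confidence
(pLDDT) is compared against every reference protein at the locus and the
**best** delta is kept — a construct survives if it is at least similar to
*one* reference. Classification uses the published ±1 band: delta > 1 is
`higher`, −1 ≤ delta ≤ 1 `similar`, delta < −1 `lower`; retained = higher
∪ similar. Means are rounded to 2 decimals before differencing (the
precision deltas are reported at), which keeps classification at the ±1
boundary free of binary-float artefacts; the predicted-junction score
threshold applies the same defence at 0.9. Structural-change categories
(end truncation, helix deletion/truncation, helix elongation,
straightening, tightening, structural addition) are operator-assigned by
visual inspection; the package stores the fixed vocabulary and
operator-provided codes but never infers categories.

## The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` builds `n_loci` single-gene loci, one small
chromosome each (≈5–11 kbp: large enough for the >1 kbp relocation case,
small enough for exhaustive brute-force oracles). Each locus draws:

* an **architecture** — single-exon 5'UTR (60%), uORF spanning two UTR
  exons (25%), or uORF overlapping the CDS start (15%; the overlap is a
  fixed 4 bases, the one geometry in which the uORF stop codon and the
  downstream start codon can share sequence without corrupting either
  frame);
* a **junction-evidence source** — none / experimental / predicted /
  both (25/30/25/20%), realised by planting a GT donor inside the uORF,
  optionally carrying the 8-mer signature the mock splice scorer marks as
  strong (0.96; bare GT scores 0.35, so accidental donors never reach the
  0.9 threshold). Every annotated intron ends with the strong-acceptor
  signature, mirroring how real acceptors of expressed transcripts score
  well;
* an **ORF-validity outcome** — valid (76%), frame violation (a donor
  retaining a non-multiple-of-3 prefix), or too-short (an acceptor deep
  in the CDS leaving under 90%);
* a **confidence delta class** — higher (+2.96), similar (+0.5), the
  similar boundary (−1.0, exercising the band edge), or lower (−3.41),
  planted through the mock backend's target means around a reference mean
  of 75; two loci carry >2,000-residue proteins to exercise the folding
  skip;
* one **mutation plan per target genome** — identical (50%), synonymous
  substitution (14%), non-synonymous substitution (10%), 1-bp deletion
  (5%), relocation >1 kbp away (8%), 5'UTR deletion from the annotation
  (9%), or locus loss (4%).

Expected conservation levels are fixed by the plan: identical and
synonymous → 7 (the latter through the protein fallback), non-synonymous
→ 3, UTR deletion → 5, relocation → 5 but not conserved (the nearest
gene still carries the expected name, so the locus weight applies while
the distance exception vetoes the verdict), deletion and locus loss → 0.
Two plans needed care to keep the labels *derivable* rather than merely
likely: a 1-bp deletion near either uORF end is always recoverable by a
shifted Hamming window (the frameshifted tail realigns), so deletions are
placed mid-uORF and the generator verifies on the derived locus that no
full-length near-match survives; and a UTR deletion over a spliced uORF
leaves content-dependent partial matches, so that plan is rejected as
incompatible with spliced uORFs and the cohort redraws it as a
non-synonymous substitution.

Junction read coverages are drawn higher (200–300) for loci destined to
be retained than for the rest (40–80), so the retained-versus-all mean
coverage comparison computed by the report has a real signal to find.

What the generator does **not** emulate: sequencing noise and read-level
evidence (junctions arrive pre-summarised), gene families and repetitive
DNA (each uORF is verified to be uniquely placeable, so alignment
ambiguity and paralogy are out of frame), indel-tolerant alignment (the
built-in aligner is exact/Hamming only), annotation errors other than the
planted ones, and real folding behaviour (profiles are planted means, not
structure predictions). Passing the recovery suite therefore demonstrates
that the inference chain is correct on unambiguous inputs, not that it is
robust to the ambiguities of real genomes.

## Numerical and representational choices

* **Coordinates** are 1-based fully closed throughout, the native
  convention of the IRanges/Biostrings stack the package is built on;
  GFF3 I/O is convention-free, and any 0-based formats convert at the
  boundary.
* **Alignment** is full-length exact match first, then best Hamming match
  (default budget 3 substitutions, no indels) — an intentionally
  exhaustive, oracle-checkable stand-in for a real short-read aligner.
* **Determinism**: every stochastic step takes an explicit seed and
  restores the caller's RNG state; mock confidence profiles use a van der
  Corput low-discrepancy sequence rescaled to the requested mean
  (exact to 1e-9) rather than RNG draws.
* **Degenerate inputs**: empty junction tables, uORFs with no GT, loci
  whose expected gene is missing from a target annotation (recorded with
  an `NA` distance for the missing-genes report), and all-skipped
  reference sets (class `skipped`) all have pinned behaviour.

## Problem sizes

The standard cohort is 100 loci × 4 target genomes, the size at which the
whole pipeline (alignment in two modes, construction over both evidence
routes, structure bookkeeping) runs in well under a minute on one CPU and
every planted label is recovered exactly; unit tests use 4–14 loci.
`scripts/acceptance.R` re-runs this cohort from a command-line seed and
recomputes the published arithmetic identities from their printed inputs.

## Known limitations

* The conservation module consumes pre-lifted annotations; it does not
  perform liftover, and the manual-inspection narrative around ambiguous
  mappings is reduced to the codified <100 bp curation bump.
* Gene-name matching is exact up to an optional synonym table.
* The aligner's Hamming fallback cannot recover indel-containing matches;
  real pipelines using affine-gap aligners would score some of those as
  protein-level matches.
* NMD status is read from annotation tags, never predicted.
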