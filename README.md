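# uorfexonizer

Thousands of short upstream open reading frames (uORFs) in the 5'
untranslated regions of human genes have been proposed as novel
protein-coding genes. Each such gene would create a bicistronic
transcript — a single mRNA encoding two proteins — an arrangement that is
extremely rare in the human annotation. `uorfexonizer` implements and
tests the competing hypothesis: that a uORF can instead be an unannotated
**first coding exon** of its downstream gene, linked to it by a splice
donor inside the uORF and an acceptor in the known CDS. It is written for
computational genomicists who want the full inference chain — conservation
screening, isoform construction, ORF validation, structure-confidence
comparison — as tested, composable R functions.

## The method

**1. Cross-genome conservation.** Each uORF is aligned to every target
genome twice (genome and transcriptome; the latter recovers uORFs
spanning two 5'UTR exons) and scored on three weighted criteria:

| criterion | weight |
|---|---|
| full-length, 100%-identical sequence match (with a six-frame protein-level fallback) | 4 |
| containment in the 5'UTR of an annotated transcript | 2 |
| gene-locus match against the expected downstream gene | 1 |

A uORF with score *s* > 3 is conserved in that genome, **unless** the
match lies more than 1 kbp from the expected gene; assessments at the
no-locus levels 0/4/6 within 100 bp of the gene are bumped by the locus
weight. Genomic and transcriptomic results reconcile by maximum level.

**2. uORF-connected transcripts.** For every uORF (conservation gating is
applied only at the end), canonical experimental junctions
(GT/GC..AG) whose donor lies inside the uORF and whose acceptor lies in
the reference CDS — plus scanned GT donors paired with annotated MANE
acceptors at a mean splice score ≥ 0.9 — yield candidate CDSs:

```
CDS_novel = uORF[start codon .. donor) ++ referenceCDS[acceptor .. stop]
```

A construct is discarded if it (1) contains a premature stop codon,
(2) has length ≢ 0 (mod 3), or (3) encodes a CDS shorter than 90% of the
reference CDS. Literal translation exposes non-AUG starts (isoleucine
instead of methionine), reference-protein duplicates are flagged, and
constructs are deduplicated to distinct (uORF, protein, reference)
triples.

**3. Structure comparison.** Mean per-residue confidence (pLDDT, via a
pluggable folding backend; proteins > 2,000 residues are skipped) is
compared between each construct and its reference proteins. With
δ = mean(novel) − mean(best reference): δ > 1 is *higher*, −1 ≤ δ ≤ 1
*similar*, δ < −1 *lower*; retained = higher ∪ similar, and a construct
needs only one sufficiently similar reference.

**4. Reporting.** Per-genome level tables with distance-exception
tallies, subset intersection counts, evidence-partitioned retention
counts with inclusion–exclusion audits, and a junction-coverage
comparison between retained and all experimental constructs.

A deterministic synthetic-data generator (`generate_cohort()`) plants
ground truth for every stage — conservation levels per mutation plan,
linking junctions, validity outcomes, confidence deltas — so the entire
pipeline is verifiable by exact label recovery.

## Worked example

```r
library(uorfexonizer)

cohort <- generate_cohort(n_loci = 20, n_genomes = 4, seed = 7)
result <- run_pipeline(cohort)

result$conservation_summary$subtotals
#>   target_genome n_conserved n_not_conserved n_exception
#> 1            G1          13               6           1
#> 2            G2          11               7           2
#> 3            G3          13               3           4
#> 4            G4          10               7           3

result$summary$n_constructs_by_evidence
#> experimental    predicted
#>            7            9

result$summary$n_retained_by_evidence
#> experimental    predicted
#>            3            6

check_truth_recovery(result, cohort)
#>              field  n n_match pct_match
#> 1     conservation 80      80       100
#> 2 linking_junction 20      20       100
#> 3   orf_validation 20      20       100
#> 4      delta_class 20      20       100
```

Reading the output: of 20 synthetic uORFs, 10–13 are conserved per
genome (the `n_exception` column counts sequence matches found > 1 kbp
from the expected gene, which score well but are not conserved); 16
validated uORF-connected transcripts were built across the two evidence
routes, 9 of which encode proteins whose mean confidence is similar to or
higher than their reference; and every planted ground-truth label was
recovered exactly.

The same run is available from a shell:

```sh
Rscript inst/scripts/uorf_exonizer.R run-all --n-loci 20 --n-genomes 4 --seed 7 --outdir out/
```

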