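test_that("protein fallback accepts synonymous drift and rejects
           frameshifts, agreeing with a six-frame oracle", {
  q <- "ATGCTGGCAAAATAA"                       # M L A K *
  expect_true(protein_fallback_match(q, q))
  syn <- "ATGCTAGCAAAATAA"                     # CTG -> CTA, both Leu
  expect_true(protein_fallback_match(q, syn))
  expect_true(oracle_six_frame_match(q, syn))
  fs <- "ATGCTGGCAAATAA"                       # 1-bp deletion, frameshift
  expect_false(protein_fallback_match(q, fs))
  expect_false(oracle_six_frame_match(q, fs))
  # a reverse-complemented target still matches (strand enumeration)
  expect_true(protein_fallback_match(q, oracle_revcomp(syn)))

  set.seed(31)
  codons <- names(ORACLE_CODONS)[ORACLE_CODONS != "*"]
  for (i in 1:100) {
    n <- sample(4:8, 1)
    orf <- paste0("ATG", paste(sample(codons, n, TRUE), collapse = ""), "TAA")
    tgt <- orf
    p <- sample(nchar(orf), 1)
    if (i %% 2 == 0) {               # substitution
      tgt <- paste0(substr(tgt, 1, p - 1),
                    chartr("ACGT", "CGTA", substr(tgt, p, p)),
                    substr(tgt, p + 1, nchar(tgt)))
    } else {                         # deletion
      tgt <- paste0(substr(tgt, 1, p - 1), substr(tgt, p + 1, nchar(tgt)))
    }
    expect_identical(protein_fallback_match(orf, tgt),
                     oracle_six_frame_match(orf, tgt))
  }
})

test_that("the score is the weighted sum of its flags, with the documented
           attainable set", {
  w <- conservation_weights()
  flags <- expand.grid(s = c(FALSE, TRUE), u = c(FALSE, TRUE),
                       l = c(FALSE, TRUE))
  scores <- integer(0)
  for (i in seq_len(nrow(flags))) {
    a <- score_assessment(flags$s[i], flags$u[i], flags$l[i], w)
    expect_identical(a$score,
                     as.integer(4L * flags$s[i] + 2L * flags$u[i] +
                                  1L * flags$l[i]))
    scores <- c(scores, a$score)
    # {1,2,3} imply no sequence match, hence never conserved
    if (a$score %in% 1:3) expect_false(a$conserved)
  }
  expect_setequal(scores, 0:7)

  # monotonicity: raising any flag never lowers the score
  for (i in seq_len(nrow(flags))) {
    base <- score_assessment(flags$s[i], flags$u[i], flags$l[i], w)$score
    for (f in c("s", "u", "l")) {
      up <- flags[i, ]
      up[[f]] <- TRUE
      expect_gte(score_assessment(up$s, up$u, up$l, w)$score, base)
    }
  }
})

test_that("verdicts honour the minimum score and the >1 kbp exception", {
  w <- conservation_weights()
  full <- score_assessment(TRUE, TRUE, TRUE, w, locus_distance = 0L)
  expect_identical(full$score, 7L)
  expect_true(full$conserved)

  far <- score_assessment(TRUE, FALSE, FALSE, w, locus_distance = 2000L)
  expect_identical(far$score, 4L)
  expect_false(far$conserved)

  near <- score_assessment(TRUE, FALSE, FALSE, w, locus_distance = 900L)
  expect_true(near$conserved)

  none <- score_assessment(FALSE, FALSE, FALSE, w)
  expect_identical(none$score, 0L)
  expect_false(none$conserved)
})

test_that("curation bumps only levels 0/4/6 within 100 bp and never
           decreases a score", {
  w <- conservation_weights()
  bump <- curate_assessment(
    score_assessment(TRUE, TRUE, FALSE, w, locus_distance = 40L), w)
  expect_identical(bump$score, 7L)
  expect_true(bump$curated)
  expect_true(bump$conserved)

  too_far <- curate_assessment(
    score_assessment(TRUE, TRUE, FALSE, w, locus_distance = 400L), w)
  expect_identical(too_far$score, 6L)
  expect_false(too_far$curated)

  at_bound <- curate_assessment(
    score_assessment(TRUE, TRUE, FALSE, w, locus_distance = 100L), w)
  expect_identical(at_bound$score, 6L)   # bound is strict (< 100)

  lvl4 <- curate_assessment(
    score_assessment(TRUE, FALSE, FALSE, w, locus_distance = 10L), w)
  expect_identical(lvl4$score, 5L)
  expect_true(lvl4$curated)

  # level 5 (sequence + locus) is not in the bump set
  lvl5 <- score_assessment(TRUE, FALSE, TRUE, w, locus_distance = 40L)
  expect_identical(curate_assessment(lvl5, w), lvl5)

  # property: curation never decreases any score
  for (s in c(FALSE, TRUE)) for (u in c(FALSE, TRUE)) for (l in c(FALSE, TRUE)) {
    a <- score_assessment(s, u, l, w, locus_distance = 50L)
    expect_gte(curate_assessment(a, w)$score, a$score)
  }
})

test_that("reconciliation takes the maximum level with a genomic tie
           rule", {
  w <- conservation_weights()
  g5 <- score_assessment(TRUE, FALSE, TRUE, w); g5$mode <- "genomic"
  t7 <- score_assessment(TRUE, TRUE, TRUE, w); t7$mode <- "transcriptomic"
  expect_identical(reconcile_assessments(g5, t7)$score, 7L)
  g7 <- score_assessment(TRUE, TRUE, TRUE, w); g7$mode <- "genomic"
  expect_identical(reconcile_assessments(g7, t7)$mode, "genomic")
  expect_identical(reconcile_assessments(g7, NULL), g7)
  expect_identical(reconcile_assessments(NULL, t7), t7)
  # idempotent
  expect_identical(reconcile_assessments(g7, g7), g7)
})

test_that("5'UTR containment allows multi-exon and CDS-overlap footprints
           but not introns", {
  loc <- toy_locus()
  ann <- loc$annotation
  expect_true(assess_utr_containment(data.frame(start = 61, end = 72),
                                     ann, "chrT"))
  expect_false(assess_utr_containment(data.frame(start = 85, end = 95),
                                      ann, "chrT"))     # intronic
  # starts in the UTR, extends into the CDS (overlap allowance)
  expect_true(assess_utr_containment(data.frame(start = 70, end = 80,
                                                stringsAsFactors = FALSE)[
                                       c(1, 1), ][1, , drop = FALSE],
                                     ann, "chrT"))
  expect_true(assess_utr_containment(
    data.frame(start = c(70, 101), end = c(80, 105)), ann, "chrT"))
  # exonic but starting inside the CDS: not 5'UTR containment
  expect_false(assess_utr_containment(data.frame(start = 101, end = 108),
                                      ann, "chrT"))
})

test_that("locus matching reports overlap, distance, and missing genes", {
  loc <- toy_locus()
  ann <- loc$annotation
  inside <- assess_locus_match(data.frame(start = 60, end = 75), ann,
                               "chrT", "TOY")
  expect_true(inside$match)
  expect_identical(inside$distance, 0L)

  # toy gene ends at 159; a hit at 170..180 is 10 bp downstream
  off <- assess_locus_match(data.frame(start = 170, end = 180), ann,
                            "chrT", "TOY")
  expect_true(off$match)
  expect_identical(off$distance, 10L)

  missing <- assess_locus_match(data.frame(start = 60, end = 75), ann,
                                "chrT", "ABSENT")
  expect_false(missing$match)
  expect_true(is.na(missing$distance))

  # synonym table maps the annotation name onto the catalogue name
  syn <- assess_locus_match(data.frame(start = 60, end = 75), ann,
                            "chrT", "TOY2", synonyms = c(TOY = "TOY2"))
  expect_true(syn$match)
})

test_that("end-to-end assessment recovers the planted conservation classes", {
  sp <- locus_spec("chrG", plant_donor = "none")
  loc <- generate_reference_locus(sp, 33)
  genome <- stats::setNames(loc$seq, loc$chrom)

  a <- assess_uorf_conservation(loc$uorf, genome, loc$annotation, "self")
  expect_identical(a$score, 7L)
  expect_identical(a$sequence_match_kind, "nucleotide")
  expect_true(a$conserved)

  syn <- derive_individual_genome(loc, mutation_plan("synonymous_sub"))
  a <- assess_uorf_conservation(loc$uorf, syn$genome, syn$annotation, "syn")
  expect_identical(a$score, 7L)
  expect_identical(a$sequence_match_kind, "protein_fallback")

  rel <- derive_individual_genome(loc, mutation_plan("relocate_gt_1kbp"))
  a <- assess_uorf_conservation(loc$uorf, rel$genome, rel$annotation, "rel")
  expect_identical(a$score, 5L)
  expect_gt(a$locus_distance, 1000L)
  expect_false(a$conserved)

  # a spanning uORF is recovered through the transcriptome alignment
  sp2 <- locus_spec("chrH", utr_exon_lengths = c(40L, 80L),
                    uorf_offset = 25L, uorf_length = 30L)
  loc2 <- generate_reference_locus(sp2, 34)
  a <- assess_uorf_conservation(loc2$uorf,
                                stats::setNames(loc2$seq, loc2$chrom),
                                loc2$annotation, "self")
  expect_identical(a$mode, "transcriptomic")
  expect_identical(a$score, 7L)
})

test_that("summaries count levels, exceptions and intersections correctly", {
  w <- conservation_weights()
  mk <- function(uorf_id, genome, score, conserved, dist = 0L) {
    data.frame(uorf_id = uorf_id, target_genome = genome, score = score,
               conserved = conserved, locus_distance = dist,
               stringsAsFactors = FALSE)
  }
  # single genome, levels {7, 4-with->1kbp-exception, 0}: one conserved
  a <- rbind(mk("u1", "g1", 7L, TRUE), mk("u2", "g1", 4L, FALSE, 2000L),
             mk("u3", "g1", 0L, FALSE))
  s <- summarize_conservation(a, w)
  expect_identical(s$subtotals$n_conserved, 1L)
  expect_identical(s$subtotals$n_exception, 1L)
  pl <- s$per_level
  expect_identical(pl$n[pl$level == 4], 0L)
  expect_identical(pl$n_exception[pl$level == 4], 1L)

  # three uORFs level 7 in both genomes: intersection "both" is 3
  b <- rbind(mk(c("u1", "u2", "u3"), "g1", 7L, TRUE),
             mk(c("u1", "u2", "u3"), "g2", 7L, TRUE),
             mk("u4", "g1", 0L, FALSE), mk("u4", "g2", 7L, TRUE))
  s <- summarize_conservation(b, w)
  expect_identical(s$intersections$n[s$intersections$genomes == "g1+g2"], 3L)
  expect_identical(s$intersections$n[s$intersections$genomes == "g2"], 1L)
  expect_identical(s$n_conserved_all, 3L)
  expect_identical(s$pct_conserved_all, 75)
})
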