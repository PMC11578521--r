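test_that("canonical filtering keeps GT/GC..AG junctions only", {
  # plant motifs explicitly: GT..AG, GC..AG, AT..AC
  seq <- paste0(strrep("C", 9), "GT", strrep("C", 8), "AG",
                strrep("C", 8), "GC", strrep("C", 8), "AG",
                strrep("C", 8), "AT", strrep("C", 8), "AC", strrep("C", 10))
  genome <- c(chrJ = seq)
  j <- data.frame(chrom = "chrJ", donor = c(10L, 30L, 50L),
                  acceptor = c(21L, 41L, 61L), strand = "+",
                  evidence = "experimental", support = 1,
                  stringsAsFactors = FALSE)
  kept <- filter_canonical(j, genome)
  expect_identical(kept$donor, c(10L, 30L))
  expect_identical(kept$donor_motif, c("GT", "GC"))
  expect_identical(kept$acceptor_motif, c("AG", "AG"))

  # the same junctions on the reverse-complemented mirror, minus strand
  L <- nchar(seq)
  mir <- c(chrJ = oracle_revcomp(seq))
  jm <- data.frame(chrom = "chrJ", donor = L - j$donor + 1L,
                   acceptor = L - j$acceptor + 1L, strand = "-",
                   evidence = "experimental", support = 1,
                   stringsAsFactors = FALSE)
  keptm <- filter_canonical(jm, mir)
  expect_identical(keptm$donor_motif, c("GT", "GC"))
  expect_identical(keptm$acceptor_motif, c("AG", "AG"))
})

test_that("linking junctions need a donor inside the uORF and an acceptor
           in the CDS", {
  loc <- toy_locus()
  refs <- reference_transcripts(loc$annotation, loc$genome)
  ref <- refs[["toy_t1"]]
  canon <- filter_canonical(loc$junction, loc$genome)
  expect_identical(nrow(find_linking_junctions(loc$uorf, canon, ref)), 1L)

  # donor past the uORF stop codon: excluded (local 71 is inside the stop)
  past <- transform(canon, donor = 71L)
  expect_identical(nrow(find_linking_junctions(loc$uorf, past, ref)), 0L)
  # donor retaining fewer than 3 bases: excluded
  early <- transform(canon, donor = 63L)
  expect_identical(nrow(find_linking_junctions(loc$uorf, early, ref)), 0L)
  # acceptor outside the CDS (3' flank): excluded
  out <- transform(canon, acceptor = 170L)
  expect_identical(nrow(find_linking_junctions(loc$uorf, out, ref)), 0L)
  # acceptor in the 5'UTR exon: excluded
  utr <- transform(canon, acceptor = 75L)
  expect_identical(nrow(find_linking_junctions(loc$uorf, utr, ref)), 0L)
})

test_that("donor scanning reports every in-bounds GT in strand
           orientation", {
  loc <- toy_locus()
  d <- scan_donor_candidates(loc$uorf, loc$genome)
  # "ATGGCAGTTTAA": GT at local 7 is the only candidate within bounds
  expect_identical(d$local_pos, 7L)
  expect_identical(d$retained, 6L)
  expect_identical(d$genomic_pos, 67L)

  u2 <- loc$uorf
  u2$nt_sequence <- "ATGGTAGTACCGTAA"       # GT at 4 and 7 (and 12, in stop zone)
  u2$blocks <- data.frame(start = 61, end = 75)
  d2 <- scan_donor_candidates(u2, loc$genome)
  expect_identical(d2$local_pos, c(4L, 7L, 12L))

  u3 <- loc$uorf
  u3$nt_sequence <- "ATGCACCACTAA"
  d3 <- scan_donor_candidates(u3, loc$genome)
  expect_identical(nrow(d3), 0L)
})

test_that("donor/acceptor pairs are scored, thresholded at the boundary,
           and deduplicated against experimental junctions", {
  loc <- toy_locus()
  refs <- reference_transcripts(loc$annotation, loc$genome)
  ref <- refs[["toy_t1"]]
  donors <- data.frame(local_pos = 7L, retained = 6L, genomic_pos = 67L)

  boundary_scorer <- function(d, a) c(donor = 0.95, acceptor = 0.85)
  got <- pair_and_score(donors, ref, loc$uorf, loc$genome,
                        scorer = boundary_scorer, threshold = 0.9)
  expect_identical(nrow(got), 2L)          # both annotated CDS acceptors
  expect_identical(got$support, c(0.9, 0.9))
  expect_identical(got$evidence, c("predicted", "predicted"))

  low_scorer <- function(d, a) c(donor = 0.5, acceptor = 0.99)
  expect_identical(nrow(pair_and_score(donors, ref, loc$uorf, loc$genome,
                                       scorer = low_scorer)), 0L)

  # a pair already seen experimentally is excluded from the predicted set
  got2 <- pair_and_score(donors, ref, loc$uorf, loc$genome,
                         scorer = boundary_scorer,
                         experimental = loc$junction)
  expect_identical(nrow(got2), 1L)
  expect_false(any(got2$acceptor == loc$junction$acceptor))
})

test_that("CDS assembly concatenates the retained uORF with the
           downstream CDS across reference introns", {
  loc <- toy_locus()
  refs <- reference_transcripts(loc$annotation, loc$genome)
  ref <- refs[["toy_t1"]]
  asm <- assemble_cds(loc$uorf, loc$junction, ref, loc$genome)
  expect_identical(asm$cds_sequence, loc$expected_cds)
  expect_identical(nchar(asm$cds_sequence), 36L)
  expect_identical(asm$uorf_part_len, 6L)
  expect_identical(asm$ref_part_len, 30L)
  # frame closure: total length is the sum of the two parts
  expect_identical(nchar(asm$cds_sequence),
                   asm$uorf_part_len + asm$ref_part_len)

  # acceptor at the first CDS exon keeps every reference intron downstream
  j1 <- transform(loc$junction, acceptor = 100L)
  asm1 <- assemble_cds(loc$uorf, j1, ref, loc$genome)
  expect_identical(asm1$cds_sequence, paste0("ATGGCA", ref$cds_seq))
  expect_identical(nrow(asm1$blocks), 3L)

  # donor right after the start codon retains exactly ATG
  j2 <- transform(loc$junction, donor = 64L)
  asm2 <- assemble_cds(loc$uorf, j2, ref, loc$genome)
  expect_match(asm2$cds_sequence, "^ATG")
  expect_identical(asm2$uorf_part_len, 3L)

  # an acceptor inside a reference intron is an error
  j3 <- transform(loc$junction, acceptor = 115L)
  expect_error(assemble_cds(loc$uorf, j3, ref, loc$genome), "link")
})

test_that("translation is literal: no initiator forcing, stops exposed", {
  expect_identical(translate_cds("ATGGCCTAA"), "MA")
  expect_identical(translate_cds("ATAGCCTAA"), "IA")   # Ile start
  expect_identical(translate_cds("ATGTAA"), "M")
  expect_identical(translate_cds("ATGTAGGCCTAA"), "M*A")
  # agreement with the literal codon-table oracle on random ORFs
  set.seed(17)
  for (i in 1:20) {
    cds <- paste0("ATG", random_test_dna(30), "TAA")
    expect_identical(translate_cds(cds), oracle_orf_protein(cds))
  }
})

test_that("the three discard rules fire independently and at the right
           boundaries", {
  v <- validate_orf(paste0("ATG", "TAG", strrep("GCA", 8), "TAA"), 30L)
  expect_false(v$passed)
  expect_identical(v$failure_reasons, "premature_stop")

  v <- validate_orf(paste0("ATG", strrep("GCA", 32), "T"), 100L)
  expect_false(v$passed)
  expect_true("frame_violation" %in% v$failure_reasons)

  v <- validate_orf(paste0("ATG", strrep("GCA", 78), "TAA"), 300L)
  expect_identical(v$cds_len_fraction, 0.8)
  expect_identical(v$failure_reasons, "too_short")

  # exactly 90% of the reference passes
  v <- validate_orf(paste0("ATG", strrep("GCA", 88), "TAA"), 300L)
  expect_identical(v$cds_len_fraction, 0.9)
  expect_true(v$passed)
})

test_that("start-codon class and reference-duplicate flags behave", {
  expect_identical(classify_start("MAPK"), "AUG")
  expect_identical(classify_start("IAPK"), "non_AUG")
  expect_error(classify_start(""), "empty")
  expect_true(detect_reference_duplicate("MAPK", "MAPK"))
  expect_false(detect_reference_duplicate("MAPK", "MAPR"))
})

test_that("deduplication keeps one construct per distinct protein, by
           support then id", {
  base <- data.frame(
    construct_id = c("uorft_1", "uorft_2", "uorft_3", "uorft_4"),
    uorf_id = c("u1", "u1", "u2", "u1"),
    protein = c("MAAA", "MAAA", "MAAA", "MCCC"),
    reference_transcript_id = "t1",
    support = c(10, 200, 50, 5), stringsAsFactors = FALSE)
  out <- deduplicate_constructs(base)
  expect_identical(sort(out$construct_id), c("uorft_2", "uorft_3", "uorft_4"))
  # the kept duplicate is the higher-support one
  expect_identical(out$support[out$uorf_id == "u1" & out$protein == "MAAA"],
                   200)
})

test_that("building on a locus and its reverse-complement mirror yields
           identical proteins", {
  plus <- toy_locus("+")
  minus <- toy_locus("-")
  for (loc in list(plus, minus)) {
    cons <- build_constructs(list(loc$uorf), loc$genome, loc$annotation,
                             loc$junction)
    expect_identical(nrow(cons[cons$evidence == "experimental", ]), 1L)
    exp_row <- cons[cons$evidence == "experimental", ]
    expect_identical(exp_row$cds_sequence, plus$expected_cds)
    expect_identical(exp_row$protein, oracle_orf_protein(plus$expected_cds))
    expect_true(exp_row$valid)
    expect_true(all(cons$donor_motif[cons$valid] %in% c("GT", "GC")))
  }

  # generator loci: mirror the whole locus and rebuild
  sp <- locus_spec("chrK", plant_donor = "gt")
  loc <- generate_reference_locus(sp, 55)
  genome <- stats::setNames(loc$seq, loc$chrom)
  jn <- generate_junction_evidence(loc, TRUE, coverage = 50,
                                   noise_junctions = 0, seed = 1)
  c_fwd <- build_constructs(list(loc$uorf), genome, loc$annotation, jn)

  L <- nchar(loc$seq)
  flip <- function(x) L - x + 1L
  ann <- loc$annotation
  tmp <- flip(ann$end); ann$end <- flip(ann$start); ann$start <- tmp
  ann$strand <- "-"
  u <- loc$uorf
  b <- data.frame(start = flip(u$blocks$end), end = flip(u$blocks$start))
  u$blocks <- b[order(b$start), , drop = FALSE]
  u$start <- min(u$blocks$start); u$end <- max(u$blocks$end); u$strand <- "-"
  jm <- transform(jn, donor = flip(donor), acceptor = flip(acceptor),
                  strand = "-")
  c_rev <- build_constructs(list(u), c(chrK = oracle_revcomp(loc$seq)),
                            ann, jm)
  expect_identical(c_fwd$protein, c_rev$protein)
  expect_identical(c_fwd$valid, c_rev$valid)
})
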