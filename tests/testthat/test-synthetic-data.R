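test_that("reference locus geometry matches the spec that requested it", {
  sp <- locus_spec("chrA", utr_exon_lengths = 120L, uorf_offset = 10L,
                   uorf_length = 30L)
  loc <- generate_reference_locus(sp, 42)
  gene_start <- loc$annotation$start[loc$annotation$type == "gene"]
  # uORF occupies transcript offsets 10..39, i.e. gene_start+10 .. +39
  expect_identical(loc$uorf$start, gene_start + 10L)
  expect_identical(loc$uorf$end, gene_start + 39L)
  expect_identical(nrow(loc$uorf$blocks), 1L)
  expect_match(loc$uorf$nt_sequence, "^ATG")
  expect_true(substr(loc$uorf$nt_sequence, 28, 30) %in% c("TAA", "TAG", "TGA"))
  # annotation carries the full feature hierarchy
  expect_setequal(unique(loc$annotation$type),
                  c("gene", "mRNA", "exon", "five_prime_UTR", "CDS"))
})

test_that("a uORF spanning two UTR exons is genomically split but
           contiguous on the transcript", {
  sp <- locus_spec("chrB", utr_exon_lengths = c(40L, 80L), uorf_offset = 25L,
                   uorf_length = 30L)
  loc <- generate_reference_locus(sp, 7)
  expect_identical(nrow(loc$uorf$blocks), 2L)
  widths <- loc$uorf$blocks$end - loc$uorf$blocks$start + 1L
  expect_identical(sum(widths), 30L)
  # the two blocks are separated by the first intron
  expect_gt(loc$uorf$blocks$start[2], loc$uorf$blocks$end[1] + 1L)
  # spliced sequence equals the catalogued sequence
  spliced <- paste0(substr(loc$seq, loc$uorf$blocks$start[1],
                           loc$uorf$blocks$end[1]),
                    substr(loc$seq, loc$uorf$blocks$start[2],
                           loc$uorf$blocks$end[2]))
  expect_identical(spliced, loc$uorf$nt_sequence)
})

test_that("locus generation is deterministic and validates its spec", {
  sp <- locus_spec("chrC", plant_donor = "strong")
  expect_identical(generate_reference_locus(sp, 5),
                   generate_reference_locus(sp, 5))
  expect_error(locus_spec("x", utr_exon_lengths = 30L, uorf_offset = 10L,
                          uorf_length = 300L), "extends past")
  expect_error(locus_spec("x", utr_exon_lengths = 30L, uorf_offset = 29L,
                          uorf_length = 30L), "start codon")
  expect_error(locus_spec("x", uorf_length = 31L), "multiple of 3")
  expect_error(locus_spec("x", cds_exon_lengths = c(10L, 10L)),
               "multiple of 3")
})

test_that("mutation plans produce the advertised genome differences", {
  sp <- locus_spec("chrD", plant_donor = "gt")
  loc <- generate_reference_locus(sp, 11)

  ident <- derive_individual_genome(loc, mutation_plan("identical"))
  expect_identical(ident$genome[[1]], loc$seq)
  expect_identical(ident$truth$expected_level, 7L)

  syn <- derive_individual_genome(loc, mutation_plan("synonymous_sub"))
  mm <- sum(utf8ToInt(syn$genome[[1]]) != utf8ToInt(loc$seq))
  expect_identical(mm, 1L)
  mutated_uorf <- substr(syn$genome[[1]], loc$uorf$start, loc$uorf$end)
  if (loc$uorf$strand == "-") mutated_uorf <- oracle_revcomp(mutated_uorf)
  expect_false(identical(mutated_uorf, loc$uorf$nt_sequence))
  expect_identical(oracle_orf_protein(mutated_uorf),
                   oracle_orf_protein(loc$uorf$nt_sequence))

  nsyn <- derive_individual_genome(loc, mutation_plan("nonsynonymous_sub"))
  mutated_uorf <- substr(nsyn$genome[[1]], loc$uorf$start, loc$uorf$end)
  expect_false(identical(oracle_orf_protein(mutated_uorf),
                         oracle_orf_protein(loc$uorf$nt_sequence)))
  expect_identical(nsyn$truth$expected_level, 3L)

  rel <- derive_individual_genome(loc,
                                  mutation_plan("relocate_gt_1kbp",
                                                list(gap = 1500L)))
  hit <- oracle_search(loc$uorf$nt_sequence, rel$genome)
  expect_identical(nrow(hit), 1L)
  gene_end <- loc$annotation$end[loc$annotation$type == "gene"]
  gene_start <- loc$annotation$start[loc$annotation$type == "gene"]
  gap <- max(hit$start - gene_end - 1, gene_start - hit$end - 1)
  expect_gt(gap, 1000L)
  expect_false(rel$truth$expected_conserved)

  dutr <- derive_individual_genome(loc, mutation_plan("delete_utr"))
  expect_identical(dutr$genome[[1]], loc$seq)      # sequence untouched
  expect_false(any(dutr$annotation$type == "five_prime_UTR"))
  expect_identical(dutr$truth$expected_level, 5L)

  dloc <- derive_individual_genome(loc, mutation_plan("delete_locus"))
  expect_null(oracle_search(loc$uorf$nt_sequence, dloc$genome, k = 3))
  expect_identical(nrow(dloc$annotation), 0L)
})

test_that("delete_utr is rejected for spliced uORFs and indels leave no
           recoverable near-match", {
  sp <- locus_spec("chrE", utr_exon_lengths = c(40L, 80L), uorf_offset = 25L,
                   uorf_length = 30L)
  loc <- generate_reference_locus(sp, 13)
  expect_error(derive_individual_genome(loc, mutation_plan("delete_utr")),
               "incompatible")
  ind <- derive_individual_genome(loc, mutation_plan("indel"))
  expect_identical(nchar(ind$genome[[1]]), nchar(loc$seq) - 1L)
  expect_null(oracle_search(loc$uorf$nt_sequence, ind$genome, k = 3))
})

test_that("junction evidence links (or does not link) as requested", {
  sp <- locus_spec("chrF", plant_donor = "gt")
  loc <- generate_reference_locus(sp, 21)
  refs <- reference_transcripts(loc$annotation,
                                stats::setNames(loc$seq, loc$chrom))
  ref <- refs[[1]]
  genome <- stats::setNames(loc$seq, loc$chrom)

  with_link <- generate_junction_evidence(loc, place_linking = TRUE,
                                          coverage = 200, seed = 1)
  canon <- filter_canonical(with_link, genome)
  linking <- find_linking_junctions(loc$uorf, canon, ref)
  expect_gte(nrow(linking), 1L)
  expect_identical(linking$support[1], 200)

  no_link <- generate_junction_evidence(loc, place_linking = FALSE,
                                        noise_junctions = 5, seed = 2)
  linking <- find_linking_junctions(loc$uorf,
                                    filter_canonical(no_link, genome), ref)
  expect_identical(nrow(linking), 0L)
})

test_that("the mock splice scorer is deterministic and separable", {
  strong <- mock_splice_scorer("GTAAGGGC", "CCCTTTAG")
  expect_gte(strong[["donor"]], 0.95)
  expect_gte(strong[["acceptor"]], 0.95)
  expect_gte(mean(strong), 0.9)
  weak <- mock_splice_scorer("GTCCCCCC", "AAAAAAAG")
  expect_lte(weak[["donor"]], 0.5)
  expect_lt(mean(weak), 0.9)
  expect_identical(mock_splice_scorer("GTAAGGGC", "CCCTTTAG"), strong)
  expect_error(mock_splice_scorer("GTAAG", "CCCTTTAG"), "window")
})

test_that("mock confidence profiles hit the requested mean exactly", {
  prof <- mock_plddt_profile(strrep("A", 10), 70)
  expect_identical(length(prof$per_residue), 10L)
  expect_lt(abs(prof$mean - 70), 1e-9)
  expect_true(all(prof$per_residue >= 0 & prof$per_residue <= 100))
  # planted delta between two profiles is recovered on comparison
  novel <- mock_plddt_profile(strrep("A", 50), 80)
  ref <- mock_plddt_profile(strrep("A", 60), 77.04)
  cmp <- compare_structures(novel, ref)
  expect_identical(cmp$delta, 2.96)
  expect_identical(mock_plddt_profile(strrep("K", 25), 63.2),
                   mock_plddt_profile(strrep("K", 25), 63.2))
  expect_error(mock_plddt_profile("", 70), "empty")
})

test_that("naive_align matches a brute-force search on planted and random
           genomes", {
  set.seed(202)
  genome <- c(chr1 = random_test_dna(6000))
  query <- substr(genome[[1]], 5000, 5029)
  hit <- naive_align(query, genome)
  expect_identical(hit$start, 5000L)
  expect_identical(hit$n_mismatch, 0L)

  rc <- c(chr1 = oracle_revcomp(genome[[1]]))
  hit_rc <- naive_align(query, rc)
  expect_identical(hit_rc$strand, "-")

  expect_identical(nrow(naive_align(strrep("ACGTT", 8), genome)), 0L)

  # property: agreement with the brute-force oracle, exact and near-exact
  for (i in 1:15) {
    g <- c(chrX = random_test_dna(400))
    q <- substr(g[[1]], 100, 119)
    if (i %% 3 == 0) q <- oracle_revcomp(q)
    if (i %% 2 == 0) {
      p <- sample(20, 1)
      q <- paste0(substr(q, 1, p - 1),
                  chartr("ACGT", "CGTA", substr(q, p, p)),
                  substr(q, p + 1, 20))
    }
    mine <- naive_align(q, g, max_mismatch = 2)
    ref <- oracle_search(q, g, k = 2)
    if (is.null(ref)) {
      expect_identical(nrow(mine), 0L)
    } else {
      expect_identical(nrow(mine), nrow(ref))
      expect_identical(mine$start, ref$start)
      expect_identical(mine$n_mismatch, ref$n_mismatch)
      expect_identical(mine$strand, ref$strand)
    }
  }
})

test_that("cohort generation is deterministic and labels are internally
           consistent", {
  c1 <- generate_cohort(n_loci = 6, n_genomes = 2, seed = 9)
  c2 <- generate_cohort(n_loci = 6, n_genomes = 2, seed = 9)
  expect_identical(c1$reference, c2$reference)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$junctions, c2$junctions)
  # linking-junction truth agrees with the planted evidence source
  expect_identical(c1$truth$uorf$has_linking_junction,
                   c1$truth$uorf$evidence_source != "none")
  # every expected level is one of the derivable outcomes
  expect_true(all(c1$truth$conservation$expected_level %in%
                    c(0L, 3L, 5L, 7L)))
})
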