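## Scenario design for the synthetic cohort. Each locus draws an
## architecture (single-exon 5'UTR, uORF spanning two UTR exons, or uORF
## overlapping the CDS start), a junction-evidence source, an ORF-validity
## outcome, a structure-confidence delta class, and one mutation plan per
## individual genome. Every downstream expectation is derived from these
## draws at generation time, never from pipeline output.

PLAN_KINDS <- c("identical", "synonymous_sub", "nonsynonymous_sub",
                "indel", "relocate_gt_1kbp", "delete_utr", "delete_locus")
PLAN_WEIGHTS <- c(0.50, 0.14, 0.10, 0.05, 0.08, 0.09, 0.04)

## Reference protein mean and the planted novel-mean offsets per class.
REF_PLDDT_MEAN <- 75
DELTA_BY_CLASS <- c(higher = 2.96, similar = 0.5, similar_boundary = -1.0,
                    lower = -3.41)

draw_scenarios <- function(n_loci, n_genomes, seed) {
  with_seed(seed, {
    arch <- sample(c("single", "spanning", "overlap"), n_loci, TRUE,
                   prob = c(0.60, 0.25, 0.15))
    strand <- sample(c("+", "-"), n_loci, TRUE)
    evidence <- sample(c("none", "experimental", "predicted", "both"), n_loci, TRUE,
                       prob = c(0.25, 0.30, 0.25, 0.20))
    validity <- ifelse(evidence == "none", "none",
                       sample(c("valid", "frame", "short"), n_loci, TRUE,
                              prob = c(0.76, 0.12, 0.12)))
    # frame/short outcomes are built from experimental junction geometry
    validity[validity != "valid" & evidence %in% c("predicted", "both")] <- "valid"
    delta_class <- ifelse(validity == "valid",
                          sample(names(DELTA_BY_CLASS), n_loci, TRUE,
                                 prob = c(0.38, 0.22, 0.15, 0.25)),
                          "skipped")
    long_protein <- rep(FALSE, n_loci)
    long_idx <- which(evidence == "experimental" & validity == "valid" &
                        arch == "single")
    if (length(long_idx) >= 2L) long_protein[long_idx[1:2]] <- TRUE
    coverage <- ifelse(delta_class %in% c("higher", "similar",
                                          "similar_boundary"),
                       sample(200:300, n_loci, TRUE),
                       sample(40:80, n_loci, TRUE))
    plans <- matrix(sample(PLAN_KINDS, n_loci * n_genomes, TRUE,
                           prob = PLAN_WEIGHTS),
                    nrow = n_loci)
    data.frame(arch = arch, strand = strand, evidence = evidence,
               validity = validity, delta_class = delta_class,
               long_protein = long_protein, coverage = coverage,
               utr1 = sample(90:140, n_loci, TRUE),
               utr2 = sample(60:90, n_loci, TRUE),
               uorf_len = 3L * sample(10:14, n_loci, TRUE),
               locus_seed = sample.int(2^30, n_loci),
               junction_seed = sample.int(2^30, n_loci),
               plans = I(plans), stringsAsFactors = FALSE)
  })
}

scenario_spec <- function(sc, locus_id) {
  len <- sc$uorf_len
  if (sc$arch == "overlap") len <- max(len, 24L)
  plant <- switch(sc$evidence,
                  none = "none",
                  experimental = "gt",
                  predicted = "strong", both = "strong")
  if (sc$evidence == "none") plant <- "none"
  donor_retained <- if (sc$validity == "frame") len - 11L
                    else len - (if (sc$arch == "overlap") 15L else 12L)
  cds <- if (sc$long_protein) c(3000L, 3009L)
         else if (sc$validity == "short") c(150L, 30L)
         else if (sc$evidence == "both") c(9L, 171L)  # both junctions valid
         else c(60L, 120L)
  if (sc$arch == "spanning") {
    utr_lens <- c(sc$utr1, sc$utr2)
    offset <- sc$utr1 - 12L                  # uORF crosses the UTR intron
  } else if (sc$arch == "overlap") {
    utr_lens <- sc$utr1
    offset <- sc$utr1 + 4L - len             # fixed 4-base CDS overlap
  } else {
    utr_lens <- sc$utr1
    offset <- 10L
  }
  locus_spec(locus_id, gene_name = paste0("GENE", sub("chrL", "", locus_id)),
             utr_exon_lengths = utr_lens, uorf_offset = offset,
             uorf_length = len, cds_exon_lengths = cds,
             intron_lengths = c(100L, 80L), strand = sc$strand,
             plant_donor = plant, donor_retained = donor_retained)
}

#' Generate a full synthetic cohort with ground-truth labels
#'
#' Builds `n_loci` independent loci (one synthetic chromosome each), a uORF
#' catalogue, junction evidence (linking and noise), `n_genomes` individual
#' genomes derived from per-locus mutation plans, planted per-protein
#' structure-confidence targets, and the truth tables every downstream
#' stage is checked against. Deterministic under `(n_loci, n_genomes,
#' seed)`.
#'
#' @param n_loci Number of loci (default 100).
#' @param n_genomes Number of individual target genomes (default 4, named
#'   `G1..Gn`).
#' @param seed Integer seed.
#' @param noise_junctions Non-linking junctions per locus (default 2).
#' @return A list of class `uorf_cohort`: `loci`, `reference`
#'   (`genome`, `annotation`), `uorfs`, `junctions`, `targets`,
#'   `plddt_targets`, `plddt_backend`, `truth` (`conservation`, `uorf`),
#'   `scenarios`.
#' @export
generate_cohort <- function(n_loci = 100L, n_genomes = 4L, seed = 1L,
                            noise_junctions = 2L) {
  genomes <- paste0("G", seq_len(n_genomes))
  sc <- draw_scenarios(n_loci, n_genomes, seed)

  loci <- vector("list", n_loci)
  junctions <- list()
  plddt_rows <- list()
  truth_uorf <- list()
  for (i in seq_len(n_loci)) {
    s <- sc[i, ]
    spec <- scenario_spec(s, sprintf("chrL%03d", i))
    loc <- generate_reference_locus(spec, s$locus_seed)
    loci[[i]] <- loc
    place <- s$evidence %in% c("experimental", "both")
    acceptor_exon <- if (s$validity == "short") 2L
                     else if (s$evidence == "both") 2L else 1L
    junctions[[i]] <- generate_junction_evidence(
      loc, place_linking = place, coverage = s$coverage,
      noise_junctions = noise_junctions, seed = s$junction_seed,
      acceptor_cds_exon = acceptor_exon)
    tid <- loc$layout$transcript_id
    delta <- if (s$delta_class %in% names(DELTA_BY_CLASS)) {
      DELTA_BY_CLASS[[s$delta_class]]
    } else 0
    plddt_rows[[i]] <- data.frame(
      protein_id = c(loc$uorf$uorf_id, tid),
      target_mean = c(REF_PLDDT_MEAN + delta, REF_PLDDT_MEAN),
      stringsAsFactors = FALSE)
    expected_class <- if (s$long_protein) "skipped"
                      else switch(s$delta_class,
                                  higher = "higher", lower = "lower",
                                  similar = , similar_boundary = "similar",
                                  "skipped")
    truth_uorf[[i]] <- data.frame(
      uorf_id = loc$uorf$uorf_id, evidence_source = s$evidence,
      has_linking_junction = s$evidence != "none",
      expected_valid_orf = s$evidence != "none" && s$validity == "valid",
      expected_delta_class = expected_class, stringsAsFactors = FALSE)
  }

  targets <- list()
  truth_cons <- list()
  for (g in seq_len(n_genomes)) {
    seqs <- character(n_loci)
    anns <- vector("list", n_loci)
    for (i in seq_len(n_loci)) {
      kind <- sc$plans[i, g]
      # delete_utr is only defined for single-block uORFs; spliced loci
      # draw a non-synonymous substitution instead
      if (kind == "delete_utr" && nrow(loci[[i]]$uorf$blocks) > 1L) {
        kind <- "nonsynonymous_sub"
      }
      plan <- mutation_plan(kind)
      der <- derive_individual_genome(loci[[i]], plan)
      seqs[i] <- der$genome[[1]]
      anns[[i]] <- der$annotation
      der$truth$target_genome <- genomes[g]
      truth_cons[[length(truth_cons) + 1L]] <- der$truth
    }
    names(seqs) <- vapply(loci, `[[`, "", "chrom")
    targets[[genomes[g]]] <- list(genome = seqs,
                                  annotation = do.call(rbind, anns))
  }

  plddt_targets <- do.call(rbind, plddt_rows)
  structure(list(
    seed = seed, n_loci = n_loci, loci = loci,
    reference = list(
      genome = stats::setNames(vapply(loci, `[[`, "", "seq"),
                               vapply(loci, `[[`, "", "chrom")),
      annotation = do.call(rbind, lapply(loci, `[[`, "annotation"))),
    uorfs = lapply(loci, `[[`, "uorf"),
    junctions = do.call(rbind, junctions),
    targets = targets,
    plddt_targets = plddt_targets,
    plddt_backend = mock_plddt_backend(plddt_targets),
    truth = list(conservation = do.call(rbind, truth_cons),
                 uorf = do.call(rbind, truth_uorf)),
    scenarios = sc
  ), class = "uorf_cohort")
}
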