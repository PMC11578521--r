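#' Conservation scoring weights and thresholds
#'
#' The three conservation criteria and their weights: a full-length,
#' 100%-identical sequence match (weight 4, with a protein-level fallback
#' for near-identical hits), containment in the 5'UTR of a protein-coding
#' transcript (weight 2), and a gene-locus match against the expected
#' downstream gene (weight 1). A uORF scoring above 3 counts as conserved
#' in a genome, unless its best sequence match lies more than
#' `max_locus_distance` (1 kbp) away from the expected gene. Assessments at
#' the no-locus levels 0, 4 and 6 whose alignment sits within
#' `curation_distance` (100 bp) of the expected gene are bumped by the
#' locus weight during curation.
#'
#' @param w_sequence,w_utr,w_locus Criterion weights (defaults 4, 2, 1).
#' @param conserved_min_score Minimum conserved score (default 4,
#'   i.e. "> 3").
#' @param max_locus_distance Distance exception bound in bp (default 1000).
#' @param curation_distance Curation bump bound in bp (default 100,
#'   strict).
#' @return A list of class `conservation_weights`.
#' @export
conservation_weights <- function(w_sequence = 4L, w_utr = 2L, w_locus = 1L,
                                 conserved_min_score = 4L,
                                 max_locus_distance = 1000L,
                                 curation_distance = 100L) {
  stopifnot(w_sequence > 0L, w_utr > 0L, w_locus > 0L,
            conserved_min_score <= w_sequence + w_utr + w_locus)
  structure(list(w_sequence = as.integer(w_sequence),
                 w_utr = as.integer(w_utr), w_locus = as.integer(w_locus),
                 conserved_min_score = as.integer(conserved_min_score),
                 max_locus_distance = as.integer(max_locus_distance),
                 curation_distance = as.integer(curation_distance)),
            class = "conservation_weights")
}

#' Protein-level fallback for a failed nucleotide match
#'
#' When a query ORF has no exact nucleotide match, all translations of the
#' aligned target span are computed (three frames on both strands, standard
#' genetic code) and compared with the protein encoded by the query ORF.
#' The match succeeds iff any of the six translations equals the query
#' protein exactly (terminal stops stripped on both sides).
#'
#' @param query_nt Query ORF sequence; length must be a multiple of 3.
#' @param target_nt Aligned target span.
#' @return `TRUE` iff some translation of the target equals the query
#'   protein.
#' @export
protein_fallback_match <- function(query_nt, target_nt) {
  stopifnot(nchar(query_nt) %% 3L == 0L)
  qp <- orf_protein(query_nt)
  if (nchar(qp) == 0L) return(FALSE)
  for (s in c(target_nt, dna_revcomp(target_nt))) {
    for (f in 0:2) {
      if (nchar(s) - f < 3L) next
      tp <- sub("\\*$", "", dna_translate(substr(s, 1L + f, nchar(s))))
      if (identical(tp, qp)) return(TRUE)
    }
  }
  FALSE
}

#' Sequence-match criterion for one alignment hit
#'
#' A complete sequence-level match means the strand-oriented target span is
#' full-length and 100% identical to the uORF sequence. A hit that fails
#' that test is deferred to the protein-level fallback on the same span.
#'
#' @param uorf A `uorf_record` (needs `nt_sequence`).
#' @param target_span Target span sequence, already read in the hit's
#'   strand orientation and trimmed to the aligned interval.
#' @return A list with `match` (flag) and `kind` (`"nucleotide"`,
#'   `"protein_fallback"`, or `"none"`).
#' @export
assess_sequence_match <- function(uorf, target_span) {
  if (identical(target_span, uorf$nt_sequence)) {
    list(match = TRUE, kind = "nucleotide")
  } else if (protein_fallback_match(uorf$nt_sequence, target_span)) {
    list(match = TRUE, kind = "protein_fallback")
  } else {
    list(match = FALSE, kind = "none")
  }
}

#' 5'UTR-containment criterion for one alignment footprint
#'
#' The footprint must be exonic in at least one protein-coding transcript,
#' with its 5'-most base (in the transcript's orientation) inside that
#' transcript's 5'UTR. The downstream part may extend into the CDS, so
#' uORFs overlapping the CDS start still count as contained as long as
#' they begin in the 5'UTR.
#'
#' @param blocks Genomic footprint of the hit (data.frame `start`, `end`).
#' @param annotation Annotation data.frame for the target genome.
#' @param chrom Chromosome of the footprint.
#' @return `TRUE` iff contained for at least one annotated transcript.
#' @export
assess_utr_containment <- function(blocks, annotation, chrom) {
  if (nrow(blocks) == 0L) return(FALSE)
  ann <- annotation[annotation$seqid == chrom, , drop = FALSE]
  mrna <- ann_of_type(ann, "mRNA")
  for (i in seq_len(nrow(mrna))) {
    tid <- mrna$transcript_id[i]
    strand <- mrna$strand[i]
    cds <- tx_feature_blocks(ann, tid, "CDS")
    if (nrow(cds) == 0L) next          # not protein-coding
    exons <- tx_feature_blocks(ann, tid, "exon")
    utr5 <- tx_utr5_blocks(ann, tid, strand)
    start5 <- if (strand == "+") min(blocks$start) else max(blocks$end)
    if (point_in_blocks(start5, utr5) && blocks_contained_in(blocks, exons)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Gene-locus criterion for one alignment footprint
#'
#' Checks whether the gene overlapping (or, failing that, nearest to) the
#' footprint carries the expected downstream-gene name, optionally through
#' a synonym table. The distance to the expected gene's span is reported
#' alongside: 0 when overlapping, the bp gap otherwise, `NA` when the
#' expected gene is absent from the target annotation (recorded for the
#' missing-genes report).
#'
#' @param blocks Genomic footprint (data.frame `start`, `end`).
#' @param annotation Annotation data.frame for the target genome.
#' @param chrom Chromosome of the footprint.
#' @param expected_gene Gene name recorded in the uORF catalogue.
#' @param synonyms Optional named character vector mapping annotation gene
#'   names to catalogue names.
#' @return List with `match` (flag) and `distance` (bp or `NA`).
#' @export
assess_locus_match <- function(blocks, annotation, chrom, expected_gene,
                               synonyms = NULL) {
  if (nrow(blocks) == 0L) return(list(match = FALSE, distance = NA_integer_))
  genes <- ann_of_type(annotation, "gene")
  canonical <- function(nm) {
    if (!is.null(synonyms) && nm %in% names(synonyms)) synonyms[[nm]] else nm
  }
  gnames <- vapply(genes$gene_name, canonical, "")
  span_s <- min(blocks$start)
  span_e <- max(blocks$end)
  here <- genes$seqid == chrom
  gaps <- ifelse(here,
                 mapply(function(s, e) interval_gap(span_s, span_e, s, e),
                        genes$start, genes$end),
                 NA_integer_)
  expected_idx <- which(here & gnames == expected_gene)
  if (length(expected_idx) == 0L) {
    # expected gene missing from this chromosome's annotation
    if (!any(gnames == expected_gene)) {
      return(list(match = FALSE, distance = NA_integer_))
    }
    return(list(match = FALSE, distance = NA_integer_))
  }
  dist_expected <- as.integer(min(gaps[expected_idx]))
  overlapping <- which(here & gaps == 0L)
  if (length(overlapping) > 0L) {
    return(list(match = expected_gene %in% gnames[overlapping],
                distance = if (expected_gene %in% gnames[overlapping]) 0L
                           else dist_expected))
  }
  nearest <- which(here)[which.min(gaps[here])]
  list(match = gnames[nearest] == expected_gene, distance = dist_expected)
}

#' Score one set of criterion flags
#'
#' The conservation score is the weighted sum of the three criterion flags.
#' The verdict is conserved iff the score reaches the minimum and the
#' best-match distance does not exceed the 1 kbp exception bound.
#'
#' @param sequence_match,utr_containment,locus_match Criterion flags.
#' @param weights A [conservation_weights()].
#' @param locus_distance Distance to the expected gene (bp or `NA`).
#' @param sequence_match_kind `"nucleotide"`, `"protein_fallback"` or
#'   `"none"`.
#' @return One-row data.frame with `sequence_match`, `sequence_match_kind`,
#'   `utr_containment`, `locus_match`, `score`, `locus_distance`,
#'   `conserved`, `curated`.
#' @export
score_assessment <- function(sequence_match, utr_containment, locus_match,
                             weights = conservation_weights(),
                             locus_distance = NA_integer_,
                             sequence_match_kind = if (sequence_match)
                               "nucleotide" else "none") {
  score <- weights$w_sequence * sequence_match +
    weights$w_utr * utr_containment + weights$w_locus * locus_match
  data.frame(
    sequence_match = sequence_match, sequence_match_kind = sequence_match_kind,
    utr_containment = utr_containment, locus_match = locus_match,
    score = as.integer(score),
    locus_distance = as.integer(locus_distance),
    conserved = score >= weights$conserved_min_score &&
      (is.na(locus_distance) || locus_distance <= weights$max_locus_distance),
    curated = FALSE, stringsAsFactors = FALSE
  )
}

#' Reconcile genomic and transcriptomic assessments
#'
#' When the genomic and transcriptomic alignments disagree, the assessment
#' with the maximum conservation level wins; on a tie the genomic record is
#' kept (its coordinates need no projection). Either argument may be `NULL`.
#'
#' @param genomic,transcriptomic One-row assessment data.frames (or `NULL`).
#' @return The winning assessment.
#' @export
reconcile_assessments <- function(genomic, transcriptomic) {
  if (is.null(genomic)) return(transcriptomic)
  if (is.null(transcriptomic)) return(genomic)
  if (transcriptomic$score > genomic$score) transcriptomic else genomic
}

#' Curation bump for near-miss locus matches
#'
#' Assessments at the no-locus score levels (0, the sequence weight alone,
#' or sequence + UTR; 0/4/6 with default weights) whose alignment lies
#' strictly within the curation distance (100 bp) of the expected gene gain
#' the locus weight and are flagged curated. Curation never decreases a
#' score.
#'
#' @param assessment One-row assessment data.frame.
#' @param weights A [conservation_weights()].
#' @return The (possibly bumped) assessment.
#' @export
curate_assessment <- function(assessment, weights = conservation_weights()) {
  bump_levels <- c(0L, weights$w_sequence, weights$w_sequence + weights$w_utr)
  if (assessment$score %in% bump_levels &&
      !is.na(assessment$locus_distance) &&
      assessment$locus_distance < weights$curation_distance &&
      !assessment$locus_match) {
    assessment$locus_match <- TRUE
    assessment$score <- assessment$score + weights$w_locus
    assessment$curated <- TRUE
    assessment$conserved <-
      assessment$score >= weights$conserved_min_score &&
      (is.na(assessment$locus_distance) ||
         assessment$locus_distance <= weights$max_locus_distance)
  }
  assessment
}

empty_assessment <- function(weights) {
  a <- score_assessment(FALSE, FALSE, FALSE, weights)
  a$mode <- NA_character_
  a$aln_chrom <- NA_character_
  a$aln_start <- NA_integer_
  a$aln_end <- NA_integer_
  a$aln_strand <- NA_character_
  a$n_mismatch <- NA_integer_
  a
}

assess_footprint <- function(uorf, blocks, target_span, annotation, chrom,
                             weights, synonyms = NULL) {
  sm <- assess_sequence_match(uorf, target_span)
  utr <- assess_utr_containment(blocks, annotation, chrom)
  loc <- assess_locus_match(blocks, annotation, chrom, uorf$gene_name,
                            synonyms)
  score_assessment(sm$match, utr, loc$match, weights,
                   locus_distance = loc$distance,
                   sequence_match_kind = sm$kind)
}

## Multiple hits: retain the one maximising (sequence_match, score,
## smallest locus distance).
best_assessment <- function(assessments) {
  if (length(assessments) == 0L) return(NULL)
  df <- do.call(rbind, assessments)
  dist_key <- ifelse(is.na(df$locus_distance), .Machine$integer.max,
                     df$locus_distance)
  df[order(-df$sequence_match, -df$score, dist_key)[1], , drop = FALSE]
}

#' Assess the conservation of one uORF in one target genome
#'
#' Aligns the uORF both to the target genome and to its annotated
#' transcripts (the transcriptome alignment handles uORFs spanning two
#' 5'UTR exons, whose genomic footprint is discontiguous), scores every hit
#' on the three weighted criteria, keeps the best hit per mode, reconciles
#' the two modes by maximum level, then applies the curation bump and the
#' >1 kbp distance exception.
#'
#' @param uorf A `uorf_record`.
#' @param genome Named character vector of target chromosome sequences.
#' @param annotation Target annotation data.frame.
#' @param target_genome Label recorded on the assessment.
#' @param weights A [conservation_weights()].
#' @param max_mismatch Hamming budget for near-exact alignment (default 3).
#' @param synonyms Optional gene-name synonym table (see
#'   [assess_locus_match()]).
#' @param index Optional precomputed [build_target_index()] for this
#'   target (built on the fly when `NULL`).
#' @param alignments Optional precomputed genomic alignment records for
#'   this uORF (e.g. from [read_alignments_paf()], filtered to this
#'   query): a data.frame with `chrom`, `start`, `end`, `strand`,
#'   `n_mismatch`. When supplied they replace the built-in genomic
#'   alignment; the transcriptomic pass still runs.
#' @return One-row assessment data.frame (see [score_assessment()], plus
#'   `uorf_id`, `target_genome`, `mode`, and alignment coordinates).
#' @export
assess_uorf_conservation <- function(uorf, genome, annotation,
                                     target_genome = "target",
                                     weights = conservation_weights(),
                                     max_mismatch = 3L, synonyms = NULL,
                                     index = NULL, alignments = NULL) {
  if (is.null(index)) index <- build_target_index(genome, annotation)
  genomic <- best_assessment(genomic_assessments(
    uorf, index, annotation, weights, max_mismatch, synonyms,
    hits = alignments))
  transcriptomic <- best_assessment(transcriptomic_assessments(
    uorf, index, annotation, weights, max_mismatch, synonyms))
  final <- reconcile_assessments(genomic, transcriptomic)
  if (is.null(final)) final <- empty_assessment(weights)
  final <- curate_assessment(final, weights)
  cbind(data.frame(uorf_id = uorf$uorf_id, target_genome = target_genome,
                   stringsAsFactors = FALSE),
        final)
}

genomic_assessments <- function(uorf, index, annotation, weights,
                                max_mismatch, synonyms, hits = NULL) {
  if (is.null(hits)) {
    hits <- naive_align(uorf$nt_sequence, index$dss, max_mismatch)
  }
  # only full-length spans can satisfy the sequence criterion; partial
  # records (soft-clipped external hits) are dropped here
  hits <- hits[hits$end - hits$start + 1L == nchar(uorf$nt_sequence), ,
               drop = FALSE]
  lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    span <- subseq_str(index$genome[[h$chrom]], h$start, h$end)
    if (h$strand == "-") span <- dna_revcomp(span)
    a <- assess_footprint(uorf, blocks_df(h$start, h$end), span,
                          annotation, h$chrom, weights, synonyms)
    a$mode <- "genomic"
    a$aln_chrom <- h$chrom
    a$aln_start <- h$start
    a$aln_end <- h$end
    a$aln_strand <- h$strand
    a$n_mismatch <- h$n_mismatch
    a
  })
}

transcriptomic_assessments <- function(uorf, index, annotation, weights,
                                       max_mismatch, synonyms) {
  if (length(index$tx) == 0L) return(list())
  hits <- naive_align(uorf$nt_sequence, index$tx_dss, max_mismatch)
  out <- list()
  for (j in seq_len(nrow(hits))) {
    h <- hits[j, ]
    tx <- index$tx[[h$chrom]]          # "chrom" of a transcriptomic hit
    span <- substr(tx$seq, h$start, h$end)
    if (h$strand == "-") span <- dna_revcomp(span)
    blocks <- tx_to_genomic_blocks(tx$exons, tx$strand, h$start, h$end)
    a <- assess_footprint(uorf, blocks, span, annotation, tx$chrom, weights,
                          synonyms)
    a$mode <- "transcriptomic"
    a$aln_chrom <- tx$chrom
    a$aln_start <- min(blocks$start)
    a$aln_end <- max(blocks$end)
    a$aln_strand <- if (h$strand == "+") tx$strand else flip_strand(tx$strand)
    a$n_mismatch <- h$n_mismatch
    out[[length(out) + 1L]] <- a
  }
  out
}

flip_strand <- function(s) if (s == "+") "-" else "+"

#' Assess all uORFs against all target genomes
#'
#' @param uorfs List of `uorf_record`s.
#' @param targets Named list of targets, each `list(genome =, annotation =)`.
#' @param weights A [conservation_weights()].
#' @param max_mismatch Hamming budget for near-exact alignment.
#' @param synonyms Optional gene-name synonym table.
#' @return data.frame of assessments, one row per (uORF, target genome).
#' @export
run_conservation <- function(uorfs, targets,
                             weights = conservation_weights(),
                             max_mismatch = 3L, synonyms = NULL) {
  rows <- list()
  for (g in names(targets)) {
    tgt <- targets[[g]]
    index <- build_target_index(tgt$genome, tgt$annotation)
    for (u in uorfs) {
      rows[[length(rows) + 1L]] <- assess_uorf_conservation(
        u, tgt$genome, tgt$annotation, g, weights, max_mismatch, synonyms,
        index = index)
    }
  }
  do.call(rbind, rows)
}

#' Summarise conservation assessments
#'
#' Produces the per-genome level counts (0 to the maximum score), the
#' conserved / not-conserved subtotals, and the intersection counts over
#' every subset of target genomes. Level counts at conserved-eligible
#' levels are split into conserved cases and distance-exception cases
#' (best match more than the exception bound away), which belong to
#' neither subtotal — mirroring how per-level tables parenthesise them.
#'
#' @param assessments Output of [run_conservation()].
#' @param weights A [conservation_weights()].
#' @return A list: `per_level` (data.frame `target_genome`, `level`, `n`,
#'   `n_exception`), `subtotals` (data.frame `target_genome`,
#'   `n_conserved`, `n_not_conserved`, `n_exception`), `intersections`
#'   (data.frame `genomes`, `n`: exact-subset counts),
#'   `n_conserved_all`, `n_uorfs`, `pct_conserved_all`.
#' @export
summarize_conservation <- function(assessments,
                                   weights = conservation_weights()) {
  genomes <- unique(assessments$target_genome)
  max_level <- weights$w_sequence + weights$w_utr + weights$w_locus
  per_level <- do.call(rbind, lapply(genomes, function(g) {
    a <- assessments[assessments$target_genome == g, ]
    do.call(rbind, lapply(max_level:0, function(lvl) {
      at <- a[a$score == lvl, ]
      if (lvl >= weights$conserved_min_score) {
        data.frame(target_genome = g, level = lvl, n = sum(at$conserved),
                   n_exception = sum(!at$conserved), stringsAsFactors = FALSE)
      } else {
        data.frame(target_genome = g, level = lvl, n = nrow(at),
                   n_exception = 0L, stringsAsFactors = FALSE)
      }
    }))
  }))
  subtotals <- do.call(rbind, lapply(genomes, function(g) {
    a <- assessments[assessments$target_genome == g, ]
    data.frame(target_genome = g, n_conserved = sum(a$conserved),
               n_not_conserved = sum(!a$conserved &
                                       a$score < weights$conserved_min_score),
               n_exception = sum(!a$conserved &
                                   a$score >= weights$conserved_min_score),
               stringsAsFactors = FALSE)
  }))
  uorf_ids <- unique(assessments$uorf_id)
  cons_sets <- lapply(uorf_ids, function(u) {
    a <- assessments[assessments$uorf_id == u, ]
    sort(a$target_genome[a$conserved])
  })
  subset_keys <- vapply(cons_sets, paste, "", collapse = "+")
  all_subsets <- unlist(lapply(0:length(genomes), function(k) {
    if (k == 0L) return("")
    apply(utils::combn(sort(genomes), k), 2, paste, collapse = "+")
  }))
  intersections <- data.frame(
    genomes = all_subsets,
    n = vapply(all_subsets, function(s) sum(subset_keys == s), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  n_all <- sum(vapply(cons_sets, length, integer(1)) == length(genomes))
  list(per_level = per_level, subtotals = subtotals,
       intersections = intersections,
       n_conserved_all = n_all, n_uorfs = length(uorf_ids),
       pct_conserved_all = percent_of(n_all, length(uorf_ids)))
}
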