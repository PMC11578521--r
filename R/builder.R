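## Splice-junction tables are data.frames with columns
##   chrom, donor, acceptor, strand, evidence, support
## where `donor` is the genomic position of the first intronic base and
## `acceptor` the last intronic base, both in transcription order
## (1-based; donor < acceptor on "+", donor > acceptor on "-").

empty_junctions <- function() {
  data.frame(chrom = character(0), donor = integer(0), acceptor = integer(0),
             strand = character(0), evidence = character(0),
             support = numeric(0), donor_motif = character(0),
             acceptor_motif = character(0), stringsAsFactors = FALSE)
}

junction_motifs <- function(junctions, genome) {
  n <- nrow(junctions)
  dm <- character(n)
  am <- character(n)
  for (i in seq_len(n)) {
    seq <- genome[[junctions$chrom[i]]]
    d <- junctions$donor[i]
    a <- junctions$acceptor[i]
    if (junctions$strand[i] == "+") {
      dm[i] <- substr(seq, d, d + 1L)
      am[i] <- substr(seq, a - 1L, a)
    } else {
      dm[i] <- dna_revcomp(substr(seq, d - 1L, d))
      am[i] <- dna_revcomp(substr(seq, a, a + 1L))
    }
  }
  junctions$donor_motif <- dm
  junctions$acceptor_motif <- am
  junctions
}

#' Keep only canonical splice junctions
#'
#' Reads the dinucleotide motifs from the genome in strand orientation and
#' retains junctions whose donor begins with GT or GC and whose acceptor
#' ends with AG.
#'
#' @param junctions Junction data.frame (`chrom`, `donor`, `acceptor`,
#'   `strand`, `evidence`, `support`).
#' @param genome Named character vector of chromosome sequences.
#' @return The retained junctions with `donor_motif` and `acceptor_motif`
#'   columns added.
#' @export
filter_canonical <- function(junctions, genome) {
  if (nrow(junctions) == 0L) return(empty_junctions())
  junctions <- junction_motifs(junctions, genome)
  keep <- junctions$donor_motif %in% c("GT", "GC") &
    junctions$acceptor_motif == "AG"
  junctions[keep, , drop = FALSE]
}

## uORF-local transcript coordinate of a genomic position (1-based along
## the uORF, 5'->3'), or NA when the position is outside the uORF blocks.
uorf_local_pos <- function(uorf, gpos) {
  genomic_to_tx_pos(uorf$blocks, uorf$strand, gpos)
}

#' Find junctions linking a uORF to a downstream CDS
#'
#' A linking junction has its donor strictly inside the uORF coding span —
#' retaining at least the start codon and placing the whole stop codon in
#' the intron — and its acceptor inside the CDS span of the reference
#' transcript, downstream of the donor in transcription order.
#'
#' @param uorf A `uorf_record`.
#' @param junctions Canonical-filtered junction data.frame.
#' @param ref A `reference_transcript`.
#' @return The linking subset of `junctions`.
#' @export
find_linking_junctions <- function(uorf, junctions, ref) {
  if (nrow(junctions) == 0L) return(junctions[0, , drop = FALSE])
  len <- nchar(uorf$nt_sequence)
  keep <- vapply(seq_len(nrow(junctions)), function(i) {
    j <- junctions[i, ]
    if (j$chrom != uorf$chrom || j$strand != uorf$strand) return(FALSE)
    local <- uorf_local_pos(uorf, j$donor)     # first intronic base
    if (is.na(local) || local < 4L || local > len - 3L) return(FALSE)
    fe <- if (j$strand == "+") j$acceptor + 1L else j$acceptor - 1L
    downstream <- if (j$strand == "+") j$acceptor > j$donor
                  else j$acceptor < j$donor
    downstream && point_in_blocks(fe, ref$cds)
  }, logical(1))
  junctions[keep, , drop = FALSE]
}

#' Scan a uORF for candidate GT splice donors
#'
#' Every uORF position where the next two would-be intronic bases read GT
#' in strand orientation is a donor candidate, subject to the construction
#' constraints: at least the start codon is retained and the donor falls
#' strictly before the stop codon. Predicted donors are restricted to GT
#' (GC donors are admitted only from experimental evidence).
#'
#' @param uorf A `uorf_record`.
#' @param genome Named character vector (unused for the scan itself, kept
#'   for interface symmetry; the uORF sequence is scanned directly).
#' @return data.frame with `local_pos` (first intronic base, uORF-local),
#'   `retained` (uORF bases kept), `genomic_pos`.
#' @export
scan_donor_candidates <- function(uorf, genome = NULL) {
  seq <- uorf$nt_sequence
  len <- nchar(seq)
  hits <- integer(0)
  for (i in seq_len(max(0L, len - 6L)) + 3L) {   # 4 .. len - 3
    if (substr(seq, i, i + 1L) == "GT") hits <- c(hits, i)
  }
  gpos <- vapply(hits, function(i) {
    tx_to_genomic_blocks(uorf$blocks, uorf$strand, i, i)$start[1]
  }, integer(1))
  data.frame(local_pos = hits, retained = hits - 1L, genomic_pos = gpos)
}

donor_context <- function(genome, chrom, strand, donor, window = 8L) {
  seq <- genome[[chrom]]
  if (strand == "+") substr(seq, donor, donor + window - 1L)
  else dna_revcomp(substr(seq, donor - window + 1L, donor))
}

acceptor_context <- function(genome, chrom, strand, acceptor, window = 8L) {
  seq <- genome[[chrom]]
  if (strand == "+") substr(seq, acceptor - window + 1L, acceptor)
  else dna_revcomp(substr(seq, acceptor, acceptor + window - 1L))
}

#' Pair scanned donors with annotated MANE acceptors and score them
#'
#' Builds every donor x acceptor pair from the scanned GT donors of a uORF
#' and the annotated acceptor sites of a MANE reference's CDS exons, scores
#' each pair with the pluggable splice-site scorer, and retains pairs whose
#' mean donor/acceptor score reaches the threshold (the boundary value is
#' retained). Pairs already present in the experimental junction set are
#' excluded: the predictor only scores junctions unseen in the experimental
#' data, so the two evidence sets stay disjoint.
#'
#' @param donors Output of [scan_donor_candidates()].
#' @param ref A MANE `reference_transcript` supplying acceptor sites.
#' @param uorf The `uorf_record` the donors came from.
#' @param genome Named character vector of chromosome sequences.
#' @param scorer Function `(donor_context, acceptor_context) ->
#'   c(donor =, acceptor =)`, e.g. [mock_splice_scorer()].
#' @param threshold Minimum mean score (default 0.9).
#' @param experimental Experimental junction data.frame used for the
#'   exclusion (pre-filter set).
#' @param window Context width handed to the scorer.
#' @return Junction data.frame with `evidence = "predicted"` and `support`
#'   set to the mean score.
#' @export
pair_and_score <- function(donors, ref, uorf, genome,
                           scorer = mock_splice_scorer, threshold = 0.9,
                           experimental = NULL, window = 8L) {
  acceptors <- ref_acceptor_sites(ref)
  out <- list()
  for (i in seq_len(nrow(donors))) {
    d <- donors$genomic_pos[i]
    for (a in acceptors) {
      downstream <- if (uorf$strand == "+") a > d else a < d
      if (!downstream) next
      if (!is.null(experimental) && nrow(experimental) > 0L &&
          any(experimental$chrom == uorf$chrom &
              experimental$donor == d & experimental$acceptor == a &
              experimental$strand == uorf$strand)) next
      sc <- scorer(donor_context(genome, uorf$chrom, uorf$strand, d, window),
                   acceptor_context(genome, uorf$chrom, uorf$strand, a, window))
      # scorers report a few decimals; rounding the mean keeps the
      # at-least-0.9 boundary free of binary-float artefacts
      m <- round(mean(sc), 6)
      if (m >= threshold) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = uorf$chrom, donor = d, acceptor = a, strand = uorf$strand,
          evidence = "predicted", support = m,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) return(empty_junctions()[, 1:6])
  do.call(rbind, out)
}

#' Assemble the CDS of a uORF-connected transcript
#'
#' Concatenates the uORF bases from its start codon up to (not including)
#' the junction's first intronic base with the reference CDS bases from the
#' acceptor's first exonic base through the reference stop codon, honouring
#' all downstream reference introns. An acceptor landing mid-exon trims the
#' 5' portion of that CDS exon.
#'
#' @param uorf A `uorf_record`.
#' @param junction One-row junction data.frame linking `uorf` to `ref`.
#' @param ref A `reference_transcript`.
#' @param genome Named character vector of chromosome sequences.
#' @return A list: `cds_sequence`, `blocks` (genomic exon chain of the
#'   novel CDS), `uorf_part_len`, `ref_part_len`.
#' @export
assemble_cds <- function(uorf, junction, ref, genome) {
  linking <- find_linking_junctions(uorf, junction, ref)
  if (nrow(linking) != 1L) {
    stop("junction does not link uORF ", uorf$uorf_id,
         " to reference ", ref$transcript_id)
  }
  strand <- uorf$strand
  local <- uorf_local_pos(uorf, junction$donor)
  retained <- local - 1L
  uorf_blocks <- tx_to_genomic_blocks(uorf$blocks, strand, 1L, retained)

  fe <- if (strand == "+") junction$acceptor + 1L else junction$acceptor - 1L
  cds <- ref$cds
  ord <- if (strand == "+") order(cds$start) else order(-cds$start)
  ds <- list()
  seen <- FALSE
  for (i in ord) {
    b <- cds[i, ]
    if (!seen) {
      if (fe >= b$start && fe <= b$end) {
        seen <- TRUE
        if (strand == "+") b$start <- fe else b$end <- fe
      } else {
        next
      }
    }
    ds[[length(ds) + 1L]] <- b
  }
  if (!seen) stop("acceptor does not fall inside the reference CDS")
  ds <- do.call(rbind, ds)

  seq <- genome[[uorf$chrom]]
  uorf_part <- extract_blocks(seq, uorf_blocks, strand)
  ref_part <- extract_blocks(seq, blocks_df(ds$start, ds$end), strand)
  list(cds_sequence = paste0(uorf_part, ref_part),
       blocks = blocks_df(c(uorf_blocks$start, ds$start),
                          c(uorf_blocks$end, ds$end)),
       uorf_part_len = nchar(uorf_part), ref_part_len = nchar(ref_part))
}

#' Literal translation of a CDS
#'
#' Standard genetic code, no forced initiator methionine (a construct
#' starting ATA yields isoleucine), terminal stop removed, internal stops
#' left in place as `*` for [validate_orf()] to detect. A trailing partial
#' codon is dropped.
#'
#' @param cds_sequence Nucleotide string, length >= 3.
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds_sequence) {
  stopifnot(nchar(cds_sequence) >= 3L)
  orf_protein(cds_sequence)
}

#' Validate a candidate uORF-connected CDS
#'
#' The three discard rules: (1) a premature stop codon, (2) length not a
#' multiple of three, (3) a CDS shorter than `min_fraction` (default 90%,
#' boundary passing) of the reference CDS length.
#'
#' @param cds_sequence Candidate CDS (nucleotides, including the stop).
#' @param ref_cds_len Reference CDS length in nucleotides.
#' @param min_fraction Minimum CDS length fraction (default 0.9).
#' @return List: `passed`, `failure_reasons` (subset of `premature_stop`,
#'   `frame_violation`, `too_short`), `cds_len_fraction`.
#' @export
validate_orf <- function(cds_sequence, ref_cds_len, min_fraction = 0.9) {
  reasons <- character(0)
  if (nchar(cds_sequence) %% 3L != 0L) reasons <- c(reasons, "frame_violation")
  protein <- translate_cds(cds_sequence)
  if (grepl("*", protein, fixed = TRUE)) reasons <- c(reasons, "premature_stop")
  fraction <- nchar(cds_sequence) / ref_cds_len
  if (fraction < min_fraction) reasons <- c(reasons, "too_short")
  list(passed = length(reasons) == 0L, failure_reasons = reasons,
       cds_len_fraction = fraction)
}

#' Start-codon class of a construct's protein
#'
#' @param protein Amino-acid string (non-empty).
#' @return `"AUG"` iff the first residue is methionine, else `"non_AUG"`.
#' @export
classify_start <- function(protein) {
  if (!nzchar(protein)) stop("cannot classify the start codon of an empty protein")
  if (substr(protein, 1L, 1L) == "M") "AUG" else "non_AUG"
}

#' Does a construct duplicate its reference protein?
#'
#' Duplications between the uORF and the downstream ORF occasionally yield
#' a novel transcript encoding exactly the reference protein; such
#' constructs are flagged (and reported separately), not dropped.
#'
#' @param protein Construct protein.
#' @param ref_protein Reference protein.
#' @return `TRUE` iff the sequences are identical.
#' @export
detect_reference_duplicate <- function(protein, ref_protein) {
  identical(protein, ref_protein)
}

#' Collapse constructs to distinct encoded proteins
#'
#' Keeps one construct per distinct (uORF, protein sequence, reference
#' transcript) triple: the one with the highest junction support, ties
#' broken by smallest construct id. Identical proteins arising from
#' different uORFs are all kept.
#'
#' @param constructs Construct data.frame from [build_constructs()].
#' @return The deduplicated data.frame.
#' @export
deduplicate_constructs <- function(constructs) {
  if (nrow(constructs) == 0L) return(constructs)
  key <- paste(constructs$uorf_id, constructs$protein,
               constructs$reference_transcript_id, sep = "\r")
  idx <- as.integer(sub("uorft_", "", constructs$construct_id))
  ord <- order(key, -constructs$support, idx)
  keep <- !duplicated(key[ord])
  out <- constructs[ord[keep], , drop = FALSE]
  out[order(as.integer(sub("uorft_", "", out$construct_id))), , drop = FALSE]
}

empty_constructs <- function() {
  data.frame(construct_id = character(0), uorf_id = character(0),
             gene_name = character(0), chrom = character(0),
             strand = character(0), donor = integer(0), acceptor = integer(0),
             evidence = character(0), support = numeric(0),
             donor_motif = character(0), acceptor_motif = character(0),
             reference_transcript_id = character(0), is_mane_ref = logical(0),
             is_nmd_ref = logical(0), cds_len = integer(0),
             ref_cds_len = integer(0), cds_len_fraction = numeric(0),
             valid = logical(0), failure_reasons = character(0),
             start_codon_class = character(0),
             duplicate_of_reference = logical(0), exon_chain = character(0),
             cds_sequence = character(0), protein = character(0),
             stringsAsFactors = FALSE)
}

#' Construct uORF-connected transcripts for a uORF catalogue
#'
#' For every uORF: canonical-filtered experimental junctions linking the
#' uORF to each reference transcript at its locus yield
#' experimental-evidence constructs; scanned GT donors paired with
#' annotated MANE acceptors and passing the splice-score threshold yield
#' predicted-evidence constructs (pairs already seen experimentally are
#' excluded). Every construct is assembled, translated literally, validated
#' against the three discard rules, classified by start codon, flagged when
#' it duplicates its reference protein, and finally deduplicated to
#' distinct (uORF, protein, reference) triples. Construction runs on the
#' full catalogue; conservation gating is applied downstream.
#'
#' @param uorfs List of `uorf_record`s.
#' @param genome Named character vector of chromosome sequences.
#' @param annotation Annotation data.frame.
#' @param junctions Experimental junction data.frame.
#' @param scorer Pluggable splice-site scorer (default
#'   [mock_splice_scorer()]).
#' @param score_threshold Minimum mean splice score for predicted junctions
#'   (default 0.9).
#' @param min_cds_fraction Minimum CDS length fraction (default 0.9).
#' @return Construct data.frame (one row per construct; invalid constructs
#'   kept with `valid = FALSE` and their failure reasons).
#' @export
build_constructs <- function(uorfs, genome, annotation, junctions,
                             scorer = mock_splice_scorer,
                             score_threshold = 0.9, min_cds_fraction = 0.9) {
  refs <- reference_transcripts(annotation, genome)
  refs_by_gene <- split(refs, vapply(refs, `[[`, "", "gene_name"))
  canon <- filter_canonical(junctions, genome)
  rows <- list()
  for (uorf in uorfs) {
    gene_refs <- refs_by_gene[[uorf$gene_name]]
    if (is.null(gene_refs)) next
    cand <- list()
    for (ref in gene_refs) {
      exp_link <- find_linking_junctions(uorf, canon, ref)
      for (i in seq_len(nrow(exp_link))) {
        cand[[length(cand) + 1L]] <- list(junction = exp_link[i, ], ref = ref)
      }
      if (ref$is_mane) {
        donors <- scan_donor_candidates(uorf, genome)
        pred <- pair_and_score(donors, ref, uorf, genome, scorer,
                               score_threshold, experimental = junctions)
        pred <- junction_motifs(pred, genome)
        for (i in seq_len(nrow(pred))) {
          cand[[length(cand) + 1L]] <- list(junction = pred[i, ], ref = ref)
        }
      }
    }
    for (cj in cand) {
      asm <- assemble_cds(uorf, cj$junction, cj$ref, genome)
      val <- validate_orf(asm$cds_sequence, cj$ref$cds_len, min_cds_fraction)
      protein <- translate_cds(asm$cds_sequence)
      rows[[length(rows) + 1L]] <- data.frame(
        construct_id = NA_character_, uorf_id = uorf$uorf_id,
        gene_name = uorf$gene_name, chrom = uorf$chrom, strand = uorf$strand,
        donor = cj$junction$donor, acceptor = cj$junction$acceptor,
        evidence = cj$junction$evidence, support = cj$junction$support,
        donor_motif = cj$junction$donor_motif,
        acceptor_motif = cj$junction$acceptor_motif,
        reference_transcript_id = cj$ref$transcript_id,
        is_mane_ref = cj$ref$is_mane, is_nmd_ref = cj$ref$is_nmd,
        cds_len = nchar(asm$cds_sequence), ref_cds_len = cj$ref$cds_len,
        cds_len_fraction = val$cds_len_fraction, valid = val$passed,
        failure_reasons = paste(val$failure_reasons, collapse = ","),
        start_codon_class = classify_start(protein),
        duplicate_of_reference = detect_reference_duplicate(protein,
                                                            cj$ref$protein),
        exon_chain = paste(asm$blocks$start, asm$blocks$end,
                           sep = "-", collapse = ";"),
        cds_sequence = asm$cds_sequence, protein = protein,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty_constructs())
  out <- do.call(rbind, rows)
  out$construct_id <- paste0("uorft_", seq_len(nrow(out)))
  deduplicate_constructs(out)
}
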