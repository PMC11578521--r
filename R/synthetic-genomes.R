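#' Declare how an individual genome differs from the reference locus
#'
#' Mutation plans emulate the ways a uORF can drift between individual
#' genomes: unchanged; a synonymous or non-synonymous substitution inside
#' the uORF; a 1-bp deletion (frameshift); relocation of the uORF sequence
#' more than 1 kbp away from the gene; deletion of the hosting 5'UTR exon
#' from the annotation; or loss of the locus altogether.
#'
#' @param kind One of `identical`, `synonymous_sub`, `nonsynonymous_sub`,
#'   `indel`, `relocate_gt_1kbp`, `delete_utr`, `delete_locus`.
#' @param params Optional kind-specific parameters: `codon` (1-based uORF
#'   codon index for substitutions), `del_local` (uORF-local position of
#'   the deleted base), `gap` (relocation distance, > 1000).
#' @return A list of class `mutation_plan`.
#' @export
mutation_plan <- function(kind = c("identical", "synonymous_sub",
                                   "nonsynonymous_sub", "indel",
                                   "relocate_gt_1kbp", "delete_utr",
                                   "delete_locus"),
                          params = list()) {
  kind <- match.arg(kind)
  if (kind == "relocate_gt_1kbp") {
    params$gap <- as.integer(params$gap %||% 1500L)
    if (params$gap <= 1000L) stop("relocation gap must exceed 1,000 bp")
  }
  structure(list(kind = kind, params = params), class = "mutation_plan")
}

## Genomic position of a uORF-local base.
uorf_genomic_pos <- function(uorf, local) {
  tx_to_genomic_blocks(uorf$blocks, uorf$strand, local, local)$start[1]
}

## Write `base` (transcript orientation) at uORF-local position `local`.
set_uorf_base <- function(seq, uorf, local, base) {
  g <- uorf_genomic_pos(uorf, local)
  if (uorf$strand == "-") base <- dna_revcomp(base)
  replace_str(seq, g, base)
}

GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE

## First codon (index >= 2, before the stop) admitting a single-base
## substitution that is synonymous (syn = TRUE) or missense-but-not-stop
## (syn = FALSE); returns list(codon_idx, new_codon) or NULL.
find_substitution <- function(uorf_seq, syn) {
  n_codons <- nchar(uorf_seq) / 3L
  for (k in seq_len(max(0L, n_codons - 2L)) + 1L) {   # codons 2 .. n-1
    codon <- substr(uorf_seq, 3L * k - 2L, 3L * k)
    aa <- GENETIC_CODE_TABLE[[codon]]
    for (p in 3:1) {
      for (b in DNA_BASES) {
        if (b == substr(codon, p, p)) next
        alt <- replace_str(codon, p, b)
        alt_aa <- GENETIC_CODE_TABLE[[alt]]
        if (alt_aa == "*") next
        if ((syn && alt_aa == aa) || (!syn && alt_aa != aa)) {
          return(list(codon_idx = k, new_codon = alt))
        }
      }
    }
  }
  NULL
}

rotate_bases <- function(x) chartr("ACGT", "CGTA", x)

## Shift annotation coordinates across a 1-bp deletion at genomic `pos`
## (an internal liftover of the mutated locus).
liftover_deletion <- function(annotation, chrom, pos) {
  sel <- annotation$seqid == chrom
  annotation$start[sel] <- annotation$start[sel] -
    (annotation$start[sel] > pos)
  annotation$end[sel] <- annotation$end[sel] - (annotation$end[sel] >= pos)
  annotation
}

#' Derive an individual genome from a reference locus
#'
#' Applies a [mutation_plan()] to a reference locus, returning the mutated
#' chromosome, its (lifted) annotation, and the ground-truth conservation
#' outcome the mutation implies. Expected levels under the default weights:
#' `identical` 7; `synonymous_sub` 7 (nucleotide match fails, the
#' protein-level fallback recovers it); `nonsynonymous_sub` 3 (5'UTR +
#' locus only); `indel` 0 (a frameshifted query has no full-length Hamming
#' match); `delete_utr` 5 (sequence + locus; the plan is rejected as
#' incompatible for uORFs spanning an intron or the CDS start, whose
#' residual partial matches would make the expected level
#' content-dependent);
#' `relocate_gt_1kbp` 5 but not conserved (the nearest gene still carries
#' the expected name, yet the match is > 1 kbp away); `delete_locus` 0.
#'
#' @param locus A `uorf_locus` from [generate_reference_locus()].
#' @param plan A [mutation_plan()].
#' @param seed Integer seed (recorded; the derivation itself is
#'   deterministic given `(locus, plan)`).
#' @return List with `genome` (named character vector), `annotation`,
#'   and `truth` (one-row data.frame: `uorf_id`, `kind`, `expected_level`,
#'   `expected_conserved`).
#' @export
derive_individual_genome <- function(locus, plan, seed = 0L) {
  stopifnot(inherits(locus, "uorf_locus"), inherits(plan, "mutation_plan"))
  uorf <- locus$uorf
  seq <- locus$seq
  annotation <- locus$annotation
  spliced <- nrow(uorf$blocks) > 1L
  level <- NA_integer_
  conserved <- NA

  if (plan$kind == "identical") {
    level <- 7L; conserved <- TRUE

  } else if (plan$kind %in% c("synonymous_sub", "nonsynonymous_sub")) {
    syn <- plan$kind == "synonymous_sub"
    sub <- find_substitution(uorf$nt_sequence, syn)
    if (is.null(sub)) stop("no ", plan$kind, " available in this uORF")
    k <- plan$params$codon %||% sub$codon_idx
    if (!identical(k, sub$codon_idx)) {
      # honour an explicit codon request when workable
      sub2 <- find_substitution_at(uorf$nt_sequence, k, syn)
      if (!is.null(sub2)) sub <- sub2
    }
    old <- substr(uorf$nt_sequence, 3L * sub$codon_idx - 2L, 3L * sub$codon_idx)
    for (p in 1:3) {
      if (substr(old, p, p) != substr(sub$new_codon, p, p)) {
        seq <- set_uorf_base(seq, uorf, 3L * (sub$codon_idx - 1L) + p,
                             substr(sub$new_codon, p, p))
      }
    }
    level <- if (syn) 7L else 3L
    conserved <- syn

  } else if (plan$kind == "indel") {
    # A 1-bp deletion near either uORF end can be absorbed by a shifted
    # Hamming window (the frameshifted tail realigns); delete mid-uORF and
    # verify on the derived locus that no full-length near-match survives,
    # so "expected level 0" is a derivable fact, not a hope.
    len <- nchar(uorf$nt_sequence)
    mid <- as.integer(len / 2L)
    candidates <- plan$params$del_local %||%
      unique(pmin(pmax(mid + c(0L, -1L, 1L, -2L, 2L, -3L, 3L), 4L),
                  len - 4L))
    done <- FALSE
    for (local in candidates) {
      g <- uorf_genomic_pos(uorf, local)
      seq2 <- paste0(substr(seq, 1L, g - 1L), substr(seq, g + 1L, nchar(seq)))
      ann2 <- liftover_deletion(annotation, locus$chrom, g)
      idx <- build_target_index(stats::setNames(seq2, locus$chrom), ann2)
      clear <- nrow(naive_align(uorf$nt_sequence, idx$dss, 3L)) == 0L &&
        (length(idx$tx) == 0L ||
           nrow(naive_align(uorf$nt_sequence, idx$tx_dss, 3L)) == 0L)
      if (clear) {
        seq <- seq2
        annotation <- ann2
        done <- TRUE
        break
      }
    }
    if (!done) stop("no indel position leaves the uORF unalignable here")
    level <- 0L; conserved <- FALSE

  } else if (plan$kind == "relocate_gt_1kbp") {
    gap <- plan$params$gap %||% 1500L
    len <- nchar(uorf$nt_sequence)
    gene_end <- locus$layout$gene_end
    gene_start <- locus$layout$gene_start
    pos <- gene_end + gap + 1L
    if (pos + len - 1L > nchar(seq)) pos <- gene_start - gap - len
    if (pos < 1L) stop("flank too short for the requested relocation gap")
    for (i in seq_len(nrow(uorf$blocks))) {   # erase the original copy
      b <- uorf$blocks[i, ]
      seq <- replace_str(seq, b$start, rotate_bases(substr(seq, b$start, b$end)))
    }
    seq <- replace_str(seq, pos, uorf$nt_sequence)
    level <- 5L; conserved <- FALSE

  } else if (plan$kind == "delete_utr") {
    if (spliced) {
      # the residual partial matches of a spliced uORF make the expected
      # level depend on sequence content; the plan is rejected as
      # incompatible with such loci
      stop("delete_utr is incompatible with a uORF spanning an intron ",
           "or the CDS start")
    }
    utr_rows <- annotation$seqid == locus$chrom &
      annotation$type %in% c("exon", "five_prime_UTR") &
      annotation$end >= uorf$start & annotation$start <= uorf$end &
      mapply(function(s, e) {       # wholly-UTR exons only
        !point_in_blocks(s, locus$annotation[locus$annotation$type == "CDS" &
                                               locus$annotation$seqid == locus$chrom,
                                             c("start", "end")]) },
        annotation$start, annotation$end)
    annotation <- annotation[!utr_rows, , drop = FALSE]
    level <- 5L
    conserved <- TRUE

  } else if (plan$kind == "delete_locus") {
    for (i in seq_len(nrow(uorf$blocks))) {
      b <- uorf$blocks[i, ]
      seq <- replace_str(seq, b$start, rotate_bases(substr(seq, b$start, b$end)))
    }
    annotation <- annotation[annotation$seqid != locus$chrom, , drop = FALSE]
    level <- 0L; conserved <- FALSE
  }

  list(genome = stats::setNames(seq, locus$chrom),
       annotation = annotation,
       truth = data.frame(uorf_id = uorf$uorf_id, kind = plan$kind,
                          expected_level = level,
                          expected_conserved = conserved,
                          stringsAsFactors = FALSE))
}

find_substitution_at <- function(uorf_seq, k, syn) {
  codon <- substr(uorf_seq, 3L * k - 2L, 3L * k)
  aa <- GENETIC_CODE_TABLE[[codon]]
  if (aa == "*") return(NULL)
  for (p in 3:1) {
    for (b in DNA_BASES) {
      if (b == substr(codon, p, p)) next
      alt <- replace_str(codon, p, b)
      alt_aa <- GENETIC_CODE_TABLE[[alt]]
      if (alt_aa == "*") next
      if ((syn && alt_aa == aa) || (!syn && alt_aa != aa)) {
        return(list(codon_idx = k, new_codon = alt))
      }
    }
  }
  NULL
}

#' Generate splice-junction evidence for a locus
#'
#' Emulates junction-level summaries of a large RNA-seq collection (with
#' per-junction read coverage). When `place_linking` is set, exactly one
#' junction links the locus's planted GT donor inside the uORF to an
#' annotated CDS acceptor; noise junctions fall in the 5' flank (arbitrary,
#' mostly non-canonical motifs) and never link.
#'
#' @param locus A `uorf_locus` whose spec planted a donor
#'   (`plant_donor != "none"`) if `place_linking` is used.
#' @param place_linking Place the linking junction?
#' @param coverage Read coverage recorded on the linking junction.
#' @param noise_junctions Number of non-linking junctions to add.
#' @param seed Integer seed for noise placement.
#' @param acceptor_cds_exon Which CDS exon's acceptor the linking junction
#'   uses (1-based, transcription order).
#' @return Junction data.frame (`chrom`, `donor`, `acceptor`, `strand`,
#'   `evidence`, `support`).
#' @export
generate_junction_evidence <- function(locus, place_linking = TRUE,
                                       coverage = 100L, noise_junctions = 2L,
                                       seed = 0L, acceptor_cds_exon = 1L) {
  rows <- list()
  if (place_linking) {
    if (is.null(locus$layout$donor)) {
      stop("locus has no planted donor; regenerate with plant_donor set")
    }
    rows[[1L]] <- data.frame(
      chrom = locus$chrom, donor = locus$layout$donor$genomic_pos,
      acceptor = locus$layout$acceptors[acceptor_cds_exon],
      strand = locus$uorf$strand, evidence = "experimental",
      support = as.numeric(coverage), stringsAsFactors = FALSE)
  }
  if (noise_junctions > 0L) {
    flank <- locus$layout$spec$flank
    rows[[length(rows) + 1L]] <- with_seed(seed, {
      d <- sample(50:(flank - 300L), noise_junctions, replace = TRUE)
      data.frame(chrom = locus$chrom, donor = as.integer(d),
                 acceptor = as.integer(d + 80L), strand = locus$uorf$strand,
                 evidence = "experimental",
                 support = as.numeric(sample(5:30, noise_junctions,
                                             replace = TRUE)),
                 stringsAsFactors = FALSE)
    })
  }
  if (length(rows) == 0L) return(empty_junctions()[, 1:6])
  do.call(rbind, rows)
}
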