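#' Describe a synthetic gene locus hosting a uORF
#'
#' A `locus_spec` declares the anatomy of one toy protein-coding locus: a
#' transcript made of one or more 5'UTR exons followed by CDS exons (each
#' exon separated by an intron), with an upstream ORF planted inside the
#' 5'UTR. The uORF may span two UTR exons (its genomic footprint is then
#' discontiguous while its transcript footprint stays contiguous) or overlap
#' the CDS start by a fixed 4 bases.
#'
#' @param locus_id Chromosome/locus identifier (one synthetic chromosome per
#'   locus).
#' @param gene_name Gene symbol used for locus-match checks; defaults to
#'   `locus_id`.
#' @param utr_exon_lengths Integer vector of 5'UTR exon lengths (bp),
#'   transcription order.
#' @param uorf_offset 0-based offset of the uORF start from the transcript
#'   5' end (bases).
#' @param uorf_length uORF length in bases including its stop codon;
#'   a multiple of 3, at least 6.
#' @param cds_exon_lengths Integer vector of CDS exon lengths (bp); their sum
#'   must be a multiple of 3 and includes the terminal stop codon.
#' @param intron_lengths Intron lengths between consecutive exons; recycled
#'   to `n_exons - 1`. Minimum 12 bp (room for canonical ends).
#' @param strand `"+"` or `"-"`.
#' @param flank Flanking sequence added on each side of the gene (bp); must
#'   leave room for the >1 kbp relocation mutation (default 2000).
#' @param plant_donor `"none"`, `"gt"` (a bare GT splice donor inside the
#'   uORF), or `"strong"` (a GT donor followed by the high-score signature
#'   recognised by [mock_splice_scorer()]).
#' @param donor_retained Number of uORF bases retained upstream of the
#'   planted donor. Default: `uorf_length - 12` (`- 15` for CDS-overlapping
#'   uORFs). Must be >= 3 and leave the uORF stop codon intronic.
#'
#' @return An object of class `locus_spec`.
#' @seealso [generate_reference_locus()]
#' @export
locus_spec <- function(locus_id,
                       gene_name = locus_id,
                       utr_exon_lengths = 120L,
                       uorf_offset = 10L,
                       uorf_length = 30L,
                       cds_exon_lengths = c(60L, 120L),
                       intron_lengths = 120L,
                       strand = c("+", "-"),
                       flank = 2000L,
                       plant_donor = c("none", "gt", "strong"),
                       donor_retained = NULL) {
  strand <- match.arg(strand)
  plant_donor <- match.arg(plant_donor)
  utr_exon_lengths <- as.integer(utr_exon_lengths)
  cds_exon_lengths <- as.integer(cds_exon_lengths)
  n_exons <- length(utr_exon_lengths) + length(cds_exon_lengths)
  intron_lengths <- as.integer(rep_len(intron_lengths, n_exons - 1L))

  if (any(c(utr_exon_lengths, cds_exon_lengths, intron_lengths) <= 0L)) {
    stop("all exon and intron lengths must be positive")
  }
  if (any(intron_lengths < 12L)) stop("introns must be at least 12 bp")
  if (uorf_length %% 3L != 0L || uorf_length < 6L) {
    stop("uorf_length must be a multiple of 3 and >= 6")
  }
  if (sum(cds_exon_lengths) %% 3L != 0L) {
    stop("total CDS length must be a multiple of 3")
  }
  utr_len <- sum(utr_exon_lengths)
  tx_len <- utr_len + sum(cds_exon_lengths)
  if (uorf_offset < 0L || uorf_offset + 3L > utr_len) {
    stop("uORF start codon must lie inside the 5'UTR")
  }
  if (uorf_offset + uorf_length > tx_len) {
    stop("uORF extends past the transcript end")
  }
  overlap <- max(0L, uorf_offset + uorf_length - utr_len)
  if (overlap != 0L && overlap != 4L) {
    stop("CDS-overlapping uORFs are generated with a fixed 4-base overlap; ",
         "got overlap of ", overlap, " bases")
  }
  if (is.null(donor_retained)) {
    donor_retained <- uorf_length - (if (overlap > 0L) 15L else 12L)
  }
  donor_retained <- as.integer(donor_retained)
  if (plant_donor != "none") {
    if (donor_retained < 3L || donor_retained > uorf_length - 4L) {
      stop("donor must retain >= 3 uORF bases and start before the stop codon")
    }
    if (plant_donor == "strong") {
      lim <- uorf_length - (if (overlap > 0L) 6L else 3L)
      if (donor_retained %% 3L != 0L || donor_retained + 8L > lim) {
        stop("the strong-donor signature needs donor_retained to be a ",
             "multiple of 3 with 8 clear bases before the uORF tail")
      }
    }
  }
  if (flank < 1600L + uorf_length) {
    stop("flank too short to host the >1 kbp relocation mutation")
  }
  structure(list(
    locus_id = locus_id, gene_name = gene_name,
    n_utr_exons = length(utr_exon_lengths),
    utr_exon_lengths = utr_exon_lengths,
    uorf_offset = as.integer(uorf_offset),
    uorf_length = as.integer(uorf_length),
    cds_exon_lengths = cds_exon_lengths,
    intron_lengths = intron_lengths,
    strand = strand, flank = as.integer(flank),
    cds_overlap = overlap,
    plant_donor = plant_donor, donor_retained = donor_retained
  ), class = "locus_spec")
}

## The 8-mer the mock splice scorer recognises as a strong donor (GT + 6-mer
## signature) and the intron tail it recognises as a strong acceptor.
DONOR_SIGNATURE <- "GTAAGGGC"
ACCEPTOR_SIGNATURE <- "CCCTTTAG"

## Rewrite any stop codon in the uORF body created by donor planting,
## touching only positions outside `protected`.
repair_uorf_stops <- function(uorf_seq, protected) {
  n <- nchar(uorf_seq)
  for (k in seq_len(n / 3L - 1L)) {   # skip the final (stop) codon
    s <- 3L * (k - 1L) + 1L
    codon <- substr(uorf_seq, s, s + 2L)
    if (codon %in% STOP_CODONS && k > 1L) {
      for (p in s:(s + 2L)) {
        if (!(p %in% protected)) {
          uorf_seq <- replace_str(uorf_seq, p, "C")
          break
        }
      }
    }
  }
  uorf_seq
}

build_uorf_sequence <- function(spec) {
  len <- spec$uorf_length
  if (spec$cds_overlap > 0L) {
    body <- random_codons((len - 9L) / 3L)
    seq <- paste0("ATG", body, "CCA", "TGA")
  } else {
    body <- random_codons(len / 3L - 2L)
    seq <- paste0("ATG", body, "TAA")
  }
  protected <- integer(0)
  d <- spec$donor_retained
  if (spec$plant_donor == "strong") {
    seq <- replace_str(seq, d + 1L, DONOR_SIGNATURE)
    protected <- (d + 1L):(d + 8L)
  } else if (spec$plant_donor == "gt") {
    seq <- replace_str(seq, d + 1L, "GT")
    protected <- (d + 1L):(d + 2L)
  }
  repair_uorf_stops(seq, protected)
}

build_cds_sequence <- function(spec) {
  total <- sum(spec$cds_exon_lengths)
  if (spec$cds_overlap > 0L) {
    # first 6 bases pinned so the uORF tail (…CCATGA) and the CDS start agree
    paste0("ATGACC", random_codons(total / 3L - 3L), "TAA")
  } else {
    paste0("ATG", random_codons(total / 3L - 2L), "TAA")
  }
}

build_intron <- function(len) {
  paste0("GT", random_dna(len - 10L), ACCEPTOR_SIGNATURE)
}

#' Generate the reference copy of a synthetic locus
#'
#' Builds a single synthetic chromosome carrying one protein-coding gene, its
#' GFF-style annotation (gene, mRNA, exon, CDS, five_prime_UTR features;
#' 1-based closed coordinates) and a catalogued uORF record. All introns are
#' canonical (GT..AG) and every annotated acceptor carries the strong-site
#' signature recognised by [mock_splice_scorer()]. Deterministic: identical
#' `(spec, seed)` yield byte-identical output.
#'
#' @param spec A [locus_spec()].
#' @param seed Integer seed for the locus sequence.
#' @return A list of class `uorf_locus` with elements `chrom`, `seq`,
#'   `annotation` (data.frame), `uorf` (a `uorf_record` list with genomic
#'   `blocks`), and `layout` (internal geometry used by the generator).
#' @export
generate_reference_locus <- function(spec, seed) {
  stopifnot(inherits(spec, "locus_spec"))
  n_sig_expected <- if (spec$plant_donor == "strong") 1L else 0L
  for (attempt in 0:24) {
    loc <- with_seed(seed + 1000003L * attempt, build_locus_once(spec))
    # the catalogued uORF must be uniquely placeable for the alignment oracle,
    # and must not carry an accidental copy of the strong-donor signature
    n_occ <- count_exact_occurrences(loc$uorf$nt_sequence, loc$seq)
    n_sig <- lengths(regmatches(loc$uorf$nt_sequence,
                                gregexpr(DONOR_SIGNATURE, loc$uorf$nt_sequence,
                                         fixed = TRUE)))
    placeable <- nrow(loc$uorf$blocks) > 1L || n_occ == 1L
    if (placeable && n_sig == n_sig_expected) return(loc)
  }
  stop("could not generate a locus with a unique uORF placement")
}

build_locus_once <- function(spec) {
  utr_len <- sum(spec$utr_exon_lengths)
  cds_len <- sum(spec$cds_exon_lengths)
  tx_len <- utr_len + cds_len

  tx_seq <- random_dna(tx_len)
  tx_seq <- replace_str(tx_seq, utr_len + 1L, build_cds_sequence(spec))
  uorf_seq <- build_uorf_sequence(spec)
  tx_seq <- replace_str(tx_seq, spec$uorf_offset + 1L, uorf_seq)

  exon_widths <- c(spec$utr_exon_lengths, spec$cds_exon_lengths)
  n_exons <- length(exon_widths)
  introns <- lapply(spec$intron_lengths, build_intron)

  # assemble the chromosome (sense orientation first)
  gene_start <- spec$flank + 1L
  pieces <- character(0)
  exon_start <- integer(n_exons)
  exon_end <- integer(n_exons)
  pos <- gene_start
  tx_off <- 0L
  for (i in seq_len(n_exons)) {
    exon_start[i] <- pos
    exon_end[i] <- pos + exon_widths[i] - 1L
    pieces <- c(pieces, substr(tx_seq, tx_off + 1L, tx_off + exon_widths[i]))
    pos <- pos + exon_widths[i]
    tx_off <- tx_off + exon_widths[i]
    if (i < n_exons) {
      pieces <- c(pieces, introns[[i]])
      pos <- pos + spec$intron_lengths[i]
    }
  }
  gene_end <- exon_end[n_exons]
  seq <- paste0(random_dna(spec$flank), paste(pieces, collapse = ""),
                random_dna(spec$flank))
  chrom_len <- nchar(seq)
  stopifnot(chrom_len == gene_end + spec$flank)

  exons <- blocks_df(exon_start, exon_end)
  exons$role <- c(rep("utr", spec$n_utr_exons),
                  rep("cds", length(spec$cds_exon_lengths)))

  if (spec$strand == "-") {
    seq <- dna_revcomp(seq)
    new_start <- chrom_len - exons$end + 1L
    new_end <- chrom_len - exons$start + 1L
    exons$start <- new_start
    exons$end <- new_end
    exons <- exons[order(exons$start), , drop = FALSE]
    tmp <- gene_start
    gene_start <- chrom_len - gene_end + 1L
    gene_end <- chrom_len - tmp + 1L
  }

  tid <- paste0(spec$locus_id, "_t1")
  exon_only <- exons[, c("start", "end")]
  utr_rows <- exons[exons$role == "utr", c("start", "end"), drop = FALSE]
  cds_rows <- exons[exons$role == "cds", c("start", "end"), drop = FALSE]
  annotation <- rbind(
    ann_row(spec, "gene", gene_start, gene_end, NA_character_),
    ann_row(spec, "mRNA", gene_start, gene_end, tid),
    ann_rows(spec, "exon", exon_only, tid),
    ann_rows(spec, "five_prime_UTR", utr_rows, tid),
    ann_rows(spec, "CDS", cds_rows, tid)
  )

  uorf_blocks <- tx_to_genomic_blocks(exon_only, spec$strand,
                                      spec$uorf_offset + 1L,
                                      spec$uorf_offset + spec$uorf_length)
  uorf <- structure(list(
    uorf_id = paste0("u_", spec$locus_id),
    chrom = spec$locus_id,
    start = min(uorf_blocks$start), end = max(uorf_blocks$end),
    strand = spec$strand, nt_sequence = uorf_seq,
    gene_name = spec$gene_name, n_publications = 2L,
    blocks = uorf_blocks
  ), class = "uorf_record")

  layout <- list(
    spec = spec, transcript_id = tid, exons = exons,
    utr_len = utr_len, cds_len = cds_len, tx_len = tx_len,
    gene_start = gene_start, gene_end = gene_end, chrom_len = chrom_len,
    donor = donor_site_info(spec, exon_only),
    acceptors = acceptor_site_info(spec, exon_only)
  )

  structure(list(chrom = spec$locus_id, seq = seq, annotation = annotation,
                 uorf = uorf, layout = layout),
            class = "uorf_locus")
}

ann_row <- function(spec, type, start, end, transcript_id) {
  data.frame(seqid = spec$locus_id, type = type,
             start = as.integer(start), end = as.integer(end),
             strand = spec$strand, gene_name = spec$gene_name,
             transcript_id = transcript_id,
             tag = if (type == "mRNA") "MANE" else NA_character_,
             stringsAsFactors = FALSE)
}

ann_rows <- function(spec, type, blocks, transcript_id) {
  if (nrow(blocks) == 0L) return(NULL)
  do.call(rbind, lapply(seq_len(nrow(blocks)), function(i) {
    ann_row(spec, type, blocks$start[i], blocks$end[i], transcript_id)
  }))
}

## Genomic position of the planted donor's first intronic base, if any.
donor_site_info <- function(spec, exons) {
  if (spec$plant_donor == "none") return(NULL)
  t_first_intronic <- spec$uorf_offset + spec$donor_retained + 1L
  g <- tx_to_genomic_blocks(exons, spec$strand, t_first_intronic, t_first_intronic)
  list(retained = spec$donor_retained, genomic_pos = g$start[1],
       plant = spec$plant_donor)
}

## Genomic position of the last intronic base upstream of each CDS exon
## (every CDS exon in this architecture has a preceding intron).
acceptor_site_info <- function(spec, exons) {
  utr_len <- sum(spec$utr_exon_lengths)
  starts <- utr_len + cumsum(c(0L, spec$cds_exon_lengths))
  starts <- starts[seq_along(spec$cds_exon_lengths)] + 1L  # tx pos of exon starts
  vapply(starts, function(t_fe) {
    g <- tx_to_genomic_blocks(exons, spec$strand, t_fe, t_fe)$start[1]
    if (spec$strand == "+") g - 1L else g + 1L
  }, integer(1))
}

count_exact_occurrences <- function(query, subject) {
  s <- Biostrings::DNAString(subject)
  n <- length(Biostrings::matchPattern(Biostrings::DNAString(query), s))
  n + length(Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString(query)), s))
}
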