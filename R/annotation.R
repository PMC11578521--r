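## Annotation tables are plain data.frames with columns
## seqid, type, start, end, strand, gene_name, transcript_id, tag
## (1-based closed coordinates, GFF3 semantics).

ann_of_type <- function(annotation, type) {
  annotation[annotation$type == type, , drop = FALSE]
}

tx_feature_blocks <- function(annotation, transcript_id, type) {
  rows <- annotation[annotation$type == type &
                     !is.na(annotation$transcript_id) &
                     annotation$transcript_id == transcript_id, , drop = FALSE]
  blocks_df(rows$start, rows$end)
}

## 5'UTR genomic blocks of a transcript: explicit five_prime_UTR features
## when present, otherwise exonic sequence upstream of the CDS start.
tx_utr5_blocks <- function(annotation, transcript_id, strand) {
  utr <- tx_feature_blocks(annotation, transcript_id, "five_prime_UTR")
  if (nrow(utr) > 0L) return(utr)
  exons <- tx_feature_blocks(annotation, transcript_id, "exon")
  cds <- tx_feature_blocks(annotation, transcript_id, "CDS")
  if (nrow(cds) == 0L) return(exons[0, , drop = FALSE])
  ex <- IRanges::IRanges(exons$start, exons$end)
  up <- if (strand == "+") {
    IRanges::IRanges(1L, min(cds$start) - 1L)
  } else {
    IRanges::IRanges(max(cds$end) + 1L, .Machine$integer.max)
  }
  res <- IRanges::intersect(ex, up)
  blocks_df(IRanges::start(res), IRanges::end(res))
}

blocks_contained_in <- function(blocks, container) {
  if (nrow(blocks) == 0L) return(FALSE)
  if (nrow(container) == 0L) return(FALSE)
  a <- IRanges::IRanges(blocks$start, blocks$end)
  b <- IRanges::reduce(IRanges::IRanges(container$start, container$end))
  length(IRanges::setdiff(a, b)) == 0L
}

point_in_blocks <- function(pos, blocks) {
  any(pos >= blocks$start & pos <= blocks$end)
}

#' Extract reference transcripts from an annotation
#'
#' Builds one `reference_transcript` object per annotated mRNA: ordered
#' exon and CDS chains, the spliced CDS sequence, its encoded protein
#' (terminal stop stripped), and the MANE/NMD tags read from the
#' annotation's `tag` column. CDS features are expected to include the
#' terminal stop codon.
#'
#' @param annotation Annotation data.frame (`seqid`, `type`, `start`, `end`,
#'   `strand`, `gene_name`, `transcript_id`, `tag`).
#' @param genome Named character vector of chromosome sequences.
#' @return A named list of `reference_transcript` objects keyed by
#'   transcript id, each with fields `transcript_id`, `gene_name`, `chrom`,
#'   `strand`, `exons`, `cds`, `cds_len`, `cds_seq`, `protein`, `is_mane`,
#'   `is_nmd`.
#' @export
reference_transcripts <- function(annotation, genome) {
  mrna <- ann_of_type(annotation, "mRNA")
  out <- lapply(seq_len(nrow(mrna)), function(i) {
    tid <- mrna$transcript_id[i]
    chrom <- mrna$seqid[i]
    strand <- mrna$strand[i]
    exons <- tx_feature_blocks(annotation, tid, "exon")
    cds <- tx_feature_blocks(annotation, tid, "CDS")
    cds_seq <- if (nrow(cds) > 0L) {
      extract_blocks(genome[[chrom]], cds, strand)
    } else ""
    tags <- strsplit(mrna$tag[i] %||% NA_character_, ",")[[1]]
    structure(list(
      transcript_id = tid, gene_name = mrna$gene_name[i],
      chrom = chrom, strand = strand, exons = exons, cds = cds,
      cds_len = nchar(cds_seq), cds_seq = cds_seq,
      protein = orf_protein(cds_seq),
      is_mane = isTRUE("MANE" %in% tags),
      is_nmd = isTRUE("NMD" %in% tags)
    ), class = "reference_transcript")
  })
  stats::setNames(out, mrna$transcript_id)
}

## Genomic positions of the last intronic base upstream of each internal
## CDS acceptor of a reference transcript (transcription order).
ref_acceptor_sites <- function(ref) {
  if (nrow(ref$cds) == 0L) return(integer(0))
  tx_first <- if (ref$strand == "+") min(ref$exons$start) else max(ref$exons$end)
  ord <- if (ref$strand == "+") order(ref$cds$start) else order(-ref$cds$start)
  sites <- integer(0)
  for (i in ord) {
    fe <- if (ref$strand == "+") ref$cds$start[i] else ref$cds$end[i]
    # acceptor exists only if fe opens an exon that is not the first exon
    opens_exon <- if (ref$strand == "+") fe %in% ref$exons$start
                  else fe %in% ref$exons$end
    if (opens_exon && fe != tx_first) {
      sites <- c(sites, if (ref$strand == "+") fe - 1L else fe + 1L)
    }
  }
  sites
}
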