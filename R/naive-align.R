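#' Exhaustively align a query against a small genome
#'
#' A desk-scale alignment oracle: scans both strands of every chromosome for
#' exact full-length matches of `query`. When no exact match exists and
#' `max_mismatch > 0`, reports the best near-exact full-length matches under
#' Hamming distance (no indels), up to `max_mismatch` substitutions.
#'
#' @param query Nucleotide string (non-empty).
#' @param genome Named character vector of chromosome sequences, or a
#'   `Biostrings::DNAStringSet` (precompute it when aligning many queries
#'   against the same genome).
#' @param max_mismatch Maximum Hamming distance for the near-exact fallback
#'   (default 3); `0` restricts to exact matches.
#' @return A data.frame with one row per hit: `chrom`, `start`, `end`
#'   (1-based closed), `strand`, `n_mismatch`, ordered by `n_mismatch`.
#'   Zero rows when the query is absent. An empty hit list is a valid
#'   result.
#' @export
naive_align <- function(query, genome, max_mismatch = 3L) {
  stopifnot(is.character(query), nchar(query) > 0L)
  subject <- as_dss(genome)
  exact <- align_pass(query, subject, 0L)
  if (nrow(exact) > 0L || max_mismatch == 0L) return(exact)
  near <- align_pass(query, subject, max_mismatch)
  near[order(near$n_mismatch, near$chrom, near$start), , drop = FALSE]
}

as_dss <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  stopifnot(length(genome) >= 1L)
  if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))
  Biostrings::DNAStringSet(genome)
}

align_pass <- function(query, subject, max_mismatch) {
  q_fwd <- Biostrings::DNAString(query)
  q_rev <- Biostrings::reverseComplement(q_fwd)
  out <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") q_fwd else q_rev
    m <- Biostrings::vmatchPattern(pat, subject, max.mismatch = max_mismatch,
                                   with.indels = FALSE)
    for (k in which(S4Vectors::elementNROWS(m) > 0L)) {
      r <- m[[k]]
      spans <- as.character(Biostrings::extractAt(subject[[k]], r))
      mm <- vapply(spans, function(s) {
        sum(utf8ToInt(s) != utf8ToInt(as.character(pat)))
      }, integer(1), USE.NAMES = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        chrom = names(subject)[k],
        start = IRanges::start(r), end = IRanges::end(r),
        strand = strand, n_mismatch = mm, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      n_mismatch = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Precompute the alignment index of a target genome
#'
#' Bundles a target's chromosome set, its annotated transcript sequences
#' (spliced, transcript orientation) and their exon chains, so repeated
#' conservation assessments against the same target avoid rebuilding them.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param annotation Target annotation data.frame.
#' @return A list of class `target_index`.
#' @export
build_target_index <- function(genome, annotation) {
  mrna <- ann_of_type(annotation, "mRNA")
  tx <- lapply(seq_len(nrow(mrna)), function(i) {
    tid <- mrna$transcript_id[i]
    exons <- tx_feature_blocks(annotation, tid, "exon")
    if (nrow(exons) == 0L) return(NULL)
    list(transcript_id = tid, chrom = mrna$seqid[i],
         strand = mrna$strand[i], exons = exons,
         seq = extract_blocks(genome[[mrna$seqid[i]]], exons,
                              mrna$strand[i]))
  })
  tx <- Filter(Negate(is.null), tx)
  names(tx) <- vapply(tx, `[[`, "", "transcript_id")
  tx_seqs <- vapply(tx, `[[`, "", "seq")
  structure(list(
    genome = genome,
    dss = as_dss(genome),
    tx = tx,
    tx_dss = if (length(tx_seqs)) Biostrings::DNAStringSet(tx_seqs)
             else Biostrings::DNAStringSet()
  ), class = "target_index")
}
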