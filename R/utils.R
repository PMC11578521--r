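## Internal sequence / coordinate helpers.
## Convention: all internal coordinates are 1-based, fully closed (the
## IRanges convention). Exon block tables are data.frames with `start`,
## `end` columns in ascending genomic order; transcription order is
## ascending for "+" and descending for "-".

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' @importFrom Biostrings DNAString reverseComplement translate
dna_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Literal standard-code translation: no initiator-codon special-casing,
## internal stops kept as "*", trailing partial codon dropped.
dna_translate <- function(x) {
  n <- nchar(x) - nchar(x) %% 3L
  if (n < 3L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(x, 1L, n)),
                                     no.init.codon = TRUE))
}

## Protein encoded by a complete ORF: translation minus the terminal stop.
orf_protein <- function(x) {
  p <- dna_translate(x)
  sub("\\*$", "", p)
}

subseq_str <- function(seq, start, end) {
  stopifnot(start >= 1L, end <= nchar(seq), end >= start)
  substr(seq, start, end)
}

## Replace bases in place, returning the modified string.
replace_str <- function(seq, start, replacement) {
  stopifnot(start >= 1L, start + nchar(replacement) - 1L <= nchar(seq))
  paste0(substr(seq, 1L, start - 1L), replacement,
         substr(seq, start + nchar(replacement), nchar(seq)))
}

blocks_df <- function(start, end) {
  df <- data.frame(start = as.integer(start), end = as.integer(end))
  stopifnot(all(df$end >= df$start))
  df[order(df$start), , drop = FALSE]
}

blocks_width <- function(blocks) sum(blocks$end - blocks$start + 1L)

## Spliced sequence of a block chain, read 5'->3' on `strand`.
extract_blocks <- function(seq, blocks, strand) {
  parts <- mapply(function(s, e) substr(seq, s, e), blocks$start, blocks$end)
  out <- paste(parts, collapse = "")
  if (strand == "-") out <- dna_revcomp(out)
  out
}

## Map a transcript-coordinate interval [t_start, t_end] (1-based along the
## spliced transcript, 5'->3') to genomic blocks through an exon chain.
tx_to_genomic_blocks <- function(exons, strand, t_start, t_end) {
  stopifnot(t_start >= 1L, t_end >= t_start)
  widths <- exons$end - exons$start + 1L
  if (t_end > sum(widths)) {
    stop("transcript interval [", t_start, ",", t_end,
         "] extends past the transcript end (", sum(widths), " nt)")
  }
  ord <- if (strand == "+") seq_len(nrow(exons)) else rev(seq_len(nrow(exons)))
  res_s <- integer(0)
  res_e <- integer(0)
  off <- 0L
  for (i in ord) {
    w <- widths[i]
    s <- off + 1L
    e <- off + w
    ov_s <- max(s, t_start)
    ov_e <- min(e, t_end)
    if (ov_s <= ov_e) {
      if (strand == "+") {
        gs <- exons$start[i] + (ov_s - s)
        ge <- exons$start[i] + (ov_e - s)
      } else {
        ge <- exons$end[i] - (ov_s - s)
        gs <- exons$end[i] - (ov_e - s)
      }
      res_s <- c(res_s, gs)
      res_e <- c(res_e, ge)
    }
    off <- off + w
  }
  blocks_df(res_s, res_e)
}

## Transcript coordinate of a genomic position through an exon chain,
## or NA if the position is intronic/outside.
genomic_to_tx_pos <- function(exons, strand, gpos) {
  ord <- if (strand == "+") seq_len(nrow(exons)) else rev(seq_len(nrow(exons)))
  off <- 0L
  for (i in ord) {
    w <- exons$end[i] - exons$start[i] + 1L
    if (gpos >= exons$start[i] && gpos <= exons$end[i]) {
      d <- if (strand == "+") gpos - exons$start[i] else exons$end[i] - gpos
      return(off + d + 1L)
    }
    off <- off + w
  }
  NA_integer_
}

## Gap in bp between an interval and a block set; 0 when they overlap.
interval_gap <- function(start, end, b_start, b_end) {
  if (end >= b_start && start <= b_end) return(0L)
  if (end < b_start) b_start - end - 1L else start - b_end - 1L
}

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

## n/3 stop-free codons (the uORF/CDS body alphabet).
random_codons <- function(n_codons) {
  if (n_codons == 0L) return("")
  pool <- setdiff(mkAllStrings_codons(), STOP_CODONS)
  paste(sample(pool, n_codons, replace = TRUE), collapse = "")
}

mkAllStrings_codons <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      g <- expand.grid(DNA_BASES, DNA_BASES, DNA_BASES, stringsAsFactors = FALSE)
      memo <<- paste0(g[[3]], g[[2]], g[[1]])
    }
    memo
  }
})

`%||%` <- function(a, b) if (is.null(a)) b else a
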