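## Independent test oracles (no Biostrings): brute-force alignment and a
## literal codon-table translator, plus a fully hand-specified toy locus.

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

ORACLE_CODONS <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

oracle_translate <- function(nt) {
  n <- nchar(nt) - nchar(nt) %% 3
  if (n < 3) return("")
  codons <- substring(nt, seq(1, n, 3), seq(3, n, 3))
  paste(ORACLE_CODONS[codons], collapse = "")
}

## Protein of a complete ORF: literal translation minus the terminal stop.
oracle_orf_protein <- function(nt) sub("\\*$", "", oracle_translate(nt))

## Six-frame protein match: does any frame of either strand of `target`
## translate to exactly the query ORF's protein?
oracle_six_frame_match <- function(query_nt, target_nt) {
  qp <- oracle_orf_protein(query_nt)
  if (!nzchar(qp)) return(FALSE)
  for (s in c(target_nt, oracle_revcomp(target_nt))) {
    for (f in 0:2) {
      if (nchar(s) - f < 3) next
      tp <- sub("\\*$", "", oracle_translate(substr(s, 1 + f, nchar(s))))
      if (identical(tp, qp)) return(TRUE)
    }
  }
  FALSE
}

## Brute-force full-length search on both strands of every chromosome:
## exact matches first; otherwise best Hamming matches up to `k`.
oracle_search <- function(query, genome, k = 0) {
  qs <- list(`+` = utf8ToInt(query), `-` = utf8ToInt(oracle_revcomp(query)))
  n <- nchar(query)
  scan <- function(kk) {
    hits <- list()
    for (chrom in names(genome)) {
      s <- utf8ToInt(genome[[chrom]])
      if (length(s) < n) next
      for (strand in c("+", "-")) {
        q <- qs[[strand]]
        for (off in 0:(length(s) - n)) {
          mm <- sum(s[off + seq_len(n)] != q)
          if (mm <= kk) {
            hits[[length(hits) + 1]] <- data.frame(
              chrom = chrom, start = as.integer(off + 1),
              end = as.integer(off + n), strand = strand,
              n_mismatch = as.integer(mm), stringsAsFactors = FALSE)
          }
        }
      }
    }
    if (length(hits) == 0) return(NULL)
    do.call(rbind, hits)
  }
  exact <- scan(0)
  if (!is.null(exact) || k == 0) return(exact)
  near <- scan(k)
  if (is.null(near)) return(NULL)
  near[order(near$n_mismatch, near$chrom, near$start), , drop = FALSE]
}

random_test_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## A fully hand-specified toy locus for builder tests. Geometry (+ strand):
##   flank 1..50 | UTR exon 51..80 | intron 81..100 | CDS exon1 101..109 |
##   intron 110..129 | CDS exon2 130..159 | flank 160..199
## uORF "ATGGCAGTTTAA" at 61..72 with a GT donor at uORF-local 7 (genomic
## 67); the linking junction splices 67..129 (acceptor at 129, first
## exonic base 130), giving CDS "ATGGCA" + exon2 (36 nt).
toy_locus <- function(strand = "+") {
  utr <- paste0(strrep("T", 10), "ATGGCAGTTTAA", strrep("T", 8))
  intron <- paste0("GT", strrep("C", 10), "CCCTTTAG")
  cds1 <- "ATGCCCAAA"
  cds2 <- "GGCGATAAGGATTTTCCCGGGAAACCCTGA"
  seq <- paste0(strrep("C", 50), utr, intron, cds1, intron, cds2,
                strrep("A", 40))
  ann <- data.frame(
    seqid = "chrT",
    type = c("gene", "mRNA", "exon", "exon", "exon", "five_prime_UTR",
             "CDS", "CDS"),
    start = c(51, 51, 51, 101, 130, 51, 101, 130),
    end = c(159, 159, 80, 109, 159, 80, 109, 159),
    strand = "+", gene_name = "TOY",
    transcript_id = c(NA, rep("toy_t1", 7)),
    tag = c(NA, "MANE", rep(NA, 6)), stringsAsFactors = FALSE)
  uorf <- structure(list(
    uorf_id = "u_toy", chrom = "chrT", start = 61, end = 72, strand = "+",
    nt_sequence = "ATGGCAGTTTAA", gene_name = "TOY", n_publications = 2,
    blocks = data.frame(start = 61, end = 72)), class = "uorf_record")
  junction <- data.frame(chrom = "chrT", donor = 67, acceptor = 129,
                         strand = "+", evidence = "experimental",
                         support = 200, stringsAsFactors = FALSE)
  loc <- list(genome = c(chrT = seq), annotation = ann, uorf = uorf,
              junction = junction,
              expected_cds = paste0("ATGGCA", cds2))
  if (strand == "-") mirror_toy(loc) else loc
}

## Reverse-complement mirror of a toy-style locus: coordinates flip to
## L - x + 1, strands flip, donors/acceptors stay "first/last intronic
## base in transcription order".
mirror_toy <- function(loc) {
  L <- nchar(loc$genome[[1]])
  flip <- function(x) L - x + 1
  ann <- loc$annotation
  tmp <- flip(ann$end); ann$end <- flip(ann$start); ann$start <- tmp
  ann$strand <- ifelse(ann$strand == "+", "-", "+")
  u <- loc$uorf
  b <- data.frame(start = flip(u$blocks$end), end = flip(u$blocks$start))
  u$blocks <- b[order(b$start), , drop = FALSE]
  u$start <- min(u$blocks$start); u$end <- max(u$blocks$end)
  u$strand <- "-"
  j <- loc$junction
  j$donor <- flip(j$donor); j$acceptor <- flip(j$acceptor); j$strand <- "-"
  list(genome = stats::setNames(oracle_revcomp(loc$genome[[1]]),
                                names(loc$genome)),
       annotation = ann, uorf = u, junction = j,
       expected_cds = loc$expected_cds)
}
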