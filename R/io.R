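#' Write a genome to FASTA
#'
#' @param genome Named character vector of chromosome sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(as_dss(genome), path)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write an annotation table as GFF3
#'
#' Coordinates are written as stored (1-based closed, the GFF3
#' convention). Feature IDs and Parent links follow the usual
#' gene/mRNA/child layout; `gene_name` and MANE/NMD tags travel as
#' attributes.
#'
#' @param annotation Annotation data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  lines <- "##gff-version 3"
  counters <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(annotation))) {
    a <- annotation[i, ]
    attrs <- switch(a$type,
      gene = paste0("ID=gene:", a$gene_name, ";gene_name=", a$gene_name),
      mRNA = paste0("ID=transcript:", a$transcript_id,
                    ";Parent=gene:", a$gene_name,
                    ";gene_name=", a$gene_name,
                    if (!is.na(a$tag)) paste0(";tag=", a$tag) else ""),
      {
        key <- paste0(a$type, ":", a$transcript_id)
        n <- (counters[[key]] %||% 0L) + 1L
        counters[[key]] <- n
        paste0("ID=", key, ":", n, ";Parent=transcript:", a$transcript_id,
               ";gene_name=", a$gene_name)
      })
    lines <- c(lines, paste(a$seqid, "uorfexonizer", a$type, a$start, a$end,
                            ".", a$strand, ".", attrs, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFF3 annotation into the package's annotation table
#'
#' @param path GFF3 file.
#' @return Annotation data.frame (`seqid`, `type`, `start`, `end`,
#'   `strand`, `gene_name`, `transcript_id`, `tag`).
#' @export
read_annotation_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GFF3 requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  parent <- vapply(df$Parent %||% rep(list(character(0)), nrow(df)),
                   function(p) if (length(p)) p[[1]] else NA_character_, "")
  tid <- ifelse(df$type == "mRNA", sub("^transcript:", "", df$ID),
                ifelse(!is.na(parent) & startsWith(parent, "transcript:"),
                       sub("^transcript:", "", parent), NA_character_))
  data.frame(seqid = as.character(df$seqnames), type = as.character(df$type),
             start = df$start, end = df$end,
             strand = as.character(df$strand),
             gene_name = df$gene_name,
             transcript_id = tid,
             tag = if ("tag" %in% names(df)) as.character(df$tag)
                   else NA_character_,
             stringsAsFactors = FALSE)
}

encode_blocks <- function(blocks) {
  paste(blocks$start, blocks$end, sep = "-", collapse = ";")
}

decode_blocks <- function(x) {
  parts <- strsplit(strsplit(x, ";")[[1]], "-")
  blocks_df(vapply(parts, function(p) as.integer(p[1]), integer(1)),
            vapply(parts, function(p) as.integer(p[2]), integer(1)))
}

#' Write a uORF catalogue as TSV
#'
#' Columns: `uorf_id`, `chrom`, `start`, `end` (1-based closed), `strand`,
#' `sequence`, `gene_name`, `n_publications`, `blocks`
#' (`start-end;start-end` for spliced uORFs).
#'
#' @param uorfs List of `uorf_record`s.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_uorf_catalogue <- function(uorfs, path) {
  df <- do.call(rbind, lapply(uorfs, function(u) {
    data.frame(uorf_id = u$uorf_id, chrom = u$chrom, start = u$start,
               end = u$end, strand = u$strand, sequence = u$nt_sequence,
               gene_name = u$gene_name, n_publications = u$n_publications,
               blocks = encode_blocks(u$blocks), stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a uORF catalogue TSV
#'
#' @param path TSV written by [write_uorf_catalogue()].
#' @return List of `uorf_record`s.
#' @export
read_uorf_catalogue <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    structure(list(
      uorf_id = df$uorf_id[i], chrom = df$chrom[i], start = df$start[i],
      end = df$end[i], strand = df$strand[i], nt_sequence = df$sequence[i],
      gene_name = df$gene_name[i], n_publications = df$n_publications[i],
      blocks = decode_blocks(df$blocks[i])
    ), class = "uorf_record")
  })
}

#' Read alignment records from a PAF file
#'
#' Parses the 12 mandatory PAF columns (minimap2 dialect; 0-based
#' half-open target coordinates, converted to the package's 1-based
#' closed convention at this boundary). Only full-length query hits can
#' satisfy the sequence-match criterion, so `query_coverage` is reported
#' for filtering; the residue-match count stands in for the mismatch
#' count as `n_mismatch = alignment block length - residue matches`.
#'
#' @param path PAF file.
#' @return data.frame with `query`, `chrom`, `start`, `end`, `strand`,
#'   `n_mismatch`, `query_coverage`.
#' @export
read_alignments_paf <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stopifnot(ncol(df) >= 12L)
  data.frame(
    query = df[[1]],
    chrom = df[[6]],
    start = as.integer(df[[8]]) + 1L,
    end = as.integer(df[[9]]),
    strand = df[[5]],
    n_mismatch = as.integer(df[[11]]) - as.integer(df[[10]]),
    query_coverage = (as.integer(df[[4]]) - as.integer(df[[3]])) /
      as.integer(df[[2]]),
    stringsAsFactors = FALSE
  )
}

#' Write junction evidence as TSV
#'
#' @param junctions Junction data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_junctions_tsv <- function(junctions, path) {
  utils::write.table(junctions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read junction evidence from TSV
#'
#' @param path TSV written by [write_junctions_tsv()].
#' @return Junction data.frame.
#' @export
read_junctions_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a cohort's on-disk artifacts
#'
#' Writes the reference and individual genomes (FASTA), annotations
#' (GFF3), uORF catalogue, junction evidence, planted confidence targets
#' and truth tables (TSV) under `outdir`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  write_genome_fasta(cohort$reference$genome, p("reference.fa"))
  write_annotation_gff3(cohort$reference$annotation, p("reference.gff3"))
  write_uorf_catalogue(cohort$uorfs, p("uorfs.tsv"))
  write_junctions_tsv(cohort$junctions, p("junctions.tsv"))
  for (g in names(cohort$targets)) {
    write_genome_fasta(cohort$targets[[g]]$genome, p(paste0(g, ".fa")))
    write_annotation_gff3(cohort$targets[[g]]$annotation,
                          p(paste0(g, ".gff3")))
  }
  utils::write.table(cohort$plddt_targets, p("plddt_targets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth$conservation, p("truth_conservation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth$uorf, p("truth_uorf.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' Write the pipeline's stage tables
#'
#' Emits the per-uORF conservation assessments, per-genome level counts,
#' intersection counts, the construct table (with separate files for
#' non-AUG and reference-duplicate constructs), the construct protein
#' FASTA, structure comparisons, and the run summary.
#'
#' @param result A `uorf_pipeline_result`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_pipeline_tables <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  w <- function(df, name) {
    utils::write.table(df, p(name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  w(result$assessments, "conservation_assessments.tsv")
  w(result$conservation_summary$per_level, "conservation_levels.tsv")
  w(result$conservation_summary$intersections,
    "conservation_intersections.tsv")
  w(result$constructs, "constructs.tsv")
  w(result$constructs[result$constructs$valid &
                        result$constructs$start_codon_class == "non_AUG", ],
    "constructs_non_aug.tsv")
  w(result$constructs[result$constructs$valid &
                        result$constructs$duplicate_of_reference, ],
    "constructs_reference_duplicates.tsv")
  valid <- result$constructs[result$constructs$valid, ]
  if (nrow(valid) > 0L) {
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(stats::setNames(valid$protein,
                                              valid$construct_id)),
      p("construct_proteins.fa"))
  }
  w(result$comparisons, "structure_comparisons.tsv")
  w(result$final, "final_constructs.tsv")
  s <- result$summary
  scalar <- vapply(s, function(x) length(x) == 1L && !is.list(x), logical(1))
  w(data.frame(key = names(s)[scalar],
               value = vapply(s[scalar], as.character, ""),
               stringsAsFactors = FALSE), "run_summary.tsv")
  invisible(outdir)
}
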