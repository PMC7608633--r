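#' Write a synthetic genome to disk
#'
#' Emits the chromosome sequences and TE consensus library as FASTA, the
#' TE annotation (and any planted de novo insertions) as BED, and the
#' gene annotation as GFF3 (1-based closed, per the standard; all
#' in-memory coordinates stay 0-based half-open).
#'
#' @param genome a `synth_genome`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             te_library = file.path(dir, "te_library.fa"),
             tes = file.path(dir, "te_annotation.bed"),
             genes = file.path(dir, "genes.gff3"),
             insertions = file.path(dir, "insertions_truth.bed"))
  Biostrings::writeXStringSet(genome$seq, paths["genome"])
  Biostrings::writeXStringSet(genome$te_library, paths["te_library"])
  ann <- genome$annotation
  write_bed(data.frame(chrom = ann$tes$chrom, start = ann$tes$start,
                       end = ann$tes$end, name = ann$tes$family,
                       score = 0L, strand = ann$tes$strand),
            paths["tes"])
  write_gff3_genes(ann$genes, paths["genes"])
  ins <- genome$truth$insertions
  write_bed(data.frame(chrom = ins$chrom, start = ins$pos,
                       end = ins$pos + 1L,
                       name = paste(ins$ins_id, ins$family,
                                    ins$sample_id, sep = ";"),
                       score = ins$cell_fraction, strand = "+"),
            paths["insertions"])
  invisible(paths)
}

write_bed <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

write_gff3_genes <- function(genes, path) {
  con <- file(path, "w")
  writeLines("##gff-version 3", con)
  if (nrow(genes) > 0) {
    rows <- sprintf("%s\tsynth\tgene\t%d\t%d\t.\t%s\t.\tID=%s;zygotic=%s",
                    genes$chrom, genes$start + 1L, genes$end,
                    genes$strand, genes$gene_id,
                    tolower(genes$zygotic))
    writeLines(rows, con)
  }
  close(con)
}

#' Write simulated reads as FASTQ
#'
#' Reconstructs read sequences from their alignment records (genome reads
#' from the chromosome sequence, TE reads from the family consensus;
#' minus-strand reads reverse-complemented) for end-to-end runs with a
#' real aligner. Reads emitted as unaligned (junction-straddling) carry
#' no alignment record and are omitted; the precomputed-alignment path is
#' the complete one.
#'
#' @param read_set a [simulate_dna_reads()] result.
#' @param genome the `synth_genome` the reads were simulated from.
#' @param path output FASTQ file.
#' @return invisibly, the number of reads written.
#' @export
write_reads_fastq <- function(read_set, genome, path) {
  g <- read_set$genome
  gseq <- Biostrings::DNAStringSet(vapply(seq_len(nrow(g)), function(i) {
    as.character(Biostrings::subseq(genome$seq[[g$chrom[i]]],
                                    g$start[i] + 1L, g$end[i]))
  }, ""))
  t <- read_set$te
  tseq <- Biostrings::DNAStringSet(vapply(seq_len(nrow(t)), function(i) {
    as.character(Biostrings::subseq(genome$te_library[[t$family[i]]],
                                    t$start[i] + 1L, t$end[i]))
  }, ""))
  seqs <- c(gseq, tseq)
  strands <- c(g$strand, t$strand)
  neg <- strands == "-"
  if (any(neg)) seqs[neg] <- Biostrings::reverseComplement(seqs[neg])
  names(seqs) <- paste0(c(g$qname, t$qname), "/", c(g$mate, t$mate))
  Biostrings::writeXStringSet(seqs, path, format = "fastq")
  invisible(length(seqs))
}

#' Write or read a count table as TSV
#'
#' Features in rows (first column `feature_id`, second `feature_class`),
#' one column per sample thereafter.
#'
#' @param tab a `count_table`.
#' @param path TSV path.
#' @return `write_counts_tsv`: invisibly, the path; `read_counts_tsv`:
#'   a `count_table`.
#' @export
write_counts_tsv <- function(tab, path) {
  df <- data.frame(feature_id = rownames(tab$counts),
                   feature_class = tab$feature_class,
                   tab$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @param state normalization state to stamp on the table read back.
#' @export
read_counts_tsv <- function(path, state = "raw") {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- df$feature_id
  count_table(m, feature_class = df$feature_class, state = state)
}

#' Write an enrichment track as bedGraph
#'
#' @param track an `enrichment_track`.
#' @param path output path; missing windows are written as `NA` in a
#'   comment-free four-column bedGraph.
#' @export
write_track_bedgraph <- function(track, path) {
  write_bed(data.frame(chrom = track$chrom, start = track$start,
                       end = track$end, value = track$value), path)
  invisible(path)
}
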