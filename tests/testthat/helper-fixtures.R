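# Small in-code fixture builders shared across test files.

# a bare gene table row with sensible defaults
gene_row <- function(id, start, end, strand = "+", chrom = "1",
                     name = id, biotype = "protein_coding",
                     source = "reference") {
  data.table::data.table(gene_id = id, gene_name = name, biotype = biotype,
                         chrom = chrom, start = start, end = end,
                         strand = strand, source = source,
                         augmented = FALSE, parent_id = NA_character_)
}

# an annotation where each gene has one single-exon transcript spanning it
simple_annotation <- function(genes, chrom_sizes = NULL) {
  tx <- data.table::data.table(
    transcript_id = paste0(genes$gene_id, ".t1"), gene_id = genes$gene_id,
    chrom = genes$chrom, start = genes$start, end = genes$end,
    strand = genes$strand, source = genes$source[1])
  ex <- tx[, .(transcript_id, chrom, start, end, strand)]
  annotation(genes = genes, transcripts = tx, exons = ex,
             chrom_sizes = chrom_sizes)
}

# write GTF text lines to a temp file, return the path
write_gtf_text <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gtf",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

gtf_line <- function(chrom, feature, start, end, strand, attrs) {
  paste(chrom, "test", feature, start, end, ".", strand, ".", attrs,
        sep = "\t")
}

# semantic equality of two annotations: same gene table (modulo row order),
# same transcript spans, same exon coordinate sets
expect_annotation_equal <- function(a, b) {
  ga <- data.table::setorder(data.table::copy(a$genes), gene_id)
  gb <- data.table::setorder(data.table::copy(b$genes), gene_id)
  expect_equal(ga[, .(gene_id, gene_name, biotype, chrom, start, end, strand)],
               gb[, .(gene_id, gene_name, biotype, chrom, start, end, strand)])
  ta <- data.table::setorder(data.table::copy(a$transcripts), transcript_id)
  tb <- data.table::setorder(data.table::copy(b$transcripts), transcript_id)
  expect_equal(ta[, .(transcript_id, gene_id, chrom, start, end, strand)],
               tb[, .(transcript_id, gene_id, chrom, start, end, strand)])
  ea <- data.table::setorder(data.table::copy(a$exons),
                             transcript_id, start, end)
  eb <- data.table::setorder(data.table::copy(b$exons),
                             transcript_id, start, end)
  expect_equal(ea, eb)
}

# run the full pipeline on a simulated pair, returning everything
run_pipeline <- function(sim, max_kb = 10L, step_kb = 1L) {
  ref_f <- filter_biotypes(sim$reference)
  cls <- classify_transcripts(sim$novel, ref_f)
  merged <- merge_transcripts(ref_f, sim$novel, cls)
  ext <- add_extension_genes(merged$annotation, max_kb = max_kb,
                             step_kb = step_kb)
  list(filtered = ref_f, classified = cls, merged = merged,
       extended = ext)
}
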