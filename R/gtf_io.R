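# GTF reading/writing. On disk GTF is 1-based inclusive; internally
# everything is 0-based half-open: internal (start, end) = (gtf_start - 1,
# gtf_end), an exact bijection.

GTF_FEATURES <- c("gene", "transcript", "exon")

# Pull one attribute value out of a vector of GTF attribute strings.
# Accepts Ensembl style (key "value"; ) and a lenient unquoted dialect
# (key value;). Returns NA where absent.
extract_attr <- function(attrs, key) {
  pat <- paste0("(^|;)\\s*", key, "\\s+\"?([^\";]*)\"?\\s*(;|$)")
  m <- regexpr(pat, attrs, perl = TRUE)
  out <- rep(NA_character_, length(attrs))
  hit <- m > 0
  if (any(hit)) {
    st <- attr(m, "capture.start")[hit, 2L]
    len <- attr(m, "capture.length")[hit, 2L]
    out[hit] <- substr(attrs[hit], st, st + len - 1L)
  }
  out
}

#' Read a GTF file into an annotation
#'
#' Parses `gene`, `transcript` and `exon` records (other feature types are
#' ignored), converts coordinates to the internal 0-based half-open
#' convention and assembles the gene/transcript/exon hierarchy. Gene records
#' absent from the file (common in long-read GTFs) are synthesized from
#' transcript envelopes; transcript records absent for a `transcript_id`
#' seen on exon lines are synthesized from exon envelopes. Missing
#' `gene_name` defaults to the `gene_id`; missing `gene_biotype` to `""`.
#'
#' Records with strand `"."` are rejected: the downstream merge/extension
#' method is strand-dependent and guessing a strand would corrupt it.
#' Duplicate `gene_id`s (e.g. reused across chromosomes) are a hard error;
#' duplicated exon records are merged with a warning.
#'
#' @param path Path to a GTF file (plain text; `#` comment lines allowed).
#' @param source_label `"reference"` or `"novel"`; recorded on every gene
#'   and transcript.
#' @return An [annotation()] object.
#' @seealso [write_gtf()], [filter_biotypes()]
#' @export
read_gtf <- function(path, source_label = c("reference", "novel")) {
  source_label <- match.arg(source_label)
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(annotation(provenance = paste0("read_gtf(", basename(path), ", empty)")))
  fields <- tstrsplit(lines, "\t", fixed = TRUE)
  if (length(fields) < 9L)
    stop("malformed GTF: expected 9 tab-separated columns (line ",
         line_no[1L], ")")
  dt <- data.table(chrom = fields[[1]], feature = fields[[3]],
                   start = suppressWarnings(as.numeric(fields[[4]])),
                   end = suppressWarnings(as.numeric(fields[[5]])),
                   strand = fields[[7]], attrs = fields[[9]],
                   line_no = line_no)
  dt <- dt[feature %in% GTF_FEATURES]
  if (!nrow(dt))
    return(annotation(provenance = paste0("read_gtf(", basename(path), ", no records)")))

  bad <- dt[is.na(start) | is.na(end) | start > end | start < 1]
  if (nrow(bad))
    stop("malformed coordinates at line ", bad$line_no[1L],
         ": start=", bad$start[1L], " end=", bad$end[1L])
  # 1-based inclusive -> 0-based half-open
  dt[, start := start - 1]

  bad <- dt[!strand %in% c("+", "-")]
  if (nrow(bad))
    stop("unstranded or invalid strand '", bad$strand[1L],
         "' on ", bad$feature[1L], " record at line ", bad$line_no[1L],
         "; the method is strand-dependent and cannot guess")

  dt[, gene_id := extract_attr(attrs, "gene_id")]
  dt[, transcript_id := extract_attr(attrs, "transcript_id")]
  if (anyNA(dt$gene_id))
    stop("record without gene_id attribute at line ",
         dt$line_no[is.na(dt$gene_id)][1L])
  if (anyNA(dt[feature != "gene", transcript_id]))
    stop("transcript/exon record without transcript_id attribute at line ",
         dt[feature != "gene" & is.na(transcript_id), line_no][1L])

  ex <- dt[feature == "exon",
           .(transcript_id, chrom, start, end, strand, gene_id)]
  tx <- dt[feature == "transcript",
           .(transcript_id, gene_id, chrom, start, end, strand)]
  gn <- dt[feature == "gene"]

  # synthesize transcript records from exon envelopes where missing
  orphan_ids <- setdiff(ex$transcript_id, tx$transcript_id)
  if (length(orphan_ids)) {
    orphan_tx <- ex[transcript_id %in% orphan_ids,
                    .(gene_id = gene_id[1L], chrom = chrom[1L],
                      start = min(start), end = max(end),
                      strand = strand[1L]),
                    by = transcript_id]
    tx <- rbind(tx, orphan_tx, use.names = TRUE)
  }
  if (anyDuplicated(tx$transcript_id))
    stop("duplicate transcript record: ",
         tx$transcript_id[duplicated(tx$transcript_id)][1L])

  # each transcript's exons must agree on chrom and strand
  if (nrow(ex)) {
    chk <- ex[, .(nc = uniqueN(chrom), ns = uniqueN(strand)), by = transcript_id]
    if (any(chk$nc > 1L | chk$ns > 1L))
      stop("exons of transcript ", chk[nc > 1L | ns > 1L, transcript_id][1L],
           " disagree on chromosome or strand")
  }
  # grow transcript spans to their exon envelope if needed
  if (nrow(ex)) {
    env <- ex[, .(e_start = min(start), e_end = max(end)), by = transcript_id]
    tx[env, on = "transcript_id",
       `:=`(start = pmin(start, e_start), end = pmax(end, e_end))]
  }
  tx[, source := source_label]

  # gene table: explicit records, plus synthesis from transcript envelopes
  genes <- gn[, .(gene_id,
                  gene_name = extract_attr(attrs, "gene_name"),
                  biotype = extract_attr(attrs, "gene_biotype"),
                  chrom, start, end, strand)]
  tx_env <- if (nrow(tx))
    tx[, .(chrom = chrom[1L], start = min(start), end = max(end),
           strand = strand[1L], n_chrom = uniqueN(chrom),
           n_strand = uniqueN(strand)), by = gene_id]
  else
    data.table(gene_id = character(), chrom = character(), start = numeric(),
               end = numeric(), strand = character(), n_chrom = integer(),
               n_strand = integer())
  if (any(tx_env$n_chrom > 1L | tx_env$n_strand > 1L))
    stop("transcripts of gene ",
         tx_env[n_chrom > 1L | n_strand > 1L, gene_id][1L],
         " disagree on chromosome or strand (duplicate gene_id across ",
         "chromosomes is not supported)")
  synth <- tx_env[!gene_id %in% genes$gene_id,
                  .(gene_id, gene_name = NA_character_,
                    biotype = NA_character_, chrom, start, end, strand)]
  genes <- rbind(genes, synth, use.names = TRUE)
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in GTF: ",
         genes$gene_id[duplicated(genes$gene_id)][1L])
  # gene spans must cover their transcript envelopes; explicit gene lines
  # narrower than their transcripts are widened
  genes[tx_env, on = "gene_id", `:=`(start = pmin(start, i.start),
                                     end = pmax(end, i.end))]
  # transcripts must resolve to a gene on the same chromosome/strand
  chk <- tx[genes, on = "gene_id", nomatch = NULL,
            .(transcript_id, ok = chrom == i.chrom & strand == i.strand)]
  if (nrow(chk) && !all(chk$ok))
    stop("transcript ", chk[!(ok), transcript_id][1L],
         " lies on a different chromosome/strand than its gene")
  genes[is.na(gene_name), gene_name := gene_id]
  genes[is.na(biotype), biotype := ""]
  genes[, `:=`(source = source_label, augmented = FALSE,
               parent_id = NA_character_)]

  ex <- normalize_exons(ex[, .(transcript_id, chrom, start, end, strand)])
  annotation(genes = genes, transcripts = tx, exons = ex,
             provenance = paste0("read_gtf(", basename(path), ", ",
                                 source_label, ")"))
}

#' Write an annotation to a GTF file
#'
#' Emits gene, transcript and exon records in 1-based inclusive GTF with
#' Ensembl-style attributes (`gene_id`, `gene_name`, `gene_biotype`,
#' `transcript_id`). Output is fully deterministic: genes ordered by
#' (chromosome, start, gene_id), each followed by its transcripts ordered by
#' (start, transcript_id) and their exons by start; two calls on the same
#' annotation produce byte-identical files.
#'
#' @param ann An [annotation()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  g <- copy(ann$genes)[order(chrom, start, gene_id)]
  tx <- copy(ann$transcripts)
  ex <- copy(ann$exons)
  con <- file(path, open = "wb")  # binary: identical bytes on all platforms
  on.exit(close(con))
  out <- character(0)
  gtf_line <- function(chrom, feat, start, end, strand, attrs) {
    paste(chrom, "annoext", feat,
          format(start + 1, scientific = FALSE, trim = TRUE),
          format(end, scientific = FALSE, trim = TRUE),
          ".", strand, ".", attrs, sep = "\t")
  }
  for (i in seq_len(nrow(g))) {
    gr <- g[i]
    gattr <- sprintf('gene_id "%s"; gene_name "%s"; gene_biotype "%s";',
                     gr$gene_id, gr$gene_name, gr$biotype)
    out <- c(out, gtf_line(gr$chrom, "gene", gr$start, gr$end, gr$strand, gattr))
    gtx <- tx[gene_id == gr$gene_id][order(start, transcript_id)]
    for (j in seq_len(nrow(gtx))) {
      tr <- gtx[j]
      tattr <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s"; gene_biotype "%s";',
                       gr$gene_id, tr$transcript_id, gr$gene_name, gr$biotype)
      out <- c(out, gtf_line(tr$chrom, "transcript", tr$start, tr$end,
                             tr$strand, tattr))
      tex <- ex[transcript_id == tr$transcript_id][order(start)]
      for (k in seq_len(nrow(tex))) {
        er <- tex[k]
        out <- c(out, gtf_line(er$chrom, "exon", er$start, er$end, er$strand,
                               tattr))
      }
    }
  }
  writeLines(out, con, sep = "\n")
  invisible(path)
}

#' Remove genes of excluded biotypes
#'
#' Returns a copy of the annotation with every gene whose biotype is in
#' `excluded` removed along with its transcripts and exons; surviving genes
#' are untouched. The default exclusion set removes pseudogenes, whose
#' presence would otherwise soak up transcripts and block downstream
#' extensions for genuinely expressed genes.
#'
#' @param ann An [annotation()] object (typically the reference).
#' @param excluded Character vector of biotype strings to drop; default
#'   `c("pseudogene", "processed_pseudogene")`. Matching is exact: other
#'   pseudogene subtypes (e.g. `transcribed_pseudogene`) are retained unless
#'   listed explicitly.
#' @return A filtered [annotation()].
#' @export
filter_biotypes <- function(ann,
                            excluded = c("pseudogene", "processed_pseudogene")) {
  drop_ids <- ann$genes[biotype %in% excluded, gene_id]
  genes <- ann$genes[!gene_id %in% drop_ids]
  tx <- ann$transcripts[!gene_id %in% drop_ids]
  ex <- ann$exons[transcript_id %in% tx$transcript_id]
  annotation(genes = genes, transcripts = tx, exons = ex,
             chrom_sizes = ann$chrom_sizes,
             provenance = c(ann$provenance,
                            paste0("filter_biotypes(-", length(drop_ids),
                                   " genes: ",
                                   paste(excluded, collapse = ","), ")")))
}

#' Read a chromosome-sizes table
#'
#' @param path Headerless two-column TSV: chromosome name, length in bp.
#' @return Named numeric vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t",
              col.names = c("chrom", "length"))
  if (any(dt$length <= 0)) stop("non-positive chromosome length in ", path)
  stats::setNames(as.numeric(dt$length), dt$chrom)
}
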