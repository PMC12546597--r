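# Associate each novel (long-read) transcript with at most one same-strand
# reference gene by exonic overlap, and assign a simplified class code.
# This stands in for a reference-guided transcript comparison step: the
# association rule is "any same-strand exonic overlap of at least
# min_overlap bp associates"; antisense and intergenic transcripts never
# associate.

CLASS_CODES <- c("equal", "contained", "extends", "novel_isoform",
                 "antisense", "intergenic")

#' Exonic overlap between a transcript and a gene
#'
#' Number of genomic bases shared between the union of the transcript's
#' exons and the union of exonic bases over all of the gene's transcripts.
#' Zero when strands or chromosomes differ.
#'
#' @param t A transcript as returned by [get_transcript()].
#' @param g A gene as returned by [get_gene()].
#' @return Integer number of shared bases.
#' @export
exonic_overlap <- function(t, g) {
  tr <- t$transcript
  if (tr$strand != g$gene$strand || tr$chrom != g$gene$chrom) return(0)
  tex <- merge_intervals(t$exons[, .(chrom, start, end, strand)])
  gex <- g$exon_union
  if (!nrow(tex) || !nrow(gex)) return(0)
  total <- 0
  for (i in seq_len(nrow(tex))) {
    ov <- pmin(gex$end, tex$end[i]) - pmax(gex$start, tex$start[i])
    total <- total + sum(ov[ov > 0])
  }
  as.integer(total)
}

# exon-chain keys per transcript: identical keys <=> identical exon chains
chain_keys <- function(ex_dt) {
  o <- ex_dt[order(transcript_id, start)]
  o[, .(chain = paste0(chrom[1L], strand[1L], ":",
                       paste(start, end, sep = "-", collapse = ","))),
    by = transcript_id]
}

#' Classify novel transcripts against a reference annotation
#'
#' Each novel transcript is assigned to the same-strand reference gene with
#' maximal exonic overlap (at least `min_overlap` bp); ties are broken by
#' larger span overlap, then lexicographically smallest gene id. The class
#' code is `equal` (exon chain identical to some reference transcript of
#' the target gene), `contained` (span within the gene span), `extends`
#' (span exceeds the gene span on either side) or `novel_isoform`.
#' Transcripts overlapping only opposite-strand genes are `antisense`;
#' transcripts overlapping nothing are `intergenic`; neither is associated.
#' Output order equals input order and repeated runs are identical.
#'
#' @param novel An [annotation()] of long-read transcripts.
#' @param ref The (biotype-filtered) reference [annotation()].
#' @param min_overlap Minimum exonic overlap in bp to associate (default 1).
#' @return A `data.table` with one row per novel transcript:
#'   `transcript_id`, `gene_id` (NA when unassociated), `code`,
#'   `exonic_overlap`.
#' @export
classify_transcripts <- function(novel, ref, min_overlap = 1L) {
  tx <- novel$transcripts
  out <- data.table(transcript_id = tx$transcript_id,
                    gene_id = NA_character_,
                    code = "intergenic",
                    exonic_overlap = 0L)
  if (!nrow(tx)) return(out[])
  missing_chrom <- setdiff(unique(tx$chrom), unique(ref$genes$chrom))
  if (length(missing_chrom))
    warning("chromosome(s) absent from reference, transcripts classified ",
            "intergenic: ", paste(missing_chrom, collapse = ", "))
  if (!nrow(ref$genes)) return(out[])

  # exonic bases of each reference gene (union over its transcripts)
  ref_ex <- ref$exons[ref$transcripts, on = "transcript_id", nomatch = NULL,
                      .(gene_id = i.gene_id, chrom = x.chrom,
                        start = x.start, end = x.end, strand = x.strand)]
  ref_ex <- merge_intervals_by(ref_ex, "gene_id")
  nov_ex <- novel$exons

  # pairwise (novel exon, ref gene-exon) overlaps, same strand only
  gx <- GRanges(ref_ex$chrom, IRanges(ref_ex$start + 1, ref_ex$end),
                strand = ref_ex$strand)
  nx <- GRanges(nov_ex$chrom, IRanges(nov_ex$start + 1, nov_ex$end),
                strand = nov_ex$strand)
  hits <- suppressWarnings(findOverlaps(nx, gx, ignore.strand = FALSE))
  pair <- data.table(
    transcript_id = nov_ex$transcript_id[queryHits(hits)],
    gene_id = ref_ex$gene_id[subjectHits(hits)],
    width = pmin(nov_ex$end[queryHits(hits)], ref_ex$end[subjectHits(hits)]) -
      pmax(nov_ex$start[queryHits(hits)], ref_ex$start[subjectHits(hits)]))
  exonic <- pair[, .(exonic_overlap = sum(width)), by = .(transcript_id, gene_id)]

  # span-level overlaps for tie-breaking and antisense detection
  gs <- GRanges(ref$genes$chrom, IRanges(ref$genes$start + 1, ref$genes$end),
                strand = ref$genes$strand)
  ts <- GRanges(tx$chrom, IRanges(tx$start + 1, tx$end), strand = tx$strand)
  shits <- suppressWarnings(findOverlaps(ts, gs, ignore.strand = TRUE))
  span <- data.table(
    transcript_id = tx$transcript_id[queryHits(shits)],
    gene_id = ref$genes$gene_id[subjectHits(shits)],
    same_strand = tx$strand[queryHits(shits)] ==
      ref$genes$strand[subjectHits(shits)],
    span_overlap = pmin(tx$end[queryHits(shits)],
                        ref$genes$end[subjectHits(shits)]) -
      pmax(tx$start[queryHits(shits)],
           ref$genes$start[subjectHits(shits)]))

  cand <- exonic[exonic_overlap >= min_overlap]
  cand <- span[same_strand == TRUE][cand, on = c("transcript_id", "gene_id")]
  cand[is.na(span_overlap), span_overlap := 0]
  setorder(cand, transcript_id, -exonic_overlap, -span_overlap, gene_id)
  best <- cand[, .SD[1L], by = transcript_id]

  if (nrow(best)) {
    # class codes for the associated transcripts
    ref_keys <- chain_keys(ref$exons)
    ref_keys <- ref_keys[ref$transcripts[, .(transcript_id, gene_id)],
                         on = "transcript_id", nomatch = NULL]
    nov_keys <- chain_keys(novel$exons)
    best <- nov_keys[best, on = "transcript_id"]
    best[, code := {
      is_equal <- paste(gene_id, chain) %in% paste(ref_keys$gene_id, ref_keys$chain)
      ifelse(is_equal, "equal", NA_character_)
    }]
    gsp <- ref$genes[, .(gene_id, g_start = start, g_end = end)]
    best <- gsp[best, on = "gene_id"]
    tsp <- tx[, .(transcript_id, t_start = start, t_end = end)]
    best <- tsp[best, on = "transcript_id"]
    best[is.na(code), code := fifelse(t_start >= g_start & t_end <= g_end,
                                      "contained", "extends")]
    out[best, on = "transcript_id",
        `:=`(gene_id = i.gene_id, code = i.code,
             exonic_overlap = as.integer(i.exonic_overlap))]
  }

  # unassociated: antisense iff some opposite-strand span overlap exists and
  # no same-strand span overlap does; otherwise intergenic
  un <- out[is.na(gene_id), transcript_id]
  if (length(un)) {
    sflag <- span[transcript_id %in% un,
                  .(any_same = any(same_strand), any_opp = any(!same_strand)),
                  by = transcript_id]
    anti <- sflag[any_opp & !any_same, transcript_id]
    out[transcript_id %in% anti, code := "antisense"]
  }
  out[, code := factor(code, levels = CLASS_CODES)]
  out[]
}

#' Write a classification report
#'
#' @param classified Result of [classify_transcripts()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_classification_tsv <- function(classified, path) {
  fwrite(classified, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
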