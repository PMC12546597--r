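# Strand-aware interval index over gene spans. Overlap is defined on gene
# SPANS (the envelope from leftmost to rightmost base), matching the
# extension rule "no intersection with any other same-strand gene";
# exon-level overlap lives in the association module. Half-open semantics:
# [a,b) and [b,c) do not overlap — the whole 1 kb step arithmetic relies on
# this.

#' Build a strand-aware interval index over gene spans
#'
#' One entry per gene in the annotation (extension genes included only if
#' already present). The index is a snapshot: rebuild it after any mutation
#' of the annotation.
#'
#' @param ann An [annotation()] object.
#' @return An `IntervalIndex` object.
#' @seealso [query_overlaps()]
#' @export
build_index <- function(ann) {
  g <- ann$genes
  gr <- GRanges(seqnames = g$chrom,
                ranges = IRanges(start = g$start + 1, end = g$end),
                strand = g$strand)
  structure(list(gr = gr, gene_id = g$gene_id, n = nrow(g)),
            class = "IntervalIndex")
}

#' @exportS3Method base::print
print.IntervalIndex <- function(x, ...) {
  cat(sprintf("IntervalIndex over %d gene span(s)\n", x$n))
  invisible(x)
}

#' Query genes overlapping an interval, strand-aware
#'
#' Returns the ids of all genes on the query's chromosome AND strand whose
#' span shares at least one base with the query, half-open semantics.
#'
#' @param idx An `IntervalIndex` from [build_index()].
#' @param iv A [gi()] interval.
#' @param exclude Optional gene id to drop from the result (e.g. the parent
#'   gene when testing a candidate extension region).
#' @return Character vector of gene ids (possibly empty), sorted.
#' @export
query_overlaps <- function(idx, iv, exclude = NULL) {
  stopifnot(inherits(idx, "IntervalIndex"), inherits(iv, "GenomicInterval"))
  q <- GRanges(seqnames = iv$chrom,
               ranges = IRanges(start = iv$start + 1, end = iv$end),
               strand = iv$strand)
  hits <- suppressWarnings(
    findOverlaps(q, idx$gr, ignore.strand = FALSE))
  ids <- idx$gene_id[subjectHits(hits)]
  if (!is.null(exclude)) ids <- setdiff(ids, exclude)
  sort(unique(ids))
}

# Naive linear-scan overlap oracle over a gene table: plain vectorized
# comparisons, no interval machinery. Used by the fixture generator's
# ground-truth bookkeeping and as the independent oracle in tests.
naive_overlaps <- function(genes, chrom, start, end, strand, exclude = NULL) {
  hit <- genes$chrom == chrom & genes$strand == strand &
    genes$start < end & genes$end > start
  ids <- genes$gene_id[hit]
  if (!is.null(exclude)) ids <- setdiff(ids, exclude)
  sort(unique(ids))
}
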