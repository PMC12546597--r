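# Internal annotation model: a hierarchical gene -> transcript -> exon
# container held in three data.tables. Coordinates are 0-based half-open
# throughout; conversion to/from GTF's 1-based inclusive convention happens
# only at the file boundary (see read_gtf/write_gtf).

#' Construct a genomic interval
#'
#' The unit of all overlap logic: chromosome, strand and a 0-based half-open
#' coordinate pair. Touching intervals (`[a,b)` and `[b,c)`) do not overlap.
#'
#' @param chrom Chromosome name.
#' @param start 0-based inclusive start (bp), non-negative.
#' @param end 0-based exclusive end (bp), strictly greater than `start`.
#' @param strand `"+"` or `"-"`; unstranded intervals are not representable.
#' @return An object of class `GenomicInterval` (a named list).
#' @examples
#' gi("1", 1000, 2000, "+")
#' @export
gi <- function(chrom, start, end, strand) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 0 || start >= end)
    stop("invalid interval: require 0 <= start < end, got [", start, ", ", end, ")")
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-', got '", strand, "'")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "GenomicInterval")
}

#' @exportS3Method base::print
print.GenomicInterval <- function(x, ...) {
  cat(sprintf("%s:[%s, %s)%s\n", x$chrom,
              format(x$start, scientific = FALSE),
              format(x$end, scientific = FALSE), x$strand))
  invisible(x)
}

# width in bp of a GenomicInterval
gi_width <- function(x) x$end - x$start

empty_genes <- function() {
  data.table(gene_id = character(), gene_name = character(),
             biotype = character(), chrom = character(),
             start = numeric(), end = numeric(), strand = character(),
             source = character(), augmented = logical(),
             parent_id = character())
}

empty_transcripts <- function() {
  data.table(transcript_id = character(), gene_id = character(),
             chrom = character(), start = numeric(), end = numeric(),
             strand = character(), source = character())
}

empty_exons <- function() {
  data.table(transcript_id = character(), chrom = character(),
             start = numeric(), end = numeric(), strand = character())
}

#' Construct an annotation object
#'
#' An `Annotation` bundles a gene table, a transcript table and an exon
#' table (all `data.table`s, 0-based half-open coordinates), optional
#' chromosome sizes and a provenance log. Most users obtain one from
#' [read_gtf()] or [simulate_annotation()] rather than calling this
#' constructor directly.
#'
#' @param genes `data.table` with columns `gene_id`, `gene_name`, `biotype`,
#'   `chrom`, `start`, `end`, `strand`, `source`, `augmented`, `parent_id`.
#' @param transcripts `data.table` with columns `transcript_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `source`.
#' @param exons `data.table` with columns `transcript_id`, `chrom`, `start`,
#'   `end`, `strand`. Exons of one transcript are merge-normalized (sorted,
#'   pairwise non-overlapping).
#' @param chrom_sizes Optional named numeric vector of chromosome lengths.
#' @param provenance Character vector logging applied operations.
#' @param validate Run structural validation (default `TRUE`).
#' @return An object of class `Annotation`.
#' @export
annotation <- function(genes = empty_genes(), transcripts = empty_transcripts(),
                       exons = empty_exons(), chrom_sizes = NULL,
                       provenance = character(), validate = TRUE) {
  ann <- structure(list(genes = as.data.table(genes),
                        transcripts = as.data.table(transcripts),
                        exons = as.data.table(exons),
                        chrom_sizes = chrom_sizes,
                        provenance = provenance),
                   class = "Annotation")
  if (validate) validate_annotation(ann)
  ann
}

#' Validate the structural invariants of an annotation
#'
#' Checks id uniqueness, transcript-to-gene resolution, strand values,
#' coordinate sanity, and that every gene/transcript span covers the
#' envelope of its members. Called by [annotation()].
#'
#' @param ann An `Annotation`.
#' @return `ann`, invisibly; errors on violation.
#' @export
validate_annotation <- function(ann) {
  g <- ann$genes; tx <- ann$transcripts; ex <- ann$exons
  if (anyDuplicated(g$gene_id))
    stop("duplicate gene_id: ",
         paste(unique(g$gene_id[duplicated(g$gene_id)]), collapse = ", "))
  if (anyDuplicated(tx$transcript_id))
    stop("duplicate transcript_id: ",
         paste(unique(tx$transcript_id[duplicated(tx$transcript_id)]), collapse = ", "))
  if (nrow(tx) && !all(tx$gene_id %in% g$gene_id))
    stop("transcript(s) reference unknown gene_id: ",
         paste(head(setdiff(tx$gene_id, g$gene_id), 5), collapse = ", "))
  if (nrow(ex) && !all(ex$transcript_id %in% tx$transcript_id))
    stop("exon(s) reference unknown transcript_id")
  for (dt in list(g, tx, ex)) {
    if (!nrow(dt)) next
    if (!all(dt$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    if (any(dt$start < 0) || any(dt$start >= dt$end))
      stop("invalid coordinates: require 0 <= start < end")
  }
  # spans must cover the envelope of members
  if (nrow(ex)) {
    env <- ex[, .(e_start = min(start), e_end = max(end)), by = transcript_id]
    chk <- tx[env, on = "transcript_id"]
    if (any(chk$start > chk$e_start | chk$end < chk$e_end))
      stop("transcript span does not cover its exon envelope")
  }
  if (nrow(tx)) {
    env <- tx[, .(t_start = min(start), t_end = max(end)), by = gene_id]
    chk <- g[env, on = "gene_id"]
    if (any(chk$start > chk$t_start | chk$end < chk$t_end))
      stop("gene span does not cover its transcript envelope")
  }
  invisible(ann)
}

#' @exportS3Method base::print
print.Annotation <- function(x, ...) {
  cat(sprintf("Annotation: %d genes, %d transcripts, %d exons on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons),
              length(unique(x$genes$chrom))))
  if (!is.null(x$chrom_sizes))
    cat(sprintf("  chromosome sizes for %d chromosome(s)\n", length(x$chrom_sizes)))
  n_ext <- sum(x$genes$biotype == "extension")
  n_iso <- sum(x$genes$augmented)
  if (n_iso || n_ext)
    cat(sprintf("  %d augmented (-iso) genes, %d extension genes\n", n_iso, n_ext))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " | "), "\n")
  invisible(x)
}

#' Number of genes in an annotation
#' @param ann An `Annotation`.
#' @return Integer gene count.
#' @export
n_genes <- function(ann) nrow(ann$genes)

#' Extract one gene with its exonic structure
#'
#' @param ann An `Annotation`.
#' @param gene_id Gene identifier.
#' @return A list with the gene row (`gene`), its transcripts
#'   (`transcripts`) and the merged union of its exonic bases (`exon_union`,
#'   a `data.table` of disjoint intervals).
#' @export
get_gene <- function(ann, gene_id) {
  target <- gene_id
  row <- ann$genes[J(target), on = "gene_id", nomatch = NULL]
  if (!nrow(row)) stop("unknown gene_id: ", target)
  tx <- ann$transcripts[gene_id == target]
  ex <- ann$exons[tx, on = "transcript_id", nomatch = NULL,
                  .(chrom = x.chrom, start = x.start, end = x.end, strand = x.strand)]
  list(gene = row, transcripts = tx, exon_union = merge_intervals(ex))
}

#' Extract one transcript with its exons
#'
#' @param ann An `Annotation`.
#' @param transcript_id Transcript identifier.
#' @return A list with the transcript row (`transcript`) and its exons
#'   (`exons`, sorted, merge-normalized).
#' @export
get_transcript <- function(ann, transcript_id) {
  target <- transcript_id
  row <- ann$transcripts[J(target), on = "transcript_id", nomatch = NULL]
  if (!nrow(row)) stop("unknown transcript_id: ", target)
  ex <- ann$exons[transcript_id == target][order(start)]
  list(transcript = row, exons = ex)
}

# Merge a set of intervals (single chrom/strand assumed) into a disjoint
# sorted union. Returns a data.table with chrom/start/end/strand.
merge_intervals <- function(dt) {
  if (!nrow(dt)) return(dt)
  dt <- dt[order(start, end)]
  run_end <- cummax(dt$end)
  new_run <- c(TRUE, dt$start[-1] > run_end[-nrow(dt)])
  grp <- cumsum(new_run)
  dt[, .(chrom = chrom[1L], start = min(start), end = max(end),
         strand = strand[1L]), by = .(.grp = grp)][, .grp := NULL][]
}

# Merge intervals within groups of `by_col`, fully vectorized (one pass
# over the sorted table). Assumes one chrom/strand per group.
merge_intervals_by <- function(dt, by_col) {
  if (!nrow(dt)) return(copy(dt))
  o <- copy(dt)
  setnames(o, by_col, ".key")
  o <- o[order(.key, start, end)]
  key <- o$.key
  new_grp <- c(TRUE, key[-1L] != key[-length(key)])
  cm <- o$end  # running per-group max of end
  for (i in seq_along(cm)[-1L])
    if (!new_grp[i] && cm[i - 1L] > cm[i]) cm[i] <- cm[i - 1L]
  new_run <- new_grp | c(TRUE, o$start[-1L] > cm[-length(cm)])
  o[, .grp := cumsum(new_run)]
  out <- o[, .(.key = .key[1L], chrom = chrom[1L], start = min(start),
               end = max(end), strand = strand[1L]), by = .grp]
  out[, .grp := NULL]
  setnames(out, ".key", by_col)
  out[]
}

# Merge-normalize exons per transcript; warns (once) if duplicates/overlaps
# were collapsed. Returns the normalized exon table.
normalize_exons <- function(ex, warn_dups = TRUE) {
  if (!nrow(ex)) return(ex)
  n_before <- nrow(ex)
  out <- merge_intervals_by(ex, "transcript_id")
  if (warn_dups && nrow(out) < n_before)
    warning(n_before - nrow(out),
            " duplicated/overlapping exon record(s) merged during normalization")
  out[]
}
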