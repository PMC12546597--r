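# Merge associated novel transcripts into the reference annotation, extend
# gene bodies, rename augmented genes with "-iso", and generate maximal
# strand-aware downstream extension genes.

ISO_SUFFIX <- "-iso"

add_iso_suffix <- function(id) {
  # applied once, never stacked
  fifelse(endsWith(id, ISO_SUFFIX), id, paste0(id, ISO_SUFFIX))
}

ext_name <- function(stem, step_kb) paste0(stem, "-ext", step_kb, "kb")

#' Merge associated novel transcripts into the reference annotation
#'
#' Every associated transcript (one with a `gene_id` in `classified`) is
#' appended to its target gene with its `gene_id` rewritten; the gene span
#' grows to the envelope of its old span and the transcript span (extension
#' permitted on both sides). Genes that received at least one transcript are
#' renamed with the `-iso` suffix on the gene id (applied once, never
#' stacked; the gene name is left unchanged). Unassociated transcripts
#' (antisense/intergenic) are dropped and counted in the report. Genes that
#' received nothing are untouched.
#'
#' @param ref The (biotype-filtered) reference [annotation()].
#' @param novel The novel [annotation()] the classification was computed on.
#' @param classified Result of [classify_transcripts()] on (`novel`, `ref`).
#' @return A list with `annotation` (the merged [annotation()]) and
#'   `report` (a `MergeReport`).
#' @export
merge_transcripts <- function(ref, novel, classified) {
  stopifnot(is.data.table(classified),
            all(c("transcript_id", "gene_id") %in% names(classified)))
  assoc <- classified[!is.na(gene_id)]
  if (nrow(assoc) && !all(assoc$gene_id %in% ref$genes$gene_id))
    stop("classified transcript(s) reference gene(s) absent from the ",
         "reference: ",
         paste(head(setdiff(assoc$gene_id, ref$genes$gene_id), 5),
               collapse = ", "))

  genes <- copy(ref$genes)
  tx <- copy(ref$transcripts)
  ex <- copy(ref$exons)

  add_tx <- novel$transcripts[assoc[, .(transcript_id, target = gene_id)],
                              on = "transcript_id", nomatch = NULL]
  if (nrow(add_tx) < nrow(assoc))
    stop("classified transcript(s) absent from the novel annotation")
  if (any(add_tx$transcript_id %in% tx$transcript_id))
    stop("novel transcript id collides with a reference transcript id: ",
         add_tx$transcript_id[add_tx$transcript_id %in% tx$transcript_id][1L])
  add_tx[, `:=`(gene_id = target, target = NULL)]
  add_ex <- novel$exons[transcript_id %in% add_tx$transcript_id]

  old_span <- genes[, .(gene_id, old_start = start, old_end = end)]
  if (nrow(add_tx)) {
    env <- add_tx[, .(a_start = min(start), a_end = max(end)), by = gene_id]
    genes[env, on = "gene_id",
          `:=`(start = pmin(start, a_start), end = pmax(end, a_end),
               augmented = TRUE)]
    tx <- rbind(tx, add_tx, use.names = TRUE)
    ex <- rbind(ex, add_ex, use.names = TRUE)
  }

  # rename augmented genes: id gets "-iso" once; transcripts follow
  renamed <- genes[augmented == TRUE,
                   .(gene_id, new_gene_id = add_iso_suffix(gene_id))]
  if (nrow(renamed)) {
    tx[renamed, on = "gene_id", gene_id := i.new_gene_id]
    genes[renamed, on = "gene_id", gene_id := i.new_gene_id]
  }

  per_gene <- genes[augmented == TRUE,
                    .(gene_id, new_start = start, new_end = end)]
  if (nrow(per_gene)) {
    nadd <- add_tx[, .(n_added = .N),
                   by = .(gene_id = add_iso_suffix(gene_id))]
    per_gene <- nadd[per_gene, on = "gene_id"]
    per_gene <- old_span[, .(gene_id = add_iso_suffix(gene_id),
                             old_start, old_end)][per_gene, on = "gene_id"]
  } else {
    per_gene <- data.table(gene_id = character(), n_added = integer(),
                           old_start = numeric(), old_end = numeric(),
                           new_start = numeric(), new_end = numeric())
  }
  body_extended <- per_gene[new_start < old_start | new_end > old_end, gene_id]

  report <- merge_report(
    n_transcripts_added = nrow(add_tx),
    n_genes_augmented = nrow(per_gene),
    n_genes_body_extended = length(body_extended),
    n_extension_genes = 0L,
    n_dropped_antisense = sum(classified$code == "antisense"),
    n_dropped_intergenic = sum(classified$code == "intergenic"),
    per_gene = per_gene)

  ann <- annotation(genes = genes, transcripts = tx, exons = ex,
                    chrom_sizes = ref$chrom_sizes,
                    provenance = c(ref$provenance,
                                   sprintf("merge_transcripts(+%d tx, %d genes -iso)",
                                           nrow(add_tx), nrow(per_gene))))
  list(annotation = ann, report = report)
}

merge_report <- function(...) {
  structure(list(...), class = "MergeReport")
}

#' @exportS3Method base::print
print.MergeReport <- function(x, ...) {
  cat("MergeReport\n")
  for (f in setdiff(names(x), "per_gene"))
    cat(sprintf("  %s: %s\n", f, x[[f]]))
  if (!is.null(x$per_gene) && nrow(x$per_gene))
    cat(sprintf("  per_gene: %d row(s)\n", nrow(x$per_gene)))
  invisible(x)
}

#' Compute the maximal downstream extension for one gene
#'
#' The candidate region at step `x` lies immediately downstream of the
#' gene's 3' edge, strand-aware: on the `+` strand
#' `[gene end, gene end + 1000 x)`, on the `-` strand
#' `[gene start - 1000 x, gene start)`. The largest `x` in
#' `{step_kb, 2 step_kb, ..., max_kb}` whose region (a) intersects no
#' same-strand gene other than the parent and (b) stays within
#' `[0, chromosome length)` is returned; candidate regions must start at 0
#' or later even when no chromosome sizes are known (negative coordinates
#' are invalid in any convention). Only whole steps are emitted: a 2,999 bp
#' gap yields `x = 2`, never a partial region.
#'
#' @param gene_id Parent gene id (must not itself be an extension gene).
#' @param ann The post-merge [annotation()].
#' @param idx [build_index()] over `ann`'s gene spans.
#' @param max_kb Largest step in kb (default 10).
#' @param step_kb Step increment in kb (default 1).
#' @param chrom_sizes Optional named lengths; defaults to `ann$chrom_sizes`.
#' @return An `ExtensionGene` (list with `id`, `name`, `parent_id`,
#'   `step_kb`, `region`) or `NULL` when even the smallest step fails.
#' @export
compute_extension <- function(gene_id, ann, idx, max_kb = 10L, step_kb = 1L,
                              chrom_sizes = NULL) {
  target <- gene_id
  g <- ann$genes[J(target), on = "gene_id", nomatch = NULL]
  if (!nrow(g)) stop("unknown gene_id: ", target)
  if (identical(g$biotype, "extension"))
    stop("gene ", target, " is itself an extension gene")
  if (is.null(chrom_sizes)) chrom_sizes <- ann$chrom_sizes
  chrom_len <- if (!is.null(chrom_sizes) && g$chrom %in% names(chrom_sizes))
    chrom_sizes[[g$chrom]] else NA_real_

  best <- NULL
  for (x in seq.int(step_kb, max_kb, by = step_kb)) {
    len <- 1000 * x
    if (g$strand == "+") {
      s <- g$end; e <- g$end + len
    } else {
      s <- g$start - len; e <- g$start
    }
    if (s < 0) break
    if (!is.na(chrom_len) && e > chrom_len) break
    hits <- query_overlaps(idx, gi(g$chrom, s, e, g$strand), exclude = target)
    if (length(hits)) break
    best <- list(step = x, start = s, end = e)
  }
  if (is.null(best)) return(NULL)
  structure(list(id = ext_name(g$gene_id, best$step),
                 name = ext_name(g$gene_name, best$step),
                 parent_id = g$gene_id,
                 step_kb = best$step,
                 region = gi(g$chrom, best$start, best$end, g$strand)),
            class = "ExtensionGene")
}

#' @exportS3Method base::print
print.ExtensionGene <- function(x, ...) {
  cat(sprintf("ExtensionGene %s (parent %s, %d kb) ", x$id, x$parent_id,
              x$step_kb))
  print(x$region)
  invisible(x)
}

# Vectorized extension computation over all genes of a table against a
# fixed obstacle set (post-merge gene bodies). Returns a data.table
# (gene_id, step, r_start, r_end); step 0 = no feasible region. Feasibility
# is downward-closed in x (regions nest), so the best step is the largest
# feasible one.
extension_steps_indexed <- function(genes, max_kb, step_kb, chrom_sizes) {
  n <- nrow(genes)
  if (!n) return(data.table(gene_id = character(), step = integer(),
                            r_start = numeric(), r_end = numeric()))
  gr <- GRanges(genes$chrom, IRanges(genes$start + 1, genes$end),
                strand = genes$strand)
  chrom_len <- if (is.null(chrom_sizes)) rep(NA_real_, n) else
    unname(chrom_sizes[genes$chrom])
  plus <- genes$strand == "+"
  steps <- seq.int(step_kb, max_kb, by = step_kb)
  best <- integer(n)
  for (x in steps) {
    len <- 1000 * x
    s <- ifelse(plus, genes$end, genes$start - len)
    e <- ifelse(plus, genes$end + len, genes$start)
    ok <- s >= 0 & (is.na(chrom_len) | e <= chrom_len)
    cand_idx <- which(ok)
    if (length(cand_idx)) {
      cand <- GRanges(genes$chrom[cand_idx],
                      IRanges(s[cand_idx] + 1, e[cand_idx]),
                      strand = genes$strand[cand_idx])
      hits <- suppressWarnings(findOverlaps(cand, gr, ignore.strand = FALSE))
      non_parent <- genes$gene_id[cand_idx[queryHits(hits)]] !=
        genes$gene_id[subjectHits(hits)]
      blocked <- unique(queryHits(hits)[non_parent])
      ok[cand_idx[blocked]] <- FALSE
    }
    best[ok] <- x
  }
  len <- 1000 * best
  data.table(gene_id = genes$gene_id, step = best,
             r_start = ifelse(plus, genes$end, genes$start - len),
             r_end = ifelse(plus, genes$end + len, genes$start))
}

#' Add extension genes downstream of every gene
#'
#' Evaluates [compute_extension()] for every non-extension gene of the
#' post-merge annotation and materializes each result as a gene with one
#' single-exon transcript covering its region, biotype `"extension"`, named
#' `<parent id>-ext<x>kb` / `<parent name>-ext<x>kb`. By default the
#' obstacle set consists of the post-merge gene bodies only — extension
#' regions are not obstacles to one another; with
#' `strict_obstacles = TRUE` previously placed extension genes (in
#' deterministic chromosome/start iteration order) also obstruct later
#' ones. Original genes are not modified.
#'
#' @param ann The post-merge [annotation()]; must not already contain
#'   extension genes.
#' @param chrom_sizes Optional named chromosome lengths; defaults to
#'   `ann$chrom_sizes`. When absent, only the `start >= 0` bound is
#'   enforced and a warning notes that chromosome ends are unchecked.
#' @param max_kb,step_kb Extension step grid in kb (defaults 10 and 1).
#' @param strict_obstacles Treat already-placed extension genes as
#'   obstacles (default `FALSE`).
#' @return A list with `annotation` (extended) and `report` (a
#'   `MergeReport` whose `per_gene` table carries `gene_id`, `step`,
#'   `ext_id`).
#' @export
add_extension_genes <- function(ann, chrom_sizes = NULL, max_kb = 10L,
                                step_kb = 1L, strict_obstacles = FALSE) {
  stopifnot(max_kb >= 1L, step_kb >= 1L, step_kb <= max_kb)
  if (any(ann$genes$biotype == "extension"))
    stop("annotation already contains extension genes; ",
         "re-running extension is not supported")
  if (is.null(chrom_sizes)) chrom_sizes <- ann$chrom_sizes
  if (is.null(chrom_sizes))
    warning("no chromosome sizes supplied: chromosome ends are unchecked")

  core <- copy(ann$genes)[order(chrom, start, gene_id)]
  if (!strict_obstacles) {
    steps <- extension_steps_indexed(core, max_kb, step_kb, chrom_sizes)
  } else {
    # sequential: each accepted extension becomes an obstacle for later genes
    obstacles <- copy(core)
    steps_list <- vector("list", nrow(core))
    for (i in seq_len(nrow(core))) {
      g <- core[i]
      idx <- build_index(annotation(genes = obstacles, validate = FALSE))
      eg <- compute_extension(g$gene_id,
                              annotation(genes = obstacles, validate = FALSE),
                              idx, max_kb = max_kb, step_kb = step_kb,
                              chrom_sizes = chrom_sizes)
      if (is.null(eg)) {
        steps_list[[i]] <- data.table(gene_id = g$gene_id, step = 0L,
                                      r_start = NA_real_, r_end = NA_real_)
      } else {
        steps_list[[i]] <- data.table(gene_id = g$gene_id, step = eg$step_kb,
                                      r_start = eg$region$start,
                                      r_end = eg$region$end)
        obstacles <- rbind(obstacles,
                           data.table(gene_id = eg$id, gene_name = eg$name,
                                      biotype = "extension",
                                      chrom = eg$region$chrom,
                                      start = eg$region$start,
                                      end = eg$region$end,
                                      strand = eg$region$strand,
                                      source = "extension", augmented = FALSE,
                                      parent_id = eg$parent_id),
                           use.names = TRUE)
      }
    }
    steps <- rbindlist(steps_list)
  }

  got <- steps[step > 0L]
  got <- core[, .(gene_id, gene_name, chrom, strand)][got, on = "gene_id"]
  ext_genes <- got[, .(gene_id = ext_name(gene_id, step),
                       gene_name = ext_name(gene_name, step),
                       biotype = "extension", chrom,
                       start = r_start, end = r_end, strand,
                       source = "extension", augmented = FALSE,
                       parent_id = gene_id)]
  ext_tx <- ext_genes[, .(transcript_id = paste0(gene_id, "-tx"), gene_id,
                          chrom, start, end, strand, source = "extension")]
  ext_ex <- ext_tx[, .(transcript_id, chrom, start, end, strand)]

  genes <- rbind(ann$genes, ext_genes, use.names = TRUE)
  tx <- rbind(ann$transcripts, ext_tx, use.names = TRUE)
  ex <- rbind(ann$exons, ext_ex, use.names = TRUE)
  out <- annotation(genes = genes, transcripts = tx, exons = ex,
                    chrom_sizes = ann$chrom_sizes,
                    provenance = c(ann$provenance,
                                   sprintf("add_extension_genes(+%d, max_kb=%d)",
                                           nrow(ext_genes), max_kb)))
  report <- merge_report(
    n_transcripts_added = 0L,
    n_genes_augmented = 0L,
    n_genes_body_extended = 0L,
    n_extension_genes = nrow(ext_genes),
    per_gene = steps[, .(gene_id, step,
                         ext_id = fifelse(step > 0L,
                                          ext_name(gene_id, step),
                                          NA_character_))])
  list(annotation = out, report = report)
}
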