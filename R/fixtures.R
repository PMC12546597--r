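# Deterministic synthetic-annotation generator with ground truth for every
# pipeline stage. Genes are placed left-to-right with sampled inter-gene
# gaps; a fraction receive a novel transcript that shares the reference
# exon chain and extends it 3' (strand-aware); decoy transcripts (antisense
# copies, intergenic singletons) are never associable. Ground-truth
# extension steps come from an exhaustive naive scan (plain vector
# comparisons), never from the production interval index.

#' Simulation parameters
#'
#' @param n_genes Number of reference genes.
#' @param chrom_length Chromosome length in bp; generation errors out if the
#'   layout would exceed it.
#' @param gene_length `(min, max)` uniform gene length in bp.
#' @param gap_distribution `(min, max)` uniform inter-gene gap in bp.
#' @param boundary_gap_prob Probability that a gap is snapped to a 1 kb
#'   boundary regime (`k*1000 + {-1, 0, +1}` for k in 1..10), so extension
#'   maximality is exercised exactly at step boundaries.
#' @param minus_strand_prob Probability a gene lies on the `-` strand.
#' @param pseudogene_prob Probability a gene is a pseudogene (split evenly
#'   between `pseudogene` and `processed_pseudogene`).
#' @param novel_transcript_prob Per (non-pseudogene) gene probability of a
#'   novel transcript.
#' @param novel_3prime_extension `(min, max)` uniform 3' extension in bp of
#'   the novel transcript beyond the reference gene end; capped so the
#'   transcript never reaches the neighboring gene (layouts stay
#'   non-overlapping, keeping parentage unambiguous).
#' @param decoy_antisense_prob Per gene probability of an antisense decoy
#'   transcript (reference exons, flipped strand).
#' @param decoy_intergenic_prob Per gene probability of an intergenic decoy
#'   transcript placed in the preceding gap.
#' @param chrom Chromosome name.
#' @param seed Integer seed; the same seed yields byte-identical outputs.
#' @return A `SimulationParams` list.
#' @export
sim_params <- function(n_genes = 500L,
                       chrom_length = 1.5e7,
                       gene_length = c(2000, 8000),
                       gap_distribution = c(200, 15000),
                       boundary_gap_prob = 0.15,
                       minus_strand_prob = 0.4,
                       pseudogene_prob = 0.1,
                       novel_transcript_prob = 0.3,
                       novel_3prime_extension = c(200, 3000),
                       decoy_antisense_prob = 0.05,
                       decoy_intergenic_prob = 0.05,
                       chrom = "1",
                       seed = 1L) {
  p <- list(n_genes = as.integer(n_genes), chrom_length = chrom_length,
            gene_length = gene_length, gap_distribution = gap_distribution,
            boundary_gap_prob = boundary_gap_prob,
            minus_strand_prob = minus_strand_prob,
            pseudogene_prob = pseudogene_prob,
            novel_transcript_prob = novel_transcript_prob,
            novel_3prime_extension = novel_3prime_extension,
            decoy_antisense_prob = decoy_antisense_prob,
            decoy_intergenic_prob = decoy_intergenic_prob,
            chrom = chrom, seed = as.integer(seed))
  probs <- c(p$boundary_gap_prob, p$minus_strand_prob, p$pseudogene_prob,
             p$novel_transcript_prob, p$decoy_antisense_prob,
             p$decoy_intergenic_prob)
  stopifnot(all(probs >= 0 & probs <= 1),
            p$gene_length[1] <= p$gene_length[2],
            p$gap_distribution[1] <= p$gap_distribution[2],
            p$novel_3prime_extension[1] <= p$novel_3prime_extension[2],
            p$n_genes >= 1L, p$chrom_length > 0)
  structure(p, class = "SimulationParams")
}

runif_int <- function(n, lo, hi) lo + floor(runif(n) * (hi - lo + 1))

#' Exhaustive naive extension steps (testing oracle)
#'
#' For every gene in `genes`, checks each candidate step `x = step_kb, ...,
#' max_kb` exhaustively with plain vectorized comparisons: the strand-aware
#' downstream region `[end, end + 1000x)` (+) or `[start - 1000x, start)`
#' (-) must not intersect any other same-strand gene span, must start at 0
#' or later and, when a chromosome size is known, end within it. Returns
#' the largest feasible step per gene (0 when none). Independent of the
#' production interval index; intended as an oracle for tests and
#' ground-truth bookkeeping.
#'
#' @param genes A gene `data.table` (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @param chrom_sizes Optional named chromosome lengths.
#' @param max_kb,step_kb Step grid in kb.
#' @return `data.table` with `gene_id` and `step`.
#' @export
naive_extension_steps <- function(genes, chrom_sizes = NULL, max_kb = 10L,
                                  step_kb = 1L) {
  n <- nrow(genes)
  g_id <- genes$gene_id; g_chrom <- genes$chrom; g_strand <- genes$strand
  g_start <- genes$start; g_end <- genes$end
  steps <- integer(n)
  for (i in seq_len(n)) {
    chrom_len <- if (!is.null(chrom_sizes) && g_chrom[i] %in% names(chrom_sizes))
      chrom_sizes[[g_chrom[i]]] else NA_real_
    best <- 0L
    for (x in seq.int(step_kb, max_kb, by = step_kb)) {
      len <- 1000 * x
      if (g_strand[i] == "+") { s <- g_end[i]; e <- g_end[i] + len }
      else { s <- g_start[i] - len; e <- g_start[i] }
      feasible <- s >= 0 && (is.na(chrom_len) || e <= chrom_len) &&
        !any(g_chrom == g_chrom[i] & g_strand == g_strand[i] &
               g_id != g_id[i] & g_start < e & g_end > s)
      if (feasible) best <- x
    }
    steps[i] <- best
  }
  data.table(gene_id = g_id, step = steps)
}

#' Simulate a reference/novel annotation pair with ground truth
#'
#' Generates a reference annotation (genes with two-exon transcripts,
#' sampled strands, gaps and pseudogene biotypes), a novel annotation
#' (3'-extending transcripts plus antisense and intergenic decoys) and a
#' `GroundTruth` object recording, for every novel transcript, its true
#' parent (or decoy status); for every gene, whether it should end up
#' renamed `-iso`; and for every retained gene, the expected downstream
#' extension step computed by the exhaustive naive oracle on the merged
#' gene spans.
#'
#' @param p A [sim_params()] object.
#' @return A list with `reference`, `novel` (both [annotation()]s, the
#'   reference carrying `chrom_sizes`) and `truth`.
#' @export
simulate_annotation <- function(p) {
  stopifnot(inherits(p, "SimulationParams"))
  set.seed(p$seed)
  n <- p$n_genes

  # gap before each gene, gene lengths, strands, biotypes
  gaps <- runif_int(n, p$gap_distribution[1], p$gap_distribution[2])
  snap <- runif(n) < p$boundary_gap_prob
  if (any(snap)) {
    k <- runif_int(sum(snap), 1, 10)
    delta <- runif_int(sum(snap), -1, 1)
    gaps[snap] <- k * 1000 + delta
  }
  lens <- runif_int(n, p$gene_length[1], p$gene_length[2])
  ends <- cumsum(as.numeric(gaps) + as.numeric(lens))
  starts <- ends - lens
  if (ends[n] + 1000 > p$chrom_length)
    stop("generated layout exceeds chrom_length (need ", ends[n] + 1000,
         " bp); increase chrom_length or reduce n_genes")
  strands <- ifelse(runif(n) < p$minus_strand_prob, "-", "+")
  is_pseudo <- runif(n) < p$pseudogene_prob
  biotype <- rep("protein_coding", n)
  biotype[is_pseudo] <- rep_len(c("pseudogene", "processed_pseudogene"),
                                sum(is_pseudo))

  ids <- sprintf("SIMG%04d", seq_len(n))
  names_ <- sprintf("GENE%04d", seq_len(n))
  genes <- data.table(gene_id = ids, gene_name = names_, biotype = biotype,
                      chrom = p$chrom, start = starts, end = ends,
                      strand = strands, source = "reference",
                      augmented = FALSE, parent_id = NA_character_)

  # one two-exon transcript per gene (exons cover ~90% of the span)
  tx_ids <- sprintf("SIMT%04d", seq_len(n))
  e1_end <- starts + floor(lens * 0.45)
  e2_start <- starts + floor(lens * 0.55)
  tx <- data.table(transcript_id = tx_ids, gene_id = ids, chrom = p$chrom,
                   start = starts, end = ends, strand = strands,
                   source = "reference")
  ex <- rbind(
    data.table(transcript_id = tx_ids, chrom = p$chrom, start = starts,
               end = e1_end, strand = strands),
    data.table(transcript_id = tx_ids, chrom = p$chrom, start = e2_start,
               end = ends, strand = strands))

  # novel 3'-extending transcripts for a fraction of retained genes
  gap_after <- c(gaps[-1L], p$chrom_length - ends[n])
  has_novel <- runif(n) < p$novel_transcript_prob & !is_pseudo
  e_raw <- runif_int(n, p$novel_3prime_extension[1], p$novel_3prime_extension[2])
  # cap so the transcript never reaches the neighboring gene or leaves the
  # chromosome; a cap of zero degenerates to an exact exon-chain match
  cap <- ifelse(strands == "+", pmax(0, pmin(gap_after - 1,
                                             p$chrom_length - ends)),
                pmax(0, pmin(gaps - 1, starts)))
  e_eff <- ifelse(has_novel, pmin(e_raw, cap), 0)

  iN <- which(has_novel)
  ns <- ifelse(strands == "+", starts, starts - e_eff)
  ne <- ifelse(strands == "+", ends + e_eff, ends)
  nov_tab <- data.table(
    transcript_id = sprintf("NOVT%04d", iN),
    gene_id = sprintf("NOVG%04d", iN),
    chrom = p$chrom, start = ns[iN], end = ne[iN], strand = strands[iN])
  nov_ex <- data.table(
    transcript_id = rep(nov_tab$transcript_id, each = 2L),
    chrom = p$chrom,
    start = as.vector(rbind(ns[iN], e2_start[iN])),
    end = as.vector(rbind(e1_end[iN], ne[iN])),
    strand = rep(strands[iN], each = 2L))
  nov_parents <- data.table(
    transcript_id = nov_tab$transcript_id, true_gene_id = ids[iN],
    kind = fifelse(e_eff[iN] > 0, "extension", "match"))

  # antisense decoys: reference exons on the flipped strand
  has_anti <- runif(n) < p$decoy_antisense_prob & !is_pseudo
  iA <- which(has_anti)
  flip <- ifelse(strands == "+", "-", "+")
  anti_tab <- data.table(
    transcript_id = sprintf("NOVTA%04d", iA),
    gene_id = sprintf("NOVGA%04d", iA),
    chrom = p$chrom, start = starts[iA], end = ends[iA], strand = flip[iA])
  anti_ex <- data.table(
    transcript_id = rep(anti_tab$transcript_id, each = 2L),
    chrom = p$chrom,
    start = as.vector(rbind(starts[iA], e2_start[iA])),
    end = as.vector(rbind(e1_end[iA], ends[iA])),
    strand = rep(flip[iA], each = 2L))
  anti_parents <- data.table(
    transcript_id = anti_tab$transcript_id, true_gene_id = NA_character_,
    kind = if (length(iA)) "antisense" else character(0))

  # intergenic decoys: single-exon transcripts centered in the gap before a
  # gene, clear of both flanking genes
  has_inter <- runif(n) < p$decoy_intergenic_prob & gaps >= 600
  inter_strand <- ifelse(runif(n) < 0.5, "+", "-")
  iI <- which(has_inter)
  ds <- floor(starts - gaps / 2 - 100)
  inter_tab <- data.table(
    transcript_id = sprintf("NOVTI%04d", iI),
    gene_id = sprintf("NOVGI%04d", iI),
    chrom = p$chrom, start = ds[iI], end = ds[iI] + 200,
    strand = inter_strand[iI])
  inter_ex <- data.table(
    transcript_id = inter_tab$transcript_id, chrom = p$chrom,
    start = ds[iI], end = ds[iI] + 200, strand = inter_strand[iI])
  inter_parents <- data.table(
    transcript_id = inter_tab$transcript_id, true_gene_id = NA_character_,
    kind = if (length(iI)) "intergenic" else character(0))

  all_tab <- rbind(nov_tab, anti_tab, inter_tab)
  nov_genes <- all_tab[, .(gene_id, gene_name = gene_id, biotype = "",
                           chrom, start, end, strand, source = "novel",
                           augmented = FALSE, parent_id = NA_character_)]
  nov_tx <- all_tab[, .(transcript_id, gene_id, chrom, start, end, strand,
                        source = "novel")]
  nov_exons <- rbind(nov_ex, anti_ex, inter_ex)
  parents_tab <- rbind(nov_parents, anti_parents, inter_parents)

  chrom_sizes <- stats::setNames(p$chrom_length, p$chrom)
  reference <- annotation(genes = genes, transcripts = tx,
                          exons = normalize_exons(ex, warn_dups = FALSE),
                          chrom_sizes = chrom_sizes,
                          provenance = sprintf("simulate_annotation(seed=%d)",
                                               p$seed))
  novel <- annotation(
    genes = nov_genes, transcripts = nov_tx, exons = nov_exons,
    provenance = sprintf("simulate_annotation(seed=%d, novel)", p$seed))

  # ground truth: -iso flags and merged spans for retained genes, expected
  # extension steps via the exhaustive naive oracle
  retained <- genes[!is_pseudo]
  merged <- copy(retained)
  idx_ret <- match(merged$gene_id, ids)
  grow <- e_eff[idx_ret]
  merged[, `:=`(start = fifelse(strand == "-", start - grow, start),
                end = fifelse(strand == "+", end + grow, end))]
  merged[, gene_id := fifelse(has_novel[idx_ret],
                              paste0(gene_id, "-iso"), gene_id)]
  ext <- naive_extension_steps(merged, chrom_sizes = chrom_sizes)

  truth <- structure(list(
    transcript_parents = parents_tab,
    iso_flags = data.table(gene_id = ids, expected_iso = has_novel),
    merged_spans = merged[, .(gene_id, start, end, strand)],
    extension_steps = ext),
    class = "GroundTruth")

  list(reference = reference, novel = novel, truth = truth)
}

#' @exportS3Method base::print
print.GroundTruth <- function(x, ...) {
  cat("GroundTruth:",
      nrow(x$transcript_parents), "novel transcript(s),",
      sum(x$iso_flags$expected_iso), "expected -iso gene(s)")
  if (!is.null(x$extension_steps))
    cat(",", sum(x$extension_steps$step > 0), "expected extension gene(s)")
  cat("\n")
  invisible(x)
}

#' Simulate a count matrix over gene variants with known collapsed totals
#'
#' For each cell and base gene a total count is drawn (Poisson with mean
#' `mean_count`) and split multinomially (uniform probabilities, via
#' sequential binomial thinning) across that gene's variant columns, so the
#' collapsed totals are known exactly by construction.
#'
#' @param ann An [annotation()] whose genes may carry `-iso` / `-ext<x>kb`
#'   suffixes (e.g. the output of [add_extension_genes()]).
#' @param n_cells Number of cells.
#' @param mean_count Poisson mean of the per-(cell, base gene) total.
#' @param seed Integer seed.
#' @return A list with `matrix` (a [count_matrix()], columns in the
#'   annotation's deterministic gene order) and `truth` (a `GroundTruth`
#'   with `totals`, the expected collapsed cells x base-genes matrix).
#' @export
simulate_counts <- function(ann, n_cells, mean_count, seed = 1L) {
  set.seed(seed)
  g <- ann$genes[order(chrom, start, gene_id)]
  ids <- g$gene_id
  keys <- parse_gene_key(ids)
  ubase <- unique(keys$base)
  groups <- split(seq_along(ids), factor(keys$base, levels = ubase))
  totals <- matrix(rpois(n_cells * length(ubase), mean_count),
                   nrow = n_cells)
  vals <- matrix(0, nrow = n_cells, ncol = length(ids))
  for (b in seq_along(ubase)) {
    cols <- groups[[b]]
    k <- length(cols)
    remaining <- totals[, b]
    if (k > 1L) {
      for (j in seq_len(k - 1L)) {
        x <- rbinom(n_cells, remaining, 1 / (k - j + 1))
        vals[, cols[j]] <- x
        remaining <- remaining - x
      }
    }
    vals[, cols[k]] <- remaining
  }
  cells <- sprintf("CELL%05d", seq_len(n_cells))
  m <- count_matrix(Matrix::Matrix(vals, sparse = TRUE), cells, ids)
  tot <- Matrix::Matrix(totals, sparse = TRUE)
  dimnames(tot) <- list(cells, ubase)
  truth <- structure(list(totals = tot), class = "GroundTruth")
  list(matrix = m, truth = truth)
}
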