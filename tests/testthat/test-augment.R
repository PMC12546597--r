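test_that("merge appends transcripts, extends spans, renames -iso once", {
  ref <- simple_annotation(gene_row("G1", 1000, 5000))
  novel <- annotation(
    genes = gene_row("NG1", 1200, 6200, source = "novel"),
    transcripts = data.table::data.table(
      transcript_id = "NT1", gene_id = "NG1", chrom = "1", start = 1200,
      end = 6200, strand = "+", source = "novel"),
    exons = data.table::data.table(transcript_id = "NT1", chrom = "1",
                                   start = 1200, end = 6200, strand = "+"))
  cls <- classify_transcripts(novel, ref)
  res <- merge_transcripts(ref, novel, cls)
  g <- res$annotation$genes
  expect_equal(g$gene_id, "G1-iso")
  expect_equal(c(g$start, g$end), c(1000, 6200))
  expect_true(g$augmented)
  expect_equal(res$report$n_transcripts_added, 1L)
  expect_equal(res$report$n_genes_augmented, 1L)
  expect_equal(res$report$n_genes_body_extended, 1L)
  # transcripts follow the renamed gene
  expect_setequal(res$annotation$transcripts$gene_id, "G1-iso")
})

test_that("two transcripts on one gene: envelope span, suffix applied once", {
  ref <- simple_annotation(gene_row("G1", 1000, 5000))
  novel <- annotation(
    genes = gene_row("NG1", 800, 6200, source = "novel"),
    transcripts = data.table::data.table(
      transcript_id = c("NT1", "NT2"), gene_id = "NG1", chrom = "1",
      start = c(800, 1200), end = c(4000, 6200), strand = "+",
      source = "novel"),
    exons = data.table::data.table(
      transcript_id = c("NT1", "NT2"), chrom = "1",
      start = c(800, 1200), end = c(4000, 6200), strand = "+"))
  cls <- classify_transcripts(novel, ref)
  res <- merge_transcripts(ref, novel, cls)
  g <- res$annotation$genes
  expect_equal(g$gene_id, "G1-iso")   # applied once, never "G1-iso-iso"
  expect_equal(c(g$start, g$end), c(800, 6200))
  expect_equal(res$report$n_transcripts_added, 2L)
})

test_that("merge with no associated transcripts is the identity", {
  ref <- simple_annotation(gene_row("G1", 1000, 5000))
  novel <- annotation()
  cls <- classify_transcripts(novel, ref)
  res <- merge_transcripts(ref, novel, cls)
  expect_equal(res$annotation$genes, ref$genes)
  expect_equal(res$annotation$transcripts, ref$transcripts)
  expect_equal(res$report$n_transcripts_added, 0L)
  expect_false(any(grepl("-iso$", res$annotation$genes$gene_id)))
})

test_that("merge refuses transcripts aimed at genes absent from the reference", {
  ref <- simple_annotation(gene_row("G1", 1000, 5000))
  cls <- data.table::data.table(transcript_id = "NT1", gene_id = "GHOST",
                                code = factor("extends"),
                                exonic_overlap = 10L)
  expect_error(merge_transcripts(ref, annotation(), cls), "absent")
})

test_that("compute_extension picks the largest non-intersecting whole step", {
  genes <- rbind(gene_row("G1", 10000, 15000, "+"),
                 gene_row("G2", 18500, 20000, "+"))
  ann <- simple_annotation(genes)
  idx <- build_index(ann)
  eg <- compute_extension("G1", ann, idx)
  expect_equal(eg$step_kb, 3L)  # 4 kb region [15000,19000) would hit G2
  expect_equal(c(eg$region$start, eg$region$end), c(15000, 18000))
  expect_equal(eg$id, "G1-ext3kb")
  expect_equal(eg$region$end - eg$region$start, 3000)
})

test_that("minus-strand extension runs downstream = leftward", {
  genes <- rbind(gene_row("G1", 50000, 60000, "-"),
                 gene_row("G2", 49000, 49700, "-"))
  ann <- simple_annotation(genes)
  idx <- build_index(ann)
  # x = 1 region [49000, 50000) already intersects G2 -> none
  expect_null(compute_extension("G1", ann, idx))
  # without the blocker the region must abut the 5'-leftward edge
  ann2 <- simple_annotation(gene_row("G1", 50000, 60000, "-"))
  eg <- compute_extension("G1", ann2, build_index(ann2))
  expect_equal(eg$step_kb, 10L)
  expect_equal(c(eg$region$start, eg$region$end), c(40000, 50000))
})

test_that("isolated gene caps at 10 kb; chromosome bounds truncate steps", {
  ann <- simple_annotation(gene_row("G1", 10000, 15000, "+"))
  eg <- compute_extension("G1", ann, build_index(ann))
  expect_equal(eg$step_kb, 10L)
  # chromosome of 18,400 bp leaves room for 3 whole kb only
  eg2 <- compute_extension("G1", ann, build_index(ann),
                           chrom_sizes = c("1" = 18400))
  expect_equal(eg2$step_kb, 3L)
  # a minus-strand gene near the origin is bounded by coordinate 0
  ann3 <- simple_annotation(gene_row("G3", 2500, 4000, "-"))
  eg3 <- compute_extension("G3", ann3, build_index(ann3))
  expect_equal(eg3$step_kb, 2L)
})

test_that("tandem layout produces the expected extension set end to end", {
  genes <- rbind(gene_row("A", 0, 2000, "+"),
                 gene_row("B", 2500, 4000, "+"),
                 gene_row("C", 20000, 21000, "+"))
  ann <- simple_annotation(genes, chrom_sizes = c("1" = 1e6))
  res <- add_extension_genes(ann)
  steps <- res$report$per_gene
  expect_equal(steps[steps$gene_id == "A", step], 0L)   # [2000,3000) hits B
  expect_equal(steps[steps$gene_id == "B", step], 10L)  # [4000,14000) clear
  expect_equal(steps[steps$gene_id == "C", step], 10L)
  eg <- res$annotation$genes[biotype == "extension"]
  expect_setequal(eg$gene_id, c("B-ext10kb", "C-ext10kb"))
  expect_equal(res$report$n_extension_genes, 2L)
  expect_equal(res$report$n_extension_genes, nrow(eg))
  # each extension gene owns exactly one single-exon transcript
  etx <- res$annotation$transcripts[gene_id %in% eg$gene_id]
  expect_equal(nrow(etx), 2L)
  expect_equal(nrow(res$annotation$exons[transcript_id %in% etx$transcript_id]),
               2L)
})

test_that("extension naming stacks -iso before -ext'x'kb", {
  sim <- simulate_annotation(sim_params(n_genes = 60, seed = 12,
                                        novel_transcript_prob = 0.5))
  out <- run_pipeline(sim)
  eg <- out$extended$annotation$genes[biotype == "extension"]
  expect_true(all(grepl("-ext([1-9]|10)kb$", eg$gene_id)))
  expect_false(any(grepl("-ext[0-9]+kb-iso$", eg$gene_id)))
  # parent ids resolve, and iso parents produce "<id>-iso-ext<x>kb"
  expect_true(all(eg$parent_id %in% out$extended$annotation$genes$gene_id))
  iso_parents <- grepl("-iso$", eg$parent_id)
  expect_true(all(grepl("-iso-ext([1-9]|10)kb$", eg$gene_id[iso_parents])))
  # names never carry -iso (only ids are renamed)
  expect_false(any(grepl("-iso", eg$gene_name)))
})

test_that("emitted extensions are adjacent, exact-length, non-intersecting, maximal", {
  for (seed in c(2L, 31L)) {
    sim <- simulate_annotation(sim_params(n_genes = 150, seed = seed))
    out <- run_pipeline(sim)
    ann <- out$extended$annotation
    core <- ann$genes[biotype != "extension"]
    eg <- ann$genes[biotype == "extension"]
    parents <- core[match(eg$parent_id, core$gene_id)]
    step <- as.integer(sub("^.*-ext([0-9]+)kb$", "\\1", eg$gene_id))
    # exact length
    expect_true(all(eg$end - eg$start == step * 1000))
    # strand-aware adjacency: zero gap, zero overlap with the parent edge
    plus <- eg$strand == "+"
    expect_true(all(eg$start[plus] == parents$end[plus]))
    expect_true(all(eg$end[!plus] == parents$start[!plus]))
    expect_identical(eg$strand, parents$strand)
    # no same-strand non-parent gene body intersected (naive check)
    for (i in seq_len(nrow(eg))) {
      hits <- annoext:::naive_overlaps(core, eg$chrom[i], eg$start[i],
                                       eg$end[i], eg$strand[i],
                                       exclude = eg$parent_id[i])
      expect_length(hits, 0L)
    }
    # maximality: the next step up must fail (obstacle or chromosome bound)
    sizes <- ann$chrom_sizes
    for (i in which(step < 10L)) {
      len <- (step[i] + 1) * 1000
      if (plus[i]) { s <- parents$end[i]; e <- parents$end[i] + len }
      else { s <- parents$start[i] - len; e <- parents$start[i] }
      blocked <- s < 0 || e > sizes[[eg$chrom[i]]] ||
        length(annoext:::naive_overlaps(core, eg$chrom[i], s, e,
                                        eg$strand[i],
                                        exclude = eg$parent_id[i])) > 0
      expect_true(blocked)
    }
  }
})

test_that("removing a gene never decreases another gene's extension step", {
  sim <- simulate_annotation(sim_params(n_genes = 80, seed = 4))
  out <- run_pipeline(sim)
  base_steps <- out$extended$report$per_gene
  merged <- out$merged$annotation
  set.seed(8)
  for (victim in sample(merged$genes$gene_id, 5)) {
    reduced <- annotation(genes = merged$genes[gene_id != victim],
                          transcripts = merged$transcripts[gene_id != victim],
                          exons = merged$exons[
                            transcript_id %in%
                              merged$transcripts[gene_id != victim,
                                                 transcript_id]],
                          chrom_sizes = merged$chrom_sizes)
    res <- add_extension_genes(reduced)
    cmp <- merge(base_steps, res$report$per_gene, by = "gene_id")
    expect_true(all(cmp$step.y >= cmp$step.x))
  }
})

test_that("strict obstacle mode never exceeds the default steps", {
  sim <- simulate_annotation(sim_params(n_genes = 60, seed = 19))
  merged <- run_pipeline(sim)$merged$annotation
  loose <- add_extension_genes(merged)
  strict <- add_extension_genes(merged, strict_obstacles = TRUE)
  cmp <- merge(loose$report$per_gene, strict$report$per_gene, by = "gene_id",
               suffixes = c(".loose", ".strict"))
  expect_true(all(cmp$step.strict <= cmp$step.loose))
  # strict results also respect non-intersection against extensions
  ann <- strict$annotation
  eg <- ann$genes[biotype == "extension"]
  for (i in seq_len(nrow(eg))) {
    hits <- annoext:::naive_overlaps(ann$genes, eg$chrom[i], eg$start[i],
                                     eg$end[i], eg$strand[i],
                                     exclude = c(eg$parent_id[i],
                                                 eg$gene_id[i]))
    expect_length(hits, 0L)
  }
})

test_that("re-running extension on an extended annotation is refused", {
  ann <- simple_annotation(gene_row("G1", 0, 2000), chrom_sizes = c("1" = 1e5))
  once <- add_extension_genes(ann)
  expect_error(add_extension_genes(once$annotation), "already contains")
})
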