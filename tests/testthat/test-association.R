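# helpers to build a two-exon transcript annotation quickly
tx_annotation <- function(spec, source = "novel") {
  # spec: list of list(tid, gid, chrom, strand, exons = list(c(s, e), ...))
  g <- list(); t <- list(); e <- list()
  for (s in spec) {
    span <- range(unlist(s$exons))
    g[[length(g) + 1L]] <- gene_row(s$gid, span[1], span[2], s$strand,
                                    chrom = s$chrom)
    t[[length(t) + 1L]] <- data.table::data.table(
      transcript_id = s$tid, gene_id = s$gid, chrom = s$chrom,
      start = span[1], end = span[2], strand = s$strand, source = source)
    for (ex in s$exons)
      e[[length(e) + 1L]] <- data.table::data.table(
        transcript_id = s$tid, chrom = s$chrom, start = ex[1], end = ex[2],
        strand = s$strand)
  }
  annotation(genes = data.table::rbindlist(g),
             transcripts = data.table::rbindlist(t),
             exons = data.table::rbindlist(e))
}

test_that("exonic overlap counts shared bases of exon unions", {
  ref <- tx_annotation(list(list(tid = "RT1", gid = "G", chrom = "1",
                                 strand = "+",
                                 exons = list(c(250, 500)))), "reference")
  nov <- tx_annotation(list(list(tid = "NT1", gid = "NG", chrom = "1",
                                 strand = "+",
                                 exons = list(c(100, 400)))))
  expect_equal(exonic_overlap(get_transcript(nov, "NT1"), get_gene(ref, "G")),
               150L)
  # identical exon sets -> total exonic length
  expect_equal(exonic_overlap(get_transcript(ref, "RT1"), get_gene(ref, "G")),
               250L)
  # opposite strand -> 0
  nov2 <- tx_annotation(list(list(tid = "NT2", gid = "NG2", chrom = "1",
                                  strand = "-",
                                  exons = list(c(100, 400)))))
  expect_equal(exonic_overlap(get_transcript(nov2, "NT2"), get_gene(ref, "G")),
               0L)
})

test_that("multi-exon overlap equals a per-base brute-force count", {
  set.seed(9)
  for (rep in 1:20) {
    mk_exons <- function() {
      s1 <- floor(runif(1, 0, 500)); e1 <- s1 + floor(runif(1, 50, 300))
      s2 <- e1 + floor(runif(1, 10, 200)); e2 <- s2 + floor(runif(1, 50, 300))
      list(c(s1, e1), c(s2, e2))
    }
    ref <- tx_annotation(list(list(tid = "RT", gid = "G", chrom = "1",
                                   strand = "+", exons = mk_exons())),
                         "reference")
    nov <- tx_annotation(list(list(tid = "NT", gid = "NG", chrom = "1",
                                   strand = "+", exons = mk_exons())))
    got <- exonic_overlap(get_transcript(nov, "NT"), get_gene(ref, "G"))
    # per-base set intersection oracle
    bases <- function(ex_dt) unlist(Map(seq, ex_dt$start, ex_dt$end - 1))
    want <- length(intersect(bases(nov$exons[transcript_id == "NT"]),
                             bases(ref$exons[transcript_id == "RT"])))
    expect_equal(got, want)
  }
})

test_that("classification assigns codes and associates by maximal overlap", {
  ref <- tx_annotation(list(
    list(tid = "RA", gid = "A", chrom = "1", strand = "+",
         exons = list(c(1000, 1600), c(2000, 2600))),
    list(tid = "RB", gid = "B", chrom = "1", strand = "+",
         exons = list(c(3000, 3400))),
    list(tid = "RM", gid = "M", chrom = "1", strand = "-",
         exons = list(c(5000, 5800)))), "reference")

  nov <- tx_annotation(list(
    # identical chain to RA -> equal
    list(tid = "N_eq", gid = "NG1", chrom = "1", strand = "+",
         exons = list(c(1000, 1600), c(2000, 2600))),
    # overlaps A by 300 bp and B by 120 bp -> A wins
    list(tid = "N_two", gid = "NG2", chrom = "1", strand = "+",
         exons = list(c(2300, 2600), c(3280, 3400))),
    # extends past the 3' end of B -> extends
    list(tid = "N_ext", gid = "NG3", chrom = "1", strand = "+",
         exons = list(c(3000, 4200))),
    # inside A's span -> contained
    list(tid = "N_in", gid = "NG4", chrom = "1", strand = "+",
         exons = list(c(2100, 2500))),
    # + strand over the - strand gene M -> antisense, never associated
    list(tid = "N_anti", gid = "NG5", chrom = "1", strand = "+",
         exons = list(c(5000, 5800))),
    # no overlap at all -> intergenic
    list(tid = "N_int", gid = "NG6", chrom = "1", strand = "+",
         exons = list(c(9000, 9500)))))

  cls <- classify_transcripts(nov, ref)
  expect_equal(nrow(cls), 6L)
  expect_equal(cls$transcript_id, nov$transcripts$transcript_id)  # input order
  row <- function(t) cls[cls$transcript_id == t]
  expect_equal(row("N_eq")$gene_id, "A")
  expect_equal(as.character(row("N_eq")$code), "equal")
  expect_equal(row("N_two")$gene_id, "A")
  expect_equal(row("N_two")$exonic_overlap, 300L)
  expect_equal(row("N_ext")$gene_id, "B")
  expect_equal(as.character(row("N_ext")$code), "extends")
  expect_equal(row("N_in")$gene_id, "A")
  expect_equal(as.character(row("N_in")$code), "contained")
  expect_true(is.na(row("N_anti")$gene_id))
  expect_equal(as.character(row("N_anti")$code), "antisense")
  expect_true(is.na(row("N_int")$gene_id))
  expect_equal(as.character(row("N_int")$code), "intergenic")
  # never associated at zero overlap; strand always matches the target
  assoc <- cls[!is.na(cls$gene_id)]
  expect_true(all(assoc$exonic_overlap > 0))
  strand_of <- function(g) ref$genes[gene_id == g, strand]
  expect_true(all(mapply(function(t, g)
    nov$transcripts[transcript_id == t, strand] == strand_of(g),
    assoc$transcript_id, assoc$gene_id)))
})

test_that("novel chromosomes classify intergenic with a warning", {
  ref <- tx_annotation(list(list(tid = "RA", gid = "A", chrom = "1",
                                 strand = "+", exons = list(c(0, 100)))),
                       "reference")
  nov <- tx_annotation(list(list(tid = "NT", gid = "NG", chrom = "chrUn",
                                 strand = "+", exons = list(c(0, 100)))))
  expect_warning(cls <- classify_transcripts(nov, ref), "chrUn")
  expect_equal(as.character(cls$code), "intergenic")
})

test_that("classification is deterministic and recovers simulated parents", {
  for (seed in c(5L, 23L)) {
    sim <- simulate_annotation(sim_params(n_genes = 120, seed = seed))
    ref_f <- filter_biotypes(sim$reference)
    cls1 <- classify_transcripts(sim$novel, ref_f)
    cls2 <- classify_transcripts(sim$novel, ref_f)
    expect_identical(cls1, cls2)
    truth <- sim$truth$transcript_parents
    got <- cls1[match(truth$transcript_id, cls1$transcript_id)]
    real <- !is.na(truth$true_gene_id)
    expect_identical(got$gene_id[real], truth$true_gene_id[real])
    expect_true(all(is.na(got$gene_id[!real])))
    expect_true(all(as.character(got$code[truth$kind == "antisense"]) ==
                      "antisense"))
    expect_true(all(as.character(got$code[truth$kind == "intergenic"]) ==
                      "intergenic"))
    expect_true(all(as.character(got$code[truth$kind == "match"]) == "equal"))
  }
})
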