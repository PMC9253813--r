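fusion_annotation <- function() {
  make_annotation(
    list(tid = "ga.1", gid = "ga", chrom = "chrA", strand = "+",
         exons = rbind(c(1000, 2000))),
    list(tid = "gb.1", gid = "gb", chrom = "chrB", strand = "+",
         exons = rbind(c(5000, 6000))),
    list(tid = "gc.1", gid = "gc", chrom = "chrA", strand = "+",
         exons = rbind(c(50000, 51000))),
    list(tid = "gd.1", gid = "gd", chrom = "chrA", strand = "+",
         exons = rbind(c(3000, 4000))))
}

split_read <- function(id, cov_a, cov_b, gene2_chrom = "chrB",
                       gene2_start = 5000, read_len = 1000) {
  dplyr::bind_rows(
    make_aln(id, "chrA", "+", rbind(c(1000, 1000 + cov_a * read_len)),
             read_length = read_len, aligned_read_span = cov_a),
    make_aln(id, gene2_chrom, "+",
             rbind(c(gene2_start, gene2_start + cov_b * read_len)),
             read_length = read_len, aligned_read_span = cov_b,
             supplementary = TRUE))
}

pe <- tibble::tibble(gene_a = c("ga", "ga"), gene_b = c("gb", "gc"),
                     n_pairs = c(3L, 3L))

test_that("the four fusion criteria admit and reject as specified", {
  ann <- fusion_annotation()
  # 45% + 55% across chromosomes with PE support: inter-chromosome candidate
  cand <- detect_fusions(split_read("f1", 0.45, 0.55), ann, pe)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$category, "inter_chromosome")
  expect_equal(cand$gene_a, "ga")
  expect_equal(cand$gene_b, "gb")
  expect_equal(cand$pe_support, 3L)

  # a segment at 8% coverage fails the per-gene criterion
  r2 <- detect_fusions(split_read("f2", 0.92, 0.08), ann, pe)
  expect_equal(nrow(r2), 0)
  expect_equal(attr(r2, "rejected")$reason, "segment_coverage")

  # 45% + 50% leaves 5% of the read unexplained: total-coverage reject
  r3 <- detect_fusions(split_read("f3", 0.45, 0.50), ann, pe)
  expect_equal(attr(r3, "rejected")$reason, "total_coverage")

  # no (or too little) junction-spanning PE support
  r4 <- detect_fusions(split_read("f4", 0.45, 0.55), ann,
                       tibble::tibble(gene_a = "ga", gene_b = "gb",
                                      n_pairs = 1L))
  expect_equal(attr(r4, "rejected")$reason, "pe_support")

  # same chromosome, genes only 1 kb apart: rejected
  r5 <- detect_fusions(split_read("f5", 0.45, 0.55, gene2_chrom = "chrA",
                                  gene2_start = 3000), ann, pe)
  expect_equal(attr(r5, "rejected")$reason, "genes_too_close")

  # same chromosome, 48 kb apart: intra-chromosome candidate
  r6 <- detect_fusions(split_read("f6", 0.45, 0.55, gene2_chrom = "chrA",
                                  gene2_start = 50000), ann, pe)
  expect_equal(r6$category, "intra_chromosome")
})

test_that("coverage thresholds are strict: exactly 10% and 99% both fail", {
  ann <- fusion_annotation()
  at10 <- detect_fusions(split_read("s1", 0.90, 0.10), ann, pe)
  expect_equal(nrow(at10), 0)
  expect_equal(attr(at10, "rejected")$reason, "segment_coverage")
  just_over <- detect_fusions(split_read("s2", 0.90, 0.101), ann, pe)
  expect_equal(nrow(just_over), 1)

  at99 <- detect_fusions(split_read("s3", 0.50, 0.49), ann, pe)
  expect_equal(attr(at99, "rejected")$reason, "total_coverage")
  over99 <- detect_fusions(split_read("s4", 0.50, 0.491), ann, pe)
  expect_equal(nrow(over99), 1)
})

test_that("fusion summary tabulates categories and gene counts", {
  ann <- fusion_annotation()
  cand <- detect_fusions(dplyr::bind_rows(
    split_read("f1", 0.45, 0.55),
    split_read("f2", 0.48, 0.52),
    split_read("f3", 0.45, 0.55, gene2_chrom = "chrA",
               gene2_start = 50000)), ann, pe)
  s <- fusion_summary(cand)
  expect_equal(s$counts$total, 3)
  expect_equal(s$counts$inter_chromosome, 2)
  expect_equal(s$counts$intra_chromosome, 1)
  expect_equal(s$genes_per_fusion$n_genes, 2)
  expect_equal(unique(cand$multi_gene), FALSE)
  empty <- fusion_summary(detect_fusions(make_aln("x", "chrA", "+",
                                                  rbind(c(1000, 1900))),
                                         ann, pe))
  expect_equal(empty$counts$total, 0)
})

test_that("implanted chimeras are found and never contaminate isoforms", {
  sim <- noiseless_sim()
  truth_pairs <- paste(sim$truth$fusions$gene_a, sim$truth$fusions$gene_b)
  det_pairs <- paste(sim$res$fusions$gene_a, sim$res$fusions$gene_b)
  expect_setequal(det_pairs, truth_pairs)
  # every fusion read is absent from all isoform support lists
  fusion_reads <- unlist(sim$truth$fusions$read_ids)
  supporting <- unlist(sim$res$isoforms$support_reads)
  expect_equal(intersect(fusion_reads, supporting), character(0))
  # intra-chromosome candidates honour the 10 kb floor by construction
  intra <- sim$res$fusions[sim$res$fusions$category == "intra_chromosome", ]
  if (nrow(intra) > 0) {
    spans <- isocraft:::annotation_gene_spans(sim$truth$annotation)
    for (i in seq_len(nrow(intra))) {
      a <- spans[spans$gene_id == intra$gene_a[i], ]
      b <- spans[spans$gene_id == intra$gene_b[i], ]
      d <- max(a$start, b$start) - min(a$end, b$end)
      expect_gte(d, 10000)
    }
  }
})
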