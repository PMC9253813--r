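ref_annotation <- function() {
  make_annotation(
    list(tid = "t1", gid = "g1", chrom = "chr1", strand = "+",
         exons = rbind(c(1000, 1400), c(1600, 2000))),
    list(tid = "t2", gid = "g2", chrom = "chr1", strand = "-",
         exons = rbind(c(5000, 5400), c(5600, 6000))))
}

locus_row <- function(id, chrom, strand, start, end, n_isoforms = 1L) {
  tibble::tibble(locus_id = id, chrom = chrom, strand = strand,
                 start = start, end = end, n_isoforms = n_isoforms,
                 isoform_ids = list(character(0)))
}

test_that("gene novelty follows the overlap and strand criteria", {
  ann <- ref_annotation()
  # 15% of the locus span overlaps the gene -> novel
  lc <- classify_genes(locus_row("L1", "chr1", "+", 1850, 2850), ann)
  expect_equal(lc$gene_call, "novel")
  expect_equal(lc$gene_reason, "overlap_lt_20")
  # 60% overlap but antisense -> novel by strand mismatch
  lc2 <- classify_genes(locus_row("L2", "chr1", "-", 1000, 2000), ann)
  expect_equal(lc2$gene_call, "novel")
  expect_equal(lc2$gene_reason, "strand_mismatch")
  # 60% overlap, same strand -> known, matched to the gene
  lc3 <- classify_genes(locus_row("L3", "chr1", "+", 1200, 2200), ann)
  expect_equal(lc3$gene_call, "known")
  expect_equal(lc3$gene_match, "g1")
  # exactly 20% overlap counts as known
  lc4 <- classify_genes(locus_row("L4", "chr1", "+", 1800, 2800), ann)
  expect_equal(lc4$gene_call, "known")
  # no chromosome neighbours at all
  lc5 <- classify_genes(locus_row("L5", "chr9", "+", 0, 1000), ann)
  expect_equal(lc5$gene_reason, "no_overlap")
})

test_that("isoform novelty is splice-site based with a single-exon rule", {
  ann <- ref_annotation()
  loci <- classify_genes(locus_row("L1", "chr1", "+", 1000, 2000), ann)
  iso <- dplyr::bind_rows(
    make_iso("exact", "chr1", "+", rbind(c(1000, 1400), c(1600, 2000))),
    make_iso("shifted", "chr1", "+", rbind(c(1000, 1400), c(1612, 2000))),
    make_iso("inside", "chr1", "+", rbind(c(1050, 1350))),
    make_iso("hanging", "chr1", "+", rbind(c(1390, 1590))))
  calls <- classify_isoforms(iso, loci, ann)
  expect_equal(calls$novelty[calls$isoform_id == "exact"], "known")
  expect_equal(calls$novelty_reason[calls$isoform_id == "exact"],
               "chain_match")
  expect_equal(calls$novelty[calls$isoform_id == "shifted"],
               "novel_of_known_gene")
  expect_equal(calls$novelty_reason[calls$isoform_id == "shifted"],
               "new_splice_site")
  # single exon fully inside an annotated exon -> known by containment
  expect_equal(calls$novelty[calls$isoform_id == "inside"], "known")
  # single exon mostly intronic -> novel by the same rule
  expect_equal(calls$novelty[calls$isoform_id == "hanging"],
               "novel_of_known_gene")
  expect_true(all(calls$novelty_reason[calls$isoform_id %in%
                                         c("inside", "hanging")] ==
                    "single_exon_rule"))
})

test_that("isoforms of novel loci are always novel and partition holds", {
  ann <- ref_annotation()
  iso <- dplyr::bind_rows(
    make_iso("n1", "chr2", "+", rbind(c(100, 300), c(500, 700)),
             locus_id = "L9"),
    make_iso("k1", "chr1", "+", rbind(c(1000, 1400), c(1600, 2000)),
             locus_id = "L1"))
  loci <- classify_genes(dplyr::bind_rows(
    locus_row("L9", "chr2", "+", 100, 700),
    locus_row("L1", "chr1", "+", 1000, 2000)), ann)
  calls <- classify_isoforms(iso, loci, ann)
  expect_equal(calls$novelty[calls$isoform_id == "n1"], "novel_gene")
  parts <- table(calls$novelty)
  expect_equal(sum(parts), nrow(calls))
})

test_that("feeding the annotation back yields 100% known calls", {
  sim <- noiseless_sim()
  ann <- sim$truth$annotation
  aln <- dplyr::bind_rows(lapply(seq_len(nrow(ann)), function(i) {
    dplyr::bind_rows(
      make_aln(paste0("p", i, "a"), ann$chrom[i], ann$strand[i],
               ann$exons[[i]]),
      make_aln(paste0("p", i, "b"), ann$chrom[i], ann$strand[i],
               ann$exons[[i]]))
  }))
  iso <- collapse_isoforms(aln) |>
    prune_5prime_degraded() |>
    filter_supported(annotation = ann) |>
    assign_loci()
  loci <- loci_table(iso) |> classify_genes(ann, iso)
  calls <- classify_isoforms(iso, loci, ann)
  expect_true(all(calls$novelty == "known"))
  expect_true(all(loci$gene_call == "known"))
})

test_that("full-length status tests only the 5'-most splice donor", {
  ann <- ref_annotation()
  loci <- classify_genes(locus_row("L1", "chr1", "+", 1000, 2000), ann)
  iso <- dplyr::bind_rows(
    make_iso("same_donor", "chr1", "+", rbind(c(1100, 1400), c(1630, 2000))),
    make_iso("late_donor", "chr1", "+", rbind(c(1100, 1408), c(1600, 2000))),
    make_iso("single", "chr1", "+", rbind(c(1000, 1400))))
  out <- classify_isoforms(iso, loci, ann) |> evaluate_full_length(ann)
  expect_true(out$full_length[out$isoform_id == "same_donor"])
  expect_false(out$full_length[out$isoform_id == "late_donor"])
  expect_true(is.na(out$full_length[out$isoform_id == "single"]))

  # minus strand: the first donor is the 3'-most junction end
  ann_m <- make_annotation(
    list(tid = "tm", gid = "gm", chrom = "chr1", strand = "-",
         exons = rbind(c(100, 400), c(600, 900))))
  loci_m <- classify_genes(locus_row("Lm", "chr1", "-", 100, 900), ann_m)
  iso_m <- make_iso("m1", "chr1", "-", rbind(c(150, 400), c(600, 850)),
                    locus_id = "Lm")
  out_m <- classify_isoforms(iso_m, loci_m, ann_m) |>
    evaluate_full_length(ann_m)
  expect_true(out_m$full_length)
})

test_that("locus structure summary bins lengths like the standard report", {
  ann <- make_annotation(
    list(tid = "a", gid = "ga", chrom = "c", strand = "+",
         exons = rbind(c(0, 500))),
    list(tid = "b", gid = "gb", chrom = "c", strand = "+",
         exons = rbind(c(10000, 11500))),
    list(tid = "c", gid = "gc", chrom = "c", strand = "+",
         exons = rbind(c(20000, 22500))),
    list(tid = "d", gid = "gd", chrom = "c", strand = "+",
         exons = rbind(c(30000, 33500))))
  loci <- dplyr::bind_rows(
    locus_row("L1", "c", "+", 0, 500),
    locus_row("L2", "c", "+", 10000, 11500),
    locus_row("L3", "c", "+", 20000, 22500),
    locus_row("L4", "c", "+", 30000, 33500))
  s <- summarize_structure(loci, ann)
  expect_equal(s$length_bins$annotation_n, rep(1L, 4))
  expect_equal(s$length_bins$annotation_pct, rep("25.00%", 4))
  expect_equal(s$length_bins$pipeline_n, rep(1L, 4))
})
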