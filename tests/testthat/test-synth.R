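small_params <- function(...) {
  sim_params(seed = 5, n_chroms = 2, genes_per_chrom = 8, ...)
}

test_that("parameter validation rejects infeasible settings", {
  expect_error(sim_params(exon_len = c(300, 100)), "infeasible geometry")
  expect_error(sim_params(intron_len = c(0, 10)), "infeasible geometry")
  expect_error(sim_params(p_5prime_degradation = 1.2), "\\[0, 1\\]")
  expect_silent(sim_params())
})

test_that("a fixed seed gives byte-identical output files", {
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  simulate_truth_set(small_params(), outdir = d1)
  simulate_truth_set(small_params(), outdir = d2)
  for (f in c("genome.fa", "annotation.gff3", "flnc.sam", "counts.tsv",
              "pe_support.tsv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
  }
  # and a different seed diverges
  d3 <- file.path(tempdir(), "det3")
  simulate_truth_set(sim_params(seed = 6, n_chroms = 2, genes_per_chrom = 8),
                     outdir = d3)
  expect_false(identical(readLines(file.path(d1, "flnc.sam")),
                         readLines(file.path(d3, "flnc.sam"))))
})

test_that("without degradation every read chain equals its source chain", {
  tr <- simulate_truth_set(small_params(p_5prime_degradation = 0,
                                        p_unmapped = 0, noise_read_frac = 0,
                                        apa_jitter = 0, p_multimap = 0))
  sam_path <- tempfile(fileext = ".sam")
  isocraft:::write_sam(tr$sam, setNames(Biostrings::width(tr$genome),
                                        names(tr$genome)), sam_path)
  aln <- read_alignments(sam_path)
  aln <- aln[!aln$supplementary & !aln$secondary & aln$mapped, ]
  aln <- aln[!(aln$read_id %in% unlist(tr$fusions$read_ids)), ]
  tx_chain <- setNames(
    lapply(tr$transcripts$exons, isocraft:::blocks_to_junctions),
    tr$transcripts$transcript_id)
  org <- tr$reads
  for (i in seq_len(nrow(aln))) {
    tid <- org$transcript_id[org$read_id == aln$read_id[i]]
    got <- isocraft:::blocks_to_junctions(aln$blocks[[i]])
    expect_equal(unname(got), unname(tx_chain[[tid]]))
  }
})

test_that("implanted chimeras appear as supplementary-linked record pairs", {
  tr <- simulate_truth_set(small_params(n_fusions = 3, n_intra_fusions = 1))
  expect_equal(nrow(tr$fusions), 3)
  spans <- isocraft:::annotation_gene_spans(tr$annotation)
  for (i in seq_len(nrow(tr$fusions))) {
    for (rid in tr$fusions$read_ids[[i]]) {
      recs <- tr$sam[tr$sam$read_id == rid, ]
      expect_equal(nrow(recs), 2)
      expect_equal(sum(bitwAnd(recs$flag, 2048L) > 0), 1)
    }
    a <- spans[spans$gene_id == tr$fusions$gene_a[i], ]
    b <- spans[spans$gene_id == tr$fusions$gene_b[i], ]
    if (a$chrom == b$chrom) {
      expect_gte(max(a$start, b$start) - min(a$end, b$end), 10000)
    }
  }
})

test_that("the expression design implants exactly the requested R-specific set", {
  tr <- simulate_truth_set(small_params(n_R_specific_isoforms = 5,
                                        nb_dispersion = 0))
  expect_equal(sum(tr$expression$r_specific), 5)
  cnt <- as.matrix(tr$counts[, -(1:2)])
  rownames(cnt) <- tr$counts$transcript_id
  f <- compute_fpkm(cnt, tr$counts$length)
  spec <- r_specific_screen(f, paste0("A", 1:3), paste0("B", 1:3),
                            paste0("R", 1:3))
  flagged <- spec$id[spec$r_specific]
  expect_setequal(flagged,
                  tr$expression$transcript_id[tr$expression$r_specific])
})

test_that("truth metrics report perfect recovery on clean data", {
  sim <- noiseless_sim()
  m <- truth_metrics(sim$truth, sim$res)
  core <- m[m$stage %in% c("collapse", "novelty", "as_events", "apa",
                           "fusion", "r_specific"), ]
  expect_true(all(core$precision == 1))
  expect_true(all(core$recall == 1))
  # recall stays a proper rate under 5' degradation
  noisy <- simulate_truth_set(small_params(p_5prime_degradation = 0.3))
  sam <- tempfile(fileext = ".sam")
  dir <- file.path(tempdir(), "noisy-run")
  noisy <- simulate_truth_set(small_params(p_5prime_degradation = 0.3),
                              outdir = dir)
  res <- run_pipeline(file.path(dir, "genome.fa"),
                      file.path(dir, "annotation.gff3"),
                      file.path(dir, "flnc.sam"),
                      counts = file.path(dir, "counts.tsv"),
                      pe_support = file.path(dir, "pe_support.tsv"))
  mn <- truth_metrics(noisy, res)
  expect_true(all(mn$recall >= 0 & mn$recall <= 1, na.rm = TRUE))
  expect_true(all(mn$precision >= 0 & mn$precision <= 1, na.rm = TRUE))
})
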