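test_that("splice chains orient TSS/TES by strand", {
  b <- rbind(c(100, 200), c(300, 400))
  plus <- build_splice_chain(b, "+")
  expect_equal(unname(plus$junctions[1, ]), c(200, 300))
  expect_equal(plus$tss, 100)
  expect_equal(plus$tes, 400)
  minus <- build_splice_chain(b, "-")
  expect_equal(minus$tss, 400)
  expect_equal(minus$tes, 100)
  expect_equal(unname(minus$junctions[1, ]), c(200, 300))
  single <- build_splice_chain(rbind(c(100, 400)), "+")
  expect_equal(nrow(single$junctions), 0)
})

test_that("reads with identical junction chains collapse into one isoform", {
  aln <- dplyr::bind_rows(
    make_aln("r1", "chr1", "+", rbind(c(100, 200), c(300, 400))),
    make_aln("r2", "chr1", "+", rbind(c(120, 200), c(300, 400))),
    make_aln("r3", "chr1", "+", rbind(c(150, 200), c(300, 420))))
  iso <- collapse_isoforms(aln)
  expect_equal(nrow(iso), 1)
  expect_equal(iso$n_support, 3)
  expect_setequal(iso$support_reads[[1]], c("r1", "r2", "r3"))
  expect_equal(iso$tss, 100)  # 5'-most supporting start

  # one shifted acceptor keeps the reads apart at zero tolerance
  aln2 <- dplyr::bind_rows(
    make_aln("a", "chr1", "+", rbind(c(100, 200), c(300, 400))),
    make_aln("b", "chr1", "+", rbind(c(100, 200), c(305, 400))))
  expect_equal(nrow(collapse_isoforms(aln2)), 2)
})

test_that("collapse grouping matches the brute-force all-pairs oracle", {
  withr::local_seed(42)
  base_chains <- list(
    rbind(c(200, 300)), rbind(c(200, 300), c(500, 650)),
    rbind(c(210, 300), c(500, 650)), rbind(c(1000, 1200)))
  idx <- sample(1:4, 60, replace = TRUE)
  aln <- dplyr::bind_rows(lapply(seq_along(idx), function(i) {
    j <- base_chains[[idx[i]]]
    start <- j[1, 1] - sample(50:150, 1)
    end <- j[nrow(j), 2] + sample(50:150, 1)
    blocks <- isocraft:::junctions_to_blocks(start, end, j)
    make_aln(paste0("r", i), "chr1", "+", blocks)
  }))
  iso <- collapse_isoforms(aln)
  chains <- lapply(aln$blocks, isocraft:::blocks_to_junctions)
  lab <- oracle_collapse_groups(aln$chrom, aln$strand, chains)
  expect_equal(nrow(iso), length(unique(lab)))
  # every oracle group ends up in exactly one isoform
  iso_of_read <- setNames(rep(seq_len(nrow(iso)), iso$n_support),
                          unlist(iso$support_reads))
  for (g in unique(lab)) {
    expect_equal(length(unique(iso_of_read[aln$read_id[lab == g]])), 1)
  }
})

test_that("collapse is order-independent and conserves supporting reads", {
  withr::local_seed(7)
  aln <- dplyr::bind_rows(lapply(1:40, function(i) {
    n_ex <- sample(1:3, 1)
    s <- sample(seq(100, 2000, by = 100), 1)
    ex <- cbind(s + c(0, 300, 600)[seq_len(n_ex)],
                s + c(200, 500, 800)[seq_len(n_ex)])
    make_aln(paste0("r", i), sample(c("chr1", "chr2"), 1),
             sample(c("+", "-"), 1), ex)
  }))
  iso1 <- collapse_isoforms(aln)
  iso2 <- collapse_isoforms(aln[sample(nrow(aln)), ])
  expect_equal(iso1, iso2)
  expect_equal(sum(iso1$n_support), nrow(aln))
  expect_setequal(unlist(iso1$support_reads), aln$read_id)
})

test_that("5'-degraded suffix fragments are pruned and support merged", {
  # Y spans junctions J1,J2,J3; X carries the J2,J3 suffix starting inside Y
  y <- make_aln("y1", "chr1", "+",
                rbind(c(100, 200), c(300, 400), c(500, 600), c(700, 800)))
  y2 <- make_aln("y2", "chr1", "+",
                 rbind(c(110, 200), c(300, 400), c(500, 600), c(700, 800)))
  x <- make_aln("x1", "chr1", "+", rbind(c(350, 400), c(500, 600), c(700, 800)))
  iso <- collapse_isoforms(dplyr::bind_rows(y, y2, x))
  expect_equal(nrow(iso), 2)
  pruned <- prune_5prime_degraded(iso)
  expect_equal(nrow(pruned), 1)
  expect_setequal(pruned$support_reads[[1]], c("y1", "y2", "x1"))

  # overlapping but non-suffix chains are both retained
  a <- make_aln("a", "chr1", "+", rbind(c(100, 200), c(300, 400), c(500, 620)))
  b <- make_aln("b", "chr1", "+", rbind(c(350, 400), c(500, 600), c(700, 800)))
  iso2 <- prune_5prime_degraded(collapse_isoforms(dplyr::bind_rows(a, b)))
  expect_equal(nrow(iso2), 2)

  # opposite strands never prune each other
  c1 <- make_aln("c1", "chr1", "+", rbind(c(100, 200), c(300, 400), c(500, 600)))
  c2 <- make_aln("c2", "chr1", "-", rbind(c(300, 400), c(500, 600)))
  iso3 <- prune_5prime_degraded(collapse_isoforms(dplyr::bind_rows(c1, c2)))
  expect_equal(nrow(iso3), 2)

  # on the minus strand the 5' suffix is the genomic prefix
  my <- make_aln("my", "chr1", "-", rbind(c(100, 200), c(300, 400), c(500, 600)))
  mx <- make_aln("mx", "chr1", "-", rbind(c(100, 200), c(300, 380)))
  iso4 <- prune_5prime_degraded(collapse_isoforms(dplyr::bind_rows(my, mx)))
  expect_equal(nrow(iso4), 1)
  expect_setequal(iso4$support_reads[[1]], c("my", "mx"))
})

test_that("the three-way support filter applies each clause as stated", {
  ann <- make_annotation(
    list(tid = "t1", gid = "g1", chrom = "chr1", strand = "+",
         exons = rbind(c(100, 200), c(300, 400))))
  iso <- function(id, identity, exons, n_support = 1L) {
    make_iso(id, "chr1", "+", exons, n_support = n_support,
             max_identity = identity)
  }
  # singleton above the identity bar is kept
  kept <- filter_supported(iso("i1", 0.995, rbind(c(100, 200), c(320, 400))))
  expect_equal(nrow(kept), 1)
  # singleton at 0.98 with fully annotated junctions is kept
  kept2 <- filter_supported(iso("i2", 0.98, rbind(c(100, 200), c(300, 400))),
                            annotation = ann)
  expect_equal(nrow(kept2), 1)
  # singleton at 0.98 with one unsupported junction is discarded
  kept3 <- filter_supported(iso("i3", 0.98, rbind(c(100, 200), c(320, 400))),
                            annotation = ann)
  expect_equal(nrow(kept3), 0)
  expect_equal(attr(kept3, "discarded")$isoform_id, "i3")
  # two supporting reads suffice regardless of identity (inclusive bound)
  kept4 <- filter_supported(iso("i4", 0.90, rbind(c(100, 200), c(320, 400)),
                                n_support = 2L))
  expect_equal(nrow(kept4), 1)
  # identity bound is strict: exactly 0.99 fails the singleton clause
  kept5 <- filter_supported(iso("i5", 0.99, rbind(c(100, 200), c(320, 400))))
  expect_equal(nrow(kept5), 0)
  # junction evidence cannot vouch for a single-exon singleton
  kept6 <- filter_supported(iso("i6", 0.98, rbind(c(100, 400))),
                            annotation = ann)
  expect_equal(nrow(kept6), 0)
})

test_that("locus assignment merges at >=20% of the shorter span, transitively", {
  iso2 <- dplyr::bind_rows(
    make_iso("A", "chr1", "+", rbind(c(0, 1000))),
    make_iso("B", "chr1", "+", rbind(c(900, 1900))))
  iso2$locus_id <- NULL
  out <- assign_loci(iso2)           # overlap 100 = 10% of 1000
  expect_equal(length(unique(out$locus_id)), 2)

  iso1 <- dplyr::bind_rows(
    make_iso("A", "chr1", "+", rbind(c(0, 1000))),
    make_iso("B", "chr1", "+", rbind(c(800, 1800))))
  iso1$locus_id <- NULL
  out1 <- assign_loci(iso1)          # overlap 200 = exactly 20%: inclusive
  expect_equal(length(unique(out1$locus_id)), 1)

  # transitive closure: A-B and B-C overlap 25%, A-C don't overlap
  iso3 <- dplyr::bind_rows(
    make_iso("A", "chr1", "+", rbind(c(0, 1000))),
    make_iso("B", "chr1", "+", rbind(c(750, 1750))),
    make_iso("C", "chr1", "+", rbind(c(1500, 2500))))
  iso3$locus_id <- NULL
  out3 <- assign_loci(iso3)
  expect_equal(length(unique(out3$locus_id)), 1)

  # strands never merge; every isoform lands in exactly one locus
  iso4 <- dplyr::bind_rows(
    make_iso("A", "chr1", "+", rbind(c(0, 1000))),
    make_iso("B", "chr1", "-", rbind(c(0, 1000))))
  iso4$locus_id <- NULL
  out4 <- assign_loci(iso4)
  expect_equal(length(unique(out4$locus_id)), 2)
  expect_false(any(is.na(out4$locus_id)))
})
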