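codons <- function(n, pool = c("GCT", "GAA", "AAG", "CTG", "TCA", "GGC")) {
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

test_that("ORF calls respect the inclusive 100-aa boundary", {
  withr::local_seed(1)
  orf100 <- paste0("ATG", codons(99), "TAA")
  o <- find_orfs(orf100, min_aa = 100)
  expect_equal(nrow(o), 1)
  expect_equal(o$aa_length, 100L)
  expect_true(o$is_complete)
  expect_equal(o$end - o$start, 3 * 100 + 3)

  orf99 <- paste0("ATG", codons(98), "TAA")
  expect_equal(nrow(find_orfs(orf99, min_aa = 100)), 0)
})

test_that("ORF finder matches the exhaustive-scan oracle on random sequences", {
  withr::local_seed(23)
  for (i in 1:200) {
    s <- random_seq(sample(200:800, 1))
    mine <- find_orfs(s, min_aa = 10)
    mine <- mine[mine$has_start & mine$has_stop, ]
    oracle <- oracle_orfs(s, min_aa = 10)
    expect_equal(nrow(mine), nrow(oracle))
    if (nrow(oracle) > 0) {
      key <- function(d) sort(paste(d$frame, d$start, d$end, d$aa_length))
      expect_equal(key(mine), key(oracle))
    }
  }
})

test_that("partial ORFs are reported and flagged incomplete", {
  withr::local_seed(2)
  # no ATG before the first stop: 5'-partial
  partial5 <- paste0(codons(60, pool = c("GCT", "GAA", "AAG")), "TAA",
                     strrep("C", 30))
  o <- find_orfs(partial5, min_aa = 50)
  expect_true(any(!o$has_start & o$has_stop & !o$is_complete))
  # ATG running off the 3' end without a stop
  partial3 <- paste0(strrep("C", 12), "ATG", codons(60))
  o3 <- find_orfs(partial3, min_aa = 50)
  expect_true(any(o3$has_start & !o3$has_stop & !o3$is_complete))
})

test_that("Fickett TESTCODE equals the hand-computed table lookup", {
  # poly-A: every A position count equal -> position value n/3/(n/3+1);
  # content 1.0 for A, 0 for C/G/T -> all at their terminal table bins
  s <- strrep("A", 300)
  got <- as.numeric(fickett_score(s))
  pos_prob <- c(A = 0.22, C = 0.23, G = 0.08, T = 0.09)  # lowest bin
  con_prob <- c(A = 0.28, C = 0.31, G = 0.29, T = 0.51)  # A top bin, rest 0
  pw <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
  cw <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
  expect_equal(got, sum(pw * pos_prob) + sum(cw * con_prob), tolerance = 1e-9)
  expect_false(attr(fickett_score(strrep("A", 150)), "reliable"))
  expect_true(attr(fickett_score(strrep("A", 200)), "reliable"))
})

test_that("Fickett scores stay inside the table-derived range", {
  withr::local_seed(31)
  for (i in 1:50) {
    s <- random_seq(sample(200:1000, 1))
    v <- as.numeric(fickett_score(s))
    expect_gte(v, 0.2)
    expect_lte(v, 1.45)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_true(is.finite(as.numeric(fickett_score(rc))))
  }
})

test_that("coding sequence outscores its shuffles on average", {
  withr::local_seed(41)
  sc <- isocraft:::sense_codons()
  cds <- function() paste0("ATG", paste(sample(sc$codons, 180, replace = TRUE,
                                               prob = sc$w), collapse = ""),
                           "TAA")
  diffs <- replicate(40, {
    s <- cds()
    shuf <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    as.numeric(fickett_score(s)) - as.numeric(fickett_score(shuf))
  })
  expect_gt(mean(diffs), 0)
})

test_that("hexamer LLR separates biased coding from uniform sequence", {
  withr::local_seed(19)
  sc <- isocraft:::sense_codons()
  cds_seqs <- replicate(40, paste(sample(sc$codons, 150, replace = TRUE,
                                         prob = sc$w), collapse = ""))
  nc_seqs <- replicate(40, random_seq(450))
  tab <- train_hexamer_table(cds_seqs, nc_seqs)
  cod_scores <- vapply(replicate(20, paste(
    sample(sc$codons, 120, replace = TRUE, prob = sc$w), collapse = "")),
    hexamer_score, numeric(1), hex_table = tab)
  nc_scores <- vapply(replicate(20, random_seq(360)),
                      hexamer_score, numeric(1), hex_table = tab)
  expect_gt(mean(cod_scores), mean(nc_scores))
  expect_gt(mean(cod_scores), 0)
})

test_that("lncRNA candidacy applies length, homology, ORF and score gates", {
  withr::local_seed(53)
  sc <- isocraft:::sense_codons()
  tab <- train_hexamer_table(
    replicate(30, paste(sample(sc$codons, 150, replace = TRUE, prob = sc$w),
                        collapse = "")),
    replicate(30, random_seq(450)))
  lnc <- isocraft:::noncoding_rna(1029)
  coding <- paste0(random_seq(30), "ATG",
                   paste(sample(sc$codons, 150, replace = TRUE, prob = sc$w),
                         collapse = ""), "TAA", random_seq(30))
  short <- random_seq(150)
  seqs <- c(lnc = lnc, coding = coding, short = short, flagged = lnc)
  calls <- call_lncrna(seqs, tab,
                       homology_flags = c(flagged = TRUE))
  expect_true(calls$lncrna[calls$id == "lnc"])
  expect_false(calls$lncrna[calls$id == "coding"])
  expect_equal(calls$exclusion_reason[calls$id == "coding"], "orf")
  expect_equal(calls$exclusion_reason[calls$id == "short"], "length")
  expect_equal(calls$exclusion_reason[calls$id == "flagged"], "homology")
  # candidates never carry a reportable ORF
  expect_true(all(calls$longest_orf_aa[calls$lncrna] < 100))
})
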