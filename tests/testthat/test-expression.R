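test_that("FPKM follows the closed form and its invariances", {
  m <- matrix(c(100, 0, 900e3, 99.9e4), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  m[, 1] <- c(100, 999900)
  f <- compute_fpkm(m, lengths = c(1000, 500))
  # count 100, length 1000 nt, library 1e6 -> FPKM 100
  expect_equal(f["a", "s1"], 100)
  # zero count -> zero FPKM
  m2 <- matrix(c(0, 1000), 2, 1, dimnames = list(c("a", "b"), "s"))
  f2 <- compute_fpkm(m2, c(1000, 500))
  expect_equal(f2["a", "s"], 0)
  # doubling every count in a sample leaves that sample's FPKM unchanged
  f3 <- compute_fpkm(m * 2, c(1000, 500))
  expect_equal(f3, f)
  # within-sample ordering of counts is preserved for equal lengths
  m4 <- matrix(c(5, 50, 500), 3, 1, dimnames = list(letters[1:3], "s"))
  f4 <- compute_fpkm(m4, rep(100, 3))
  expect_true(all(diff(f4[, 1]) > 0))
  # zero-length feature is an error naming the feature
  expect_error(compute_fpkm(m, c(1000, 0)), "b")
})

test_that("the row-wise Welch test matches stats::t.test", {
  withr::local_seed(9)
  x <- matrix(rnorm(60, 5), 10, 6)
  res <- isocraft:::welch_t_rows(x[, 1:3], x[, 4:6])
  for (i in 1:10) {
    ref <- t.test(x[i, 4:6], x[i, 1:3])
    expect_equal(res$p[i], ref$p.value, tolerance = 1e-12)
    expect_equal(res$t[i], unname(ref$statistic), tolerance = 1e-12)
  }
})

test_that("deg_screen flags by q-value and fold change, BH as hand-computed", {
  # Benjamini-Hochberg on p = (.01,.02,.03,.04) gives q = .04 throughout
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  withr::local_seed(13)
  base <- matrix(rnbinom(300 * 6, mu = 200, size = 10), 300, 6,
                 dimnames = list(paste0("f", 1:300),
                                 c(paste0("A", 1:3), paste0("R", 1:3))))
  base[1:20, 4:6] <- rnbinom(60, mu = 3200, size = 10)
  base[21, ] <- 0
  f <- compute_fpkm(base, rep(1000, 300))
  expect_message(res <- deg_screen(f, paste0("A", 1:3), paste0("R", 1:3)),
                 "all-zero")
  expect_equal(attr(res, "excluded"), "f21")
  # identical group values: zero fold change, never a DEG
  same <- f["f300", paste0("A", 1:3)]
  f2 <- f; f2["f300", paste0("R", 1:3)] <- same
  res2 <- suppressMessages(deg_screen(f2, paste0("A", 1:3), paste0("R", 1:3)))
  expect_equal(res2$log2fc[res2$id == "f300"], 0)
  expect_false(res2$deg_up[res2$id == "f300"])
  # q-values are BH of the p-values, monotone and >= p
  expect_equal(res$qvalue, p.adjust(res$pvalue, "BH"))
  ord <- order(res$pvalue)
  expect_true(all(diff(res$qvalue[ord]) >= -1e-12))
  expect_true(all(res$qvalue >= res$pvalue - 1e-12))
  # most implanted 16-fold features are recovered
  expect_gt(sum(res$deg_up[res$id %in% paste0("f", 1:20)]), 15)
})

test_that("the restorer-specific screen implements both clauses", {
  f <- rbind(
    pattern  = c(0.1, 0.15, 0.1, 0.12, 0.1, 0.1, 5.0, 6.1, 4.8),
    logfc    = c(10, 11, 9, 10, 10, 10, 95, 88, 87),
    logfc_a_hot = c(10, 10, 1.5, 10, 10, 10, 95, 88, 87),
    neither  = c(10, 10, 10, 10, 10, 10, 30, 28, 35))
  colnames(f) <- c(paste0("A", 1:3), paste0("B", 1:3), paste0("R", 1:3))
  out <- r_specific_screen(f, paste0("A", 1:3), paste0("B", 1:3),
                           paste0("R", 1:3))
  expect_true(out$r_specific[out$id == "pattern"])
  expect_true(out$by_pattern[out$id == "pattern"])
  # 9x mean with one replicate above 1 FPKM: flagged via the log FC clause
  expect_true(out$r_specific[out$id == "logfc_a_hot"])
  expect_false(out$by_pattern[out$id == "logfc_a_hot"])
  expect_true(out$by_logfc[out$id == "logfc_a_hot"])
  expect_false(out$r_specific[out$id == "neither"])
  # flagged features always have the largest mean in R
  expect_true(all(out$mean_fpkm_r[out$r_specific] >
                    pmax(out$mean_fpkm_a, out$mean_fpkm_b)[out$r_specific]))
  # conjunctive rule is stricter
  both <- r_specific_screen(f, paste0("A", 1:3), paste0("B", 1:3),
                            paste0("R", 1:3), rule = "both")
  expect_true(all(both$r_specific <= out$r_specific))
})

test_that("2^-ddCt relative expression is exact", {
  expect_equal(ddct(c(20, 20), c(20, 20), calibrator_dct = 0)$mean, 1.0)
  expect_equal(ddct(18, 20, calibrator_dct = 0)$mean, 4.0)  # ddCt -2
  r <- ddct(c(20, 20), c(18, 18), calibrator_dct = 3)
  expect_equal(r$mean, 2.0)
  expect_equal(r$rel, c(2, 2))
  expect_error(ddct(c(20, NA), c(18, 18), 0), "finite")
})

test_that("type-I error and power meet the operating targets", {
  withr::local_seed(77)
  # null: no effects -> empirical per-test alpha near nominal
  rej <- replicate(8, {
    cnt <- matrix(rnbinom(500 * 6, mu = 300, size = 10), 500, 6,
                  dimnames = list(paste0("f", 1:500),
                                  c(paste0("A", 1:3), paste0("R", 1:3))))
    f <- compute_fpkm(cnt, rep(1000, 500))
    res <- suppressMessages(deg_screen(f, paste0("A", 1:3), paste0("R", 1:3)))
    mean(res$pvalue < 0.05, na.rm = TRUE)
  })
  expect_lte(mean(rej), 0.07)
  # 8-fold effects at n = 3, dispersion 0.1: high power at q < 0.05
  hits <- replicate(8, {
    cnt <- matrix(rnbinom(500 * 6, mu = 300, size = 10), 500, 6,
                  dimnames = list(paste0("f", 1:500),
                                  c(paste0("A", 1:3), paste0("R", 1:3))))
    cnt[1:50, 4:6] <- rnbinom(150, mu = 2400, size = 10)
    f <- compute_fpkm(cnt, rep(1000, 500))
    res <- suppressMessages(deg_screen(f, paste0("A", 1:3), paste0("R", 1:3)))
    c(power = mean(res$deg_up[res$id %in% paste0("f", 1:50)]),
      fdr = sum(res$deg_up & !(res$id %in% paste0("f", 1:50))) /
        max(1, sum(res$deg_up)))
  })
  expect_gte(mean(hits["power", ]), 0.8)
  expect_lte(mean(hits["fdr", ]), 0.10)
})
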