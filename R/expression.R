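# FPKM, differential-expression screen (Welch t on log2(FPKM+1) + BH), the
# restorer-line specificity screen, and the 2^-ddCt qPCR calculation.

#' Compute FPKM from a count matrix
#'
#' `fpkm[i, s] = counts[i, s] * 1e9 / (length[i] * total_counts[s])`.
#'
#' @param counts non-negative integer matrix (features x samples) or a tibble
#'   with an id column plus sample columns.
#' @param lengths effective feature lengths in nt, recycled by feature; zero
#'   or missing lengths are an error naming the feature.
#' @return FPKM matrix with the input dimnames.
#' @export
#' @examples
#' compute_fpkm(matrix(c(100, 0), 2, 1, dimnames = list(c("a", "b"), "s1")),
#'              lengths = c(1000, 500))
compute_fpkm <- function(counts, lengths) {
  m <- as.matrix(counts)
  bad <- which(is.na(lengths) | lengths <= 0)
  if (length(bad) > 0) {
    abort(paste0("zero or missing length for feature(s): ",
                 paste(head(rownames(m)[bad] %||% bad, 5), collapse = ", ")))
  }
  totals <- colSums(m)
  if (any(totals <= 0)) abort("every sample must have a positive total count")
  sweep(m / lengths, 2, totals, "/") * 1e9
}

# moderated two-group t via limma on the combined log-scale matrix; falls
# back to the exact zero-variance convention when replicates are degenerate
moderated_t_rows <- function(y1, y2) {
  y <- cbind(y1, y2)
  design <- cbind(intercept = 1,
                  grp = c(rep(0, ncol(y1)), rep(1, ncol(y2))))
  fit <- limma::lmFit(y, design)
  if (all(fit$sigma < 1e-10)) {
    m1 <- rowMeans(y1); m2 <- rowMeans(y2)
    return(ifelse(m1 == m2, 1, 0))
  }
  eb <- limma::eBayes(fit, trend = TRUE)
  eb$p.value[, "grp"]
}

# vectorized two-sided Welch t-test on rows of x (group 1) vs y (group 2)
welch_t_rows <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1, stats::var); v2 <- apply(y, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  # degenerate zero-variance groups: differing means are unambiguous
  zero_se <- se2 == 0
  p[zero_se] <- ifelse(m1[zero_se] == m2[zero_se], 1, 0)
  p[!zero_se & !is.finite(tstat)] <- NA_real_
  list(t = tstat, df = df, p = p)
}

#' Differential-expression screen between two lines
#'
#' Per feature: log2 fold change on pseudocounted mean FPKM
#' (`log2((mean2 + 1) / (mean1 + 1))`), a two-sided two-group test on
#' log2(FPKM + 1) replicate values, and Benjamini-Hochberg adjustment.
#' `deg_up` requires `q < deg_fdr` and `log2fc > deg_min_abs_logfc`,
#' `deg_down` the mirror image. The default test is a moderated t
#' (limma's empirical-Bayes variance shrinkage, mean-variance trend): with
#' three replicates a per-feature variance estimate is too noisy to reach
#' useful power at a 5% FDR, and pooling variance information across
#' features is the standard remedy. `test = "welch"` gives the unmoderated
#' Welch t-test. Features that are all-zero across both groups are excluded
#' and reported in `attr(, "excluded")`.
#'
#' @param fpkm FPKM matrix (features x samples).
#' @param group1,group2 column names (or indices) of the two replicate
#'   groups; fold changes are group2 vs group1.
#' @param test `"moderated"` (default) or `"welch"`.
#' @param thresholds [iso_thresholds()].
#' @return tibble of class `iso_screen`: `id`, `mean_fpkm_1`, `mean_fpkm_2`,
#'   `log2fc`, `pvalue`, `qvalue`, `deg_up`, `deg_down`.
#' @export
deg_screen <- function(fpkm, group1, group2,
                       test = c("moderated", "welch"),
                       thresholds = iso_thresholds()) {
  test <- match.arg(test)
  x1 <- fpkm[, group1, drop = FALSE]
  x2 <- fpkm[, group2, drop = FALSE]
  if (ncol(x1) < 2 || ncol(x2) < 2) {
    abort("deg_screen needs at least two replicates per group")
  }
  ids <- rownames(fpkm) %||% as.character(seq_len(nrow(fpkm)))
  allzero <- rowSums(x1) == 0 & rowSums(x2) == 0
  if (any(allzero)) {
    inform(sprintf("deg_screen: excluding %d all-zero feature(s)",
                   sum(allzero)))
  }
  x1 <- x1[!allzero, , drop = FALSE]
  x2 <- x2[!allzero, , drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  lfc <- log2((m2 + 1) / (m1 + 1))
  y1 <- log2(x1 + 1); y2 <- log2(x2 + 1)
  p <- if (test == "moderated" && nrow(y1) >= 10) {
    moderated_t_rows(y1, y2)
  } else {
    welch_t_rows(y1, y2)$p
  }
  q <- p.adjust(p, method = "BH")
  res <- tibble(
    id = ids[!allzero],
    mean_fpkm_1 = unname(m1), mean_fpkm_2 = unname(m2),
    log2fc = unname(lfc), pvalue = unname(p), qvalue = unname(q),
    deg_up = !is.na(q) & q < thresholds$deg_fdr &
      lfc > thresholds$deg_min_abs_logfc,
    deg_down = !is.na(q) & q < thresholds$deg_fdr &
      lfc < -thresholds$deg_min_abs_logfc)
  attr(res, "excluded") <- ids[allzero]
  class(res) <- c("iso_screen", class(res))
  res
}

#' Restorer-line specificity screen
#'
#' Flags a feature as restorer-specific when either clause holds:
#' * fold-change clause: log2 fold change of R over A **and** over B (on
#'   pseudocounted mean FPKM) both exceed `specific_min_logfc`;
#' * expression-pattern clause: FPKM above `specific_min_fpkm` in every R
#'   replicate and below it in every A and B replicate.
#'
#' `rule = "both"` requires the two clauses jointly.
#'
#' @param fpkm FPKM matrix.
#' @param a_cols,b_cols,r_cols replicate columns of the sterile (A),
#'   maintainer (B) and restorer (R) lines.
#' @param rule `"either"` (default) or `"both"`.
#' @param thresholds [iso_thresholds()].
#' @return tibble: `id`, `mean_fpkm_a/b/r`, `log2fc_ra`, `log2fc_rb`,
#'   `by_logfc`, `by_pattern`, `r_specific`.
#' @export
r_specific_screen <- function(fpkm, a_cols, b_cols, r_cols,
                              rule = c("either", "both"),
                              thresholds = iso_thresholds()) {
  rule <- match.arg(rule)
  A <- fpkm[, a_cols, drop = FALSE]
  B <- fpkm[, b_cols, drop = FALSE]
  R <- fpkm[, r_cols, drop = FALSE]
  ma <- rowMeans(A); mb <- rowMeans(B); mr <- rowMeans(R)
  lra <- log2((mr + 1) / (ma + 1))
  lrb <- log2((mr + 1) / (mb + 1))
  thr <- thresholds$specific_min_fpkm
  by_logfc <- lra > thresholds$specific_min_logfc &
    lrb > thresholds$specific_min_logfc
  by_pattern <- apply(R > thr, 1, all) & apply(A < thr, 1, all) &
    apply(B < thr, 1, all)
  flag <- if (rule == "either") by_logfc | by_pattern else
    by_logfc & by_pattern
  tibble(id = rownames(fpkm) %||% as.character(seq_len(nrow(fpkm))),
         mean_fpkm_a = unname(ma), mean_fpkm_b = unname(mb),
         mean_fpkm_r = unname(mr),
         log2fc_ra = unname(lra), log2fc_rb = unname(lrb),
         by_logfc = unname(by_logfc), by_pattern = unname(by_pattern),
         r_specific = unname(flag))
}

#' Relative expression by the 2^-ddCt method
#'
#' `dCt = Ct_target - Ct_reference` per sample; `ddCt = dCt - dCt_calibrator`;
#' relative expression is `2^-ddCt`, reported per replicate with mean and sd.
#'
#' @param ct_target numeric vector of target-gene Ct replicates.
#' @param ct_reference matching reference-gene (internal control) Ct values.
#' @param calibrator_dct scalar dCt of the calibrator sample.
#' @return list: `rel` (per-replicate 2^-ddCt), `mean`, `sd`.
#' @export
#' @examples
#' ddct(c(20, 20), c(18, 18), calibrator_dct = 3)  # 2-fold
ddct <- function(ct_target, ct_reference, calibrator_dct) {
  if (length(ct_target) != length(ct_reference)) {
    abort("target and reference Ct vectors must align")
  }
  if (any(!is.finite(c(ct_target, ct_reference, calibrator_dct)))) {
    abort("Ct values must be finite")
  }
  dct <- ct_target - ct_reference
  ddct <- dct - calibrator_dct
  rel <- 2^(-ddct)
  list(rel = rel, mean = mean(rel), sd = if (length(rel) > 1) sd(rel) else NA_real_)
}
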