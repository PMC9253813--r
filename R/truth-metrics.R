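# Score a pipeline run against the simulator's ground truth: per-stage
# confusion counts, precision and recall.

truth_chain_keys <- function(transcripts) {
  vapply(seq_len(nrow(transcripts)), function(i) {
    chain_key(transcripts$chrom[i], transcripts$strand[i],
              blocks_to_junctions(transcripts$exons[[i]]))
  }, character(1))
}

# greedy one-to-one matching of recovered single-exon isoforms to
# single-exon truth transcripts by reciprocal overlap
match_single_exon <- function(iso, truth_tx, frac = 0.5) {
  matches <- rep(NA_integer_, nrow(iso))
  taken <- logical(nrow(truth_tx))
  for (i in seq_len(nrow(iso))) {
    cand <- which(!taken & truth_tx$chrom == iso$chrom[i] &
                    truth_tx$strand == iso$strand[i])
    for (k in cand) {
      ts <- truth_tx$exons[[k]][1, 1]; te <- truth_tx$exons[[k]][nrow(truth_tx$exons[[k]]), 2]
      ov <- overlap_len(iso$start[i], iso$end[i], ts, te)
      if (ov >= frac * (iso$end[i] - iso$start[i]) &&
          ov >= frac * (te - ts)) {
        matches[i] <- k; taken[k] <- TRUE; break
      }
    }
  }
  matches
}

#' Score pipeline results against the simulated truth
#'
#' Computes per-stage confusion counts. Stages: `collapse` (recovered
#' isoform chains vs truth transcript chains; single-exon transcripts
#' matched by reciprocal span overlap), `novelty` (novel calls vs the
#' expected calls implied by construction; noise-read isoforms are expected
#' novel genes), `as_events` (detected vs implanted signatures), `apa`
#' (site positions within `tolerance`), `fusion` (gene pairs), `lncrna`
#' (candidates among isoforms traceable to novel-gene transcripts vs the
#' implanted noncoding ones), `r_specific` and `deg_up` (screen flags vs
#' design).
#'
#' @param truth `truth_set` from [simulate_truth_set()].
#' @param results `iso_pipeline` from [run_pipeline()].
#' @param tolerance APA position tolerance in nt (default half the
#'   clustering window).
#' @return tibble: `stage`, `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
truth_metrics <- function(truth, results, tolerance = 12) {
  iso <- results$isoforms
  tx <- truth$transcripts
  row_of <- function(stage, tp, fp, fn) {
    tibble(stage = stage, tp = tp, fp = fp, fn = fn,
           precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
           recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn))
  }

  # ---- collapse: chain-for-chain recovery
  tx_keys <- truth_chain_keys(tx)
  tx_multi <- vapply(tx$exons, nrow, integer(1)) > 1
  iso_keys <- vapply(seq_len(nrow(iso)), function(i) {
    chain_key(iso$chrom[i], iso$strand[i], iso$junctions[[i]])
  }, character(1))
  multi_tp <- sum(tx_keys[tx_multi] %in% iso_keys[iso$n_junctions > 0])
  se_iso <- iso[iso$n_junctions == 0, ]
  se_match <- match_single_exon(se_iso, tx[!tx_multi, , drop = FALSE])
  se_tp <- sum(!is.na(se_match))
  tp <- multi_tp + se_tp
  fp <- nrow(iso) - sum(iso_keys %in% tx_keys[tx_multi]) - se_tp
  fn <- nrow(tx) - tp
  metrics <- row_of("collapse", tp, fp, fn)

  # ---- per-isoform origin via supporting reads (majority vote)
  origin_of <- function(i) {
    rids <- iso$support_reads[[i]]
    o <- truth$reads[truth$reads$read_id %in% rids, ]
    if (nrow(o) == 0) return(NA_character_)
    if (all(o$origin == "noise")) return("noise")
    tt <- table(o$transcript_id[o$origin == "transcript"])
    if (length(tt) == 0) return(NA_character_)
    names(tt)[which.max(tt)]
  }
  iso_origin <- vapply(seq_len(nrow(iso)), origin_of, character(1))
  expected_novelty <- ifelse(
    iso_origin == "noise", "novel_gene",
    tx$expected_novelty[match(iso_origin, tx$transcript_id)])
  known <- !is.na(expected_novelty)
  pred_novel <- iso$novelty != "known"
  true_novel <- expected_novelty != "known"
  tp <- sum(known & pred_novel & true_novel)
  fp <- sum(known & pred_novel & !true_novel)
  # recall over truth transcripts expected novel (plus noise families)
  truth_novel_ids <- tx$transcript_id[tx$expected_novelty != "known"]
  fn <- sum(!(truth_novel_ids %in% iso_origin[known & pred_novel]))
  metrics <- bind_rows(metrics, row_of("novelty", tp, fp, fn))

  # ---- AS events
  implant <- tx |> filter(!is.na(.data$as_type))
  truth_sig <- paste(implant$as_type, implant$chrom, implant$strand,
                     implant$as_start, implant$as_end, sep = ":")
  det_sig <- results$as$events$signature
  tp <- sum(truth_sig %in% det_sig)
  fp <- sum(!(det_sig %in% truth_sig))
  fn <- sum(!(truth_sig %in% det_sig))
  metrics <- bind_rows(metrics, row_of("as_events", tp, fp, fn))

  # ---- APA sites: position match within tolerance, one-to-one per strand
  det <- results$polya$sites
  taken <- rep(FALSE, nrow(det))
  tp <- 0L
  for (i in seq_len(nrow(truth$apa_sites))) {
    s <- truth$apa_sites[i, ]
    j <- which(!taken & det$chrom == s$chrom & det$strand == s$strand &
                 abs(det$position - s$position) <= tolerance)
    if (length(j) > 0) { taken[j[1]] <- TRUE; tp <- tp + 1L }
  }
  metrics <- bind_rows(metrics, row_of("apa", tp, sum(!taken),
                                       nrow(truth$apa_sites) - tp))

  # ---- fusions: unordered gene pairs
  det_pairs <- paste(results$fusions$gene_a, results$fusions$gene_b)
  truth_pairs <- paste(truth$fusions$gene_a, truth$fusions$gene_b)
  tp <- sum(unique(det_pairs) %in% truth_pairs)
  fp <- sum(!(unique(det_pairs) %in% truth_pairs))
  fn <- sum(!(truth_pairs %in% det_pairs))
  metrics <- bind_rows(metrics, row_of("fusion", tp, fp, fn))

  # ---- lncRNA among isoforms traceable to novel-gene transcripts
  if (!is.null(results$lncrna$calls) && nrow(results$lncrna$calls) > 0) {
    calls <- results$lncrna$calls
    call_origin <- iso_origin[match(calls$id, iso$isoform_id)]
    in_scope <- !is.na(call_origin) & call_origin != "noise" &
      tx$class[match(call_origin, tx$transcript_id)] == "novel_gene"
    truth_nc <- tx$transcript_id[tx$class == "novel_gene" & !tx$coding]
    pred_pos <- calls$lncrna & in_scope
    tp <- sum(pred_pos & call_origin %in% truth_nc)
    fp <- sum(pred_pos & !(call_origin %in% truth_nc))
    fn <- sum(!(truth_nc %in% call_origin[pred_pos]))
    metrics <- bind_rows(metrics, row_of("lncrna", tp, fp, fn))
  }

  # ---- expression screens
  if (!is.null(results$screen)) {
    spec <- results$screen$r_specific
    truth_spec <- truth$expression$transcript_id[truth$expression$r_specific]
    flagged <- spec$id[spec$r_specific]
    tp <- sum(flagged %in% truth_spec)
    metrics <- bind_rows(metrics,
                         row_of("r_specific", tp,
                                length(flagged) - tp,
                                length(truth_spec) - tp))
    deg <- results$screen$deg
    truth_up <- truth$expression$transcript_id[truth$expression$deg_r_vs_a]
    up <- deg$id[deg$deg_up]
    tp <- sum(up %in% truth_up)
    metrics <- bind_rows(metrics,
                         row_of("deg_up", tp, length(up) - tp,
                                length(truth_up) - tp))
  }
  metrics
}
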