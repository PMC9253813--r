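# Compare recovered loci/isoforms against the reference annotation: novel
# gene and novel isoform calls, full-length evaluation, structure summaries.

#' Classify loci as known or novel genes
#'
#' A locus is a novel gene when no annotated gene on its chromosome overlaps
#' at least 20% of the locus span on the same strand: either the best overlap
#' is below 20% of the locus span (`no_overlap` / `overlap_lt_20`), or an
#' overlapping gene exists but only antisense (`strand_mismatch`). Otherwise
#' the locus is known, matched to the same-strand gene with the largest
#' overlap (ties broken by shared splice sites, then lexicographic gene id).
#' An exactly-20% overlap counts as known.
#'
#' @param loci tibble from [loci_table()].
#' @param annotation annotation tibble ([read_annotation()]).
#' @param isoforms optional isoform tibble (with `locus_id`), used only for
#'   the shared-splice-site tie break.
#' @param thresholds [iso_thresholds()].
#' @return `loci` with columns `gene_call` (`"known"`/`"novel"`), `gene_match`
#'   (`NA` for novel) and `gene_reason` added.
#' @export
classify_genes <- function(loci, annotation, isoforms = NULL,
                           thresholds = iso_thresholds()) {
  spans <- annotation_gene_spans(annotation)
  frac <- thresholds$min_locus_overlap_frac
  ann_sites <- annotation_site_sets(annotation)

  res <- map(seq_len(nrow(loci)), function(i) {
    lc <- loci[i, ]
    cand <- spans[spans$chrom == lc$chrom, ]
    if (nrow(cand) == 0) {
      return(tibble(gene_call = "novel", gene_match = NA_character_,
                    gene_reason = "no_overlap"))
    }
    ov <- overlap_len(lc$start, lc$end, cand$start, cand$end)
    ovf <- ov / (lc$end - lc$start)
    same <- cand$strand == lc$strand
    if (any(ovf >= frac & same)) {
      hit <- cand[ovf >= frac & same, ]
      hit_ovf <- ovf[ovf >= frac & same]
      top <- hit[hit_ovf == max(hit_ovf), , drop = FALSE]
      if (nrow(top) > 1 && !is.null(isoforms)) {
        locus_sites <- locus_splice_sites(isoforms, lc$locus_id)
        shared <- vapply(top$gene_id, function(g) {
          length(intersect(locus_sites, ann_sites[[g]] %||% numeric(0)))
        }, integer(1))
        top <- top[shared == max(shared), , drop = FALSE]
      }
      best <- sort(top$gene_id)[1]
      return(tibble(gene_call = "known", gene_match = best,
                    gene_reason = "chain_match"))
    }
    if (any(ovf >= frac)) {  # only antisense overlap reaches the threshold
      return(tibble(gene_call = "novel", gene_match = NA_character_,
                    gene_reason = "strand_mismatch"))
    }
    reason <- if (max(ovf) > 0) "overlap_lt_20" else "no_overlap"
    tibble(gene_call = "novel", gene_match = NA_character_,
           gene_reason = reason)
  }) |> bind_rows()
  bind_cols(loci, res)
}

# all donor+acceptor genomic coordinates of a gene's annotated transcripts
annotation_site_sets <- function(annotation) {
  out <- lapply(split(seq_len(nrow(annotation)), annotation$gene_id),
                function(ix) {
    unique(unlist(lapply(ix, function(i) {
      j <- blocks_to_junctions(annotation$exons[[i]])
      as.numeric(j)
    })))
  })
  out
}

locus_splice_sites <- function(isoforms, locus_id) {
  ix <- which(isoforms$locus_id == locus_id)
  unique(unlist(lapply(ix, function(i) as.numeric(isoforms$junctions[[i]]))))
}

#' Classify isoforms as known or novel
#'
#' For isoforms of known genes: a multi-exon isoform is known when an
#' annotated transcript of the matched gene carries the identical junction
#' chain, novel when it contains at least one splice site absent from the
#' gene's annotated splice-site set (`new_splice_site`); a multi-exon isoform
#' whose sites are all annotated but combined in a new order is called known
#' (the novelty rule is a splice-site rule). A single-exon isoform of a known
#' gene is known when at least half of it lies inside the gene's annotated
#' exonic regions, else novel (`single_exon_rule`). Every isoform of a novel
#' gene is novel.
#'
#' @param isoforms isoform tibble with `locus_id`.
#' @param loci classified loci ([classify_genes()]).
#' @param annotation annotation tibble.
#' @return `isoforms` with `novelty` (`known` / `novel_of_known_gene` /
#'   `novel_gene`), `novelty_reason`, and `gene_match` columns added.
#' @export
classify_isoforms <- function(isoforms, loci, annotation) {
  gene_info <- loci |> select("locus_id", "gene_call", "gene_match")
  iso <- isoforms |> left_join(gene_info, by = "locus_id")
  if (any(is.na(iso$gene_call))) {
    abort("every isoform locus_id must appear in the classified loci table")
  }
  ann_by_gene <- split(seq_len(nrow(annotation)), annotation$gene_id)
  ann_sites <- annotation_site_sets(annotation)
  ann_chains <- lapply(seq_len(nrow(annotation)), function(i) {
    chain_key(annotation$chrom[i], annotation$strand[i],
              blocks_to_junctions(annotation$exons[[i]]))
  })

  call_one <- function(i) {
    if (iso$gene_call[i] == "novel") {
      return(c("novel_gene", iso$gene_reason_locus[i] %||% "no_overlap"))
    }
    g <- iso$gene_match[i]
    tx <- ann_by_gene[[g]]
    if (iso$n_junctions[i] == 0) {
      ex_regions <- do.call(rbind, annotation$exons[tx])
      ov <- exonic_overlap(iso$start[i], iso$end[i], ex_regions)
      if (ov >= 0.5 * (iso$end[i] - iso$start[i])) {
        return(c("known", "single_exon_rule"))
      }
      return(c("novel_of_known_gene", "single_exon_rule"))
    }
    key <- chain_key(iso$chrom[i], iso$strand[i], iso$junctions[[i]])
    if (key %in% unlist(ann_chains[tx])) return(c("known", "chain_match"))
    sites <- as.numeric(iso$junctions[[i]])
    if (any(!(sites %in% (ann_sites[[g]] %||% numeric(0))))) {
      return(c("novel_of_known_gene", "new_splice_site"))
    }
    c("known", "chain_match")
  }
  # carry the locus-level reason for novel-gene isoforms
  iso$gene_reason_locus <- (loci$gene_reason)[match(iso$locus_id, loci$locus_id)]
  calls <- vapply(seq_len(nrow(iso)), call_one, character(2))
  iso |>
    mutate(novelty = calls[1, ], novelty_reason = calls[2, ]) |>
    select(-"gene_call", -"gene_reason_locus")
}

# overlap of [s,e) with the union of exon intervals
exonic_overlap <- function(s, e, exons) {
  if (is.null(exons) || nrow(exons) == 0) return(0)
  m <- exons[order(exons[, 1]), , drop = FALSE]
  tot <- 0; cur_s <- m[1, 1]; cur_e <- m[1, 2]
  if (nrow(m) > 1) {
    for (i in 2:nrow(m)) {
      if (m[i, 1] <= cur_e) cur_e <- max(cur_e, m[i, 2])
      else { tot <- tot + overlap_len(s, e, cur_s, cur_e); cur_s <- m[i, 1]; cur_e <- m[i, 2] }
    }
  }
  tot + overlap_len(s, e, cur_s, cur_e)
}

#' Evaluate full-length status of multi-exon isoforms
#'
#' A multi-exon, gene-matched isoform counts as full-length when its 5'-most
#' splice donor coincides with the 5'-most donor of at least one annotated
#' transcript of the matched gene. Single-exon or novel-gene isoforms are
#' inapplicable (`NA`).
#'
#' @param isoforms classified isoforms ([classify_isoforms()]).
#' @param annotation annotation tibble.
#' @return `isoforms` with logical `full_length` column added.
#' @export
evaluate_full_length <- function(isoforms, annotation) {
  ann_by_gene <- split(seq_len(nrow(annotation)), annotation$gene_id)
  first_donor <- function(junctions, strand) {
    if (nrow(junctions) == 0) return(NA_real_)
    if (strand == "+") junctions[1, 1] else junctions[nrow(junctions), 2]
  }
  ann_first_donors <- lapply(ann_by_gene, function(ix) {
    vapply(ix, function(i) {
      first_donor(blocks_to_junctions(annotation$exons[[i]]),
                  annotation$strand[i])
    }, numeric(1))
  })
  fl <- vapply(seq_len(nrow(isoforms)), function(i) {
    if (isoforms$n_junctions[i] == 0 || is.na(isoforms$gene_match[i])) {
      return(NA)
    }
    fd <- first_donor(isoforms$junctions[[i]], isoforms$strand[i])
    fd %in% ann_first_donors[[isoforms$gene_match[i]]]
  }, logical(1))
  mutate(isoforms, full_length = fl)
}

#' Summarise locus structure
#'
#' Bins locus span lengths (<1 kb, 1-2 kb, 2-3 kb, >=3 kb) for both the
#' reference annotation and the recovered loci, and tabulates isoforms per
#' locus, mirroring the standard gene-structure report.
#'
#' @param loci loci tibble.
#' @param annotation annotation tibble.
#' @return list with tibbles `length_bins` (feature, annotation/pipeline
#'   counts and formatted percentages) and `isoforms_per_locus`.
#' @export
summarize_structure <- function(loci, annotation) {
  bin_lengths <- function(len) {
    cut(len, breaks = c(-Inf, 1000, 2000, 3000, Inf), right = FALSE,
        labels = c("Loci < 1 K", "Loci 1-2 K", "Loci 2-3 K", "Loci >= 3 K"))
  }
  ann_spans <- annotation_gene_spans(annotation)
  ann_bins <- table(bin_lengths(ann_spans$end - ann_spans$start))
  pb_bins <- table(bin_lengths(loci$end - loci$start))
  length_bins <- tibble(
    feature = names(ann_bins),
    annotation_n = as.integer(ann_bins),
    annotation_pct = fmt_pct(as.integer(ann_bins), nrow(ann_spans)),
    pipeline_n = as.integer(pb_bins),
    pipeline_pct = fmt_pct(as.integer(pb_bins), nrow(loci))
  )
  ipl <- loci |> count(.data$n_isoforms, name = "n_loci")
  list(length_bins = length_bins, isoforms_per_locus = ipl,
       totals = tibble(annotation_loci = nrow(ann_spans),
                       pipeline_loci = nrow(loci)))
}
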