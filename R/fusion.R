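# Fusion (chimeric) transcript detection from split FLNC alignments, using
# the four-criterion rule: >=2 annotated genes >=10 kb apart (or on different
# chromosomes), each segment covering >10% of the read, total coverage >99%,
# and paired-end short-read support across the fusion junction.

#' Detect fusion transcript candidates
#'
#' Takes alignment records grouped by read (a chimeric read appears as a
#' primary plus supplementary record per segment), assigns each segment to an
#' annotated gene by largest same-strand exonic overlap, and keeps a read as
#' a fusion candidate when all four criteria hold:
#' 1. segments hit two or more distinct genes at least
#'    `fusion_min_gene_distance` apart (closest annotated boundaries) or on
#'    different chromosomes;
#' 2. every segment covers strictly more than `fusion_min_gene_cov_frac` of
#'    the read length;
#' 3. the summed coverage strictly exceeds `fusion_min_total_cov`;
#' 4. at least `fusion_min_pe_support` paired-end read pairs span the fusion
#'    junction.
#'
#' @param alignments tibble from [read_alignments()]; all records of split
#'   reads are used (secondary records are ignored).
#' @param annotation annotation tibble ([read_annotation()]).
#' @param pe_junction_support optional tibble `gene_a`, `gene_b`, `n_pairs`
#'   of short-read pairs spanning each candidate junction (unordered pairs);
#'   missing pairs count 0.
#' @param thresholds [iso_thresholds()].
#' @return tibble of candidates: `read_id`, `gene_a`, `gene_b` (alphabetical),
#'   `genes` (list of all genes hit), `n_genes`, `cov_fracs` (list),
#'   `total_cov`, `pe_support`, `category`
#'   (`inter_chromosome`/`intra_chromosome`), `multi_gene` flag. Rejected
#'   split reads and their failing criterion are in `attr(, "rejected")`.
#' @export
detect_fusions <- function(alignments, annotation, pe_junction_support = NULL,
                           thresholds = iso_thresholds()) {
  spans <- annotation_gene_spans(annotation)
  split_ids <- unique(alignments$read_id[alignments$supplementary])
  aln <- alignments |>
    filter(.data$read_id %in% split_ids, .data$mapped, !.data$secondary)

  pe_lookup <- function(ga, gb) {
    if (is.null(pe_junction_support) || nrow(pe_junction_support) == 0) {
      return(0L)
    }
    a <- pmin(ga, gb); b <- pmax(ga, gb)
    hit <- pe_junction_support$n_pairs[
      pmin(pe_junction_support$gene_a, pe_junction_support$gene_b) == a &
      pmax(pe_junction_support$gene_a, pe_junction_support$gene_b) == b]
    if (length(hit) == 0) 0L else as.integer(sum(hit))
  }

  out <- list(); rej <- list()
  for (rid in unique(aln$read_id)) {
    segs <- aln[aln$read_id == rid, ]
    read_len <- max(segs$read_length, na.rm = TRUE)
    # gene per segment: largest same-strand exonic overlap
    seg_gene <- vapply(seq_len(nrow(segs)), function(k) {
      cand <- spans[spans$chrom == segs$chrom[k] &
                      spans$strand == segs$strand[k], ]
      if (nrow(cand) == 0) return(NA_character_)
      ov <- overlap_len(segs$span_start[k], segs$span_end[k],
                        cand$start, cand$end)
      if (max(ov) == 0) return(NA_character_)
      sort(cand$gene_id[ov == max(ov)])[1]
    }, character(1))
    if (all(is.na(seg_gene))) next  # silently skipped per contract
    known <- !is.na(seg_gene)
    genes <- unique(seg_gene[known])
    cov <- segs$aligned_read_span
    reason <- NULL
    if (length(genes) < 2) {
      reason <- "single_gene"
    } else {
      gs <- spans[match(genes, spans$gene_id), ]
      far <- FALSE
      for (a in seq_along(genes)[-length(genes)]) {
        for (b in seq(a + 1, length(genes))) {
          if (gs$chrom[a] != gs$chrom[b]) { far <- TRUE; next }
          d <- max(gs$start[a], gs$start[b]) - min(gs$end[a], gs$end[b])
          if (d >= thresholds$fusion_min_gene_distance) far <- TRUE
        }
      }
      if (!far) reason <- "genes_too_close"
      else if (!all(cov > thresholds$fusion_min_gene_cov_frac)) {
        reason <- "segment_coverage"
      } else if (!(sum(cov) > thresholds$fusion_min_total_cov)) {
        reason <- "total_coverage"
      } else {
        pe <- if (length(genes) == 2) pe_lookup(genes[1], genes[2]) else
          min(vapply(utils::combn(genes, 2, simplify = FALSE),
                     function(p) pe_lookup(p[1], p[2]), integer(1)))
        if (pe < thresholds$fusion_min_pe_support) reason <- "pe_support"
      }
    }
    if (!is.null(reason)) {
      rej[[length(rej) + 1]] <- tibble(read_id = rid, reason = reason)
      next
    }
    chroms <- unique(segs$chrom)
    g2 <- sort(genes)[1:2]
    n_genes <- length(genes)
    out[[length(out) + 1]] <- tibble(
      read_id = rid,
      gene_a = g2[1], gene_b = g2[2],
      genes = list(sort(genes)), n_genes = n_genes,
      cov_fracs = list(cov), total_cov = sum(cov),
      pe_support = pe_lookup(g2[1], g2[2]),
      category = if (length(chroms) > 1) "inter_chromosome" else
        "intra_chromosome",
      multi_gene = n_genes > 2)
  }
  res <- if (length(out)) bind_rows(out) |> arrange(.data$read_id) else
    tibble(read_id = character(), gene_a = character(), gene_b = character(),
           genes = list(), n_genes = integer(), cov_fracs = list(),
           total_cov = numeric(), pe_support = integer(),
           category = character(), multi_gene = logical())
  attr(res, "rejected") <- if (length(rej)) bind_rows(rej) else
    tibble(read_id = character(), reason = character())
  res
}

#' Summarise fusion candidates
#'
#' @param candidates tibble from [detect_fusions()].
#' @return list with `counts` (total / inter / intra), `genes_per_fusion`
#'   distribution, and `links` (gene-pair table with chromosomes, for
#'   circos-style plotting).
#' @export
fusion_summary <- function(candidates) {
  counts <- tibble(
    total = nrow(candidates),
    inter_chromosome = sum(candidates$category == "inter_chromosome"),
    intra_chromosome = sum(candidates$category == "intra_chromosome"))
  gpf <- candidates |> count(.data$n_genes, name = "n_fusions")
  links <- candidates |>
    count(.data$gene_a, .data$gene_b, .data$category, name = "n_reads")
  list(counts = counts, genes_per_fusion = gpf, links = links)
}
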