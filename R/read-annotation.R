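#' Read a GFF3 gene annotation into transcript models
#'
#' Parses a GFF3 file (gene / mRNA / exon, optionally CDS) into one row per
#' transcript. Exon and CDS intervals are converted from GFF3's 1-based closed
#' convention to the package-internal 0-based half-open convention on the
#' forward strand; strand is carried as metadata.
#'
#' @param path GFF3 file.
#' @return A tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `n_exons`, `exons` (list column of two-column
#'   `start`/`end` matrices, sorted, non-overlapping) and `cds` (list column,
#'   `NULL` when the transcript has no CDS rows).
#' @export
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3",
#'   "chr1\tsrc\tgene\t101\t600\t.\t+\t.\tID=g1",
#'   "chr1\tsrc\tmRNA\t101\t600\t.\t+\t.\tID=t1;Parent=g1",
#'   "chr1\tsrc\texon\t101\t200\t.\t+\t.\tParent=t1",
#'   "chr1\tsrc\texon\t301\t400\t.\t+\t.\tParent=t1"), gff)
#' read_annotation(gff)
read_annotation <- function(path) {
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(body) == 0) {
    warn("annotation file contains no features; returning empty model set")
    return(empty_annotation())
  }
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- tolower(as.character(gr$type))
  ids <- as.character(gr$ID %||% rep(NA_character_, length(gr)))
  parents <- gr$Parent
  first_parent <- function(i) {
    p <- parents[[i]]
    if (length(p) == 0) NA_character_ else as.character(p[[1]])
  }

  tx_idx <- which(typ %in% c("mrna", "transcript"))
  exon_idx <- which(typ == "exon")
  cds_idx <- which(typ == "cds")
  if (length(tx_idx) == 0) {
    warn("annotation file contains no mRNA/transcript features")
    return(empty_annotation())
  }

  tx_id <- ids[tx_idx]
  tx_gene <- vapply(tx_idx, first_parent, character(1))
  tx_gene[is.na(tx_gene)] <- tx_id[is.na(tx_gene)]  # orphan transcript = own gene

  gather_children <- function(idx, what) {
    if (length(idx) == 0) {
      return(setNames(vector("list", length(tx_id)), tx_id))
    }
    par <- vapply(idx, first_parent, character(1))
    bad <- which(is.na(par) | !(par %in% tx_id))
    if (length(bad) > 0) {
      i <- idx[bad[1]]
      abort(sprintf(
        "malformed GFF3: %s at %s:%d-%d has Parent '%s' which is not a transcript",
        what, as.character(GenomicRanges::seqnames(gr))[i],
        GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i],
        if (is.na(par[bad[1]])) "<missing>" else par[bad[1]]))
    }
    split(idx, factor(par, levels = tx_id))
  }
  exons_by_tx <- gather_children(exon_idx, "exon")
  cds_by_tx <- gather_children(cds_idx, "CDS")

  starts <- GenomicRanges::start(gr)
  ends <- GenomicRanges::end(gr)
  block_mat <- function(idx) {
    if (is.null(idx) || length(idx) == 0) return(NULL)
    m <- gff_to_internal(starts[idx], ends[idx])
    m <- m[order(m[, 1]), , drop = FALSE]
    if (nrow(m) > 1 && any(m[-1, 1] < m[-nrow(m), 2])) {
      abort("malformed GFF3: overlapping exon intervals within one transcript")
    }
    m
  }

  chrom <- as.character(GenomicRanges::seqnames(gr))[tx_idx]
  strand <- as.character(GenomicRanges::strand(gr))[tx_idx]
  if (any(!strand %in% c("+", "-"))) {
    abort("malformed GFF3: transcript strand must be '+' or '-'")
  }
  exons <- lapply(tx_id, function(t) block_mat(exons_by_tx[[t]]))
  no_ex <- vapply(exons, is.null, logical(1))
  if (any(no_ex)) {
    # transcripts without exon rows: use their own span as a single exon
    exons[no_ex] <- lapply(which(no_ex), function(k) {
      gff_to_internal(starts[tx_idx[k]], ends[tx_idx[k]])
    })
  }
  tibble(
    transcript_id = tx_id,
    gene_id = tx_gene,
    chrom = chrom,
    strand = strand,
    n_exons = vapply(exons, nrow, integer(1)),
    exons = exons,
    cds = lapply(tx_id, function(t) block_mat(cds_by_tx[[t]]))
  )
}

empty_annotation <- function() {
  tibble(transcript_id = character(), gene_id = character(),
         chrom = character(), strand = character(), n_exons = integer(),
         exons = list(), cds = list())
}

#' Write transcript models to GFF3
#'
#' Inverse of [read_annotation()]: emits gene, mRNA and exon (and CDS) rows in
#' 1-based closed coordinates. `read_annotation(write_annotation(x, f))`
#' reproduces `x`.
#'
#' @param annotation tibble as returned by [read_annotation()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  rows <- character(0)
  for (g in unique(annotation$gene_id)) {
    sub <- annotation[annotation$gene_id == g, ]
    g_start <- min(vapply(sub$exons, function(e) min(e[, 1]), numeric(1)))
    g_end <- max(vapply(sub$exons, function(e) max(e[, 2]), numeric(1)))
    rows <- c(rows, sprintf("%s\tisocraft\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                            sub$chrom[1], g_start + 1, g_end, sub$strand[1], g))
    for (i in seq_len(nrow(sub))) {
      ex <- sub$exons[[i]]
      rows <- c(rows, sprintf("%s\tisocraft\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                              sub$chrom[i], min(ex[, 1]) + 1, max(ex[, 2]),
                              sub$strand[i], sub$transcript_id[i], g))
      rows <- c(rows, sprintf("%s\tisocraft\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                              sub$chrom[i], ex[, 1] + 1, ex[, 2], sub$strand[i],
                              sub$transcript_id[i]))
      cd <- sub$cds[[i]]
      if (!is.null(cd)) {
        rows <- c(rows, sprintf("%s\tisocraft\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                                sub$chrom[i], cd[, 1] + 1, cd[, 2], sub$strand[i],
                                sub$transcript_id[i]))
      }
    }
  }
  writeLines(rows, con)
  invisible(path)
}

# per-gene span table: gene_id, chrom, strand, start, end
annotation_gene_spans <- function(annotation) {
  annotation |>
    mutate(g_start = vapply(.data$exons, function(e) min(e[, 1]), numeric(1)),
           g_end = vapply(.data$exons, function(e) max(e[, 2]), numeric(1))) |>
    group_by(.data$gene_id) |>
    summarise(chrom = first(.data$chrom), strand = first(.data$strand),
              start = min(.data$g_start), end = max(.data$g_end),
              .groups = "drop")
}

# set of annotated junction keys "chrom|strand|start-end"
annotation_junction_keys <- function(annotation) {
  keys <- unlist(lapply(seq_len(nrow(annotation)), function(i) {
    j <- blocks_to_junctions(annotation$exons[[i]])
    if (nrow(j) == 0) return(character(0))
    paste(annotation$chrom[i], annotation$strand[i],
          paste0(j[, 1], "-", j[, 2]), sep = "|")
  }))
  unique(keys)
}
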