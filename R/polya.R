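# Poly(A) cleavage-site detection from FLNC 3' ends, APA gene calls, and the
# +/-30 nt nucleotide-composition profile around cleavage sites.

#' Detect poly(A) cleavage sites from read 3' ends
#'
#' Read 3' ends within one gene (or locus) are sorted along the strand and
#' clustered by single linkage: a gap larger than `polya_cluster_window`
#' (default 24 nt) opens a new cluster. Each cluster's site position is the
#' modal 3' end, ties resolved to the most downstream coordinate (larger on
#' `+`, smaller on `-`). Clusters supported by fewer than
#' `polya_min_site_support` reads are dropped.
#'
#' @param read_ends tibble with one row per read: `gene_id` (or locus id),
#'   `chrom`, `strand`, `end3` (genomic 3'-end coordinate of the read).
#' @param thresholds [iso_thresholds()].
#' @return tibble of sites: `gene_id`, `chrom`, `strand`, `position`,
#'   `n_support`.
#' @export
detect_polya_sites <- function(read_ends, thresholds = iso_thresholds()) {
  win <- thresholds$polya_cluster_window
  min_sup <- thresholds$polya_min_site_support
  if (nrow(read_ends) == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  strand = character(), position = numeric(),
                  n_support = integer()))
  }
  read_ends |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    summarise(sites = list(cluster_ends(.data$end3, .data$strand[1], win)),
              .groups = "drop") |>
    unnest("sites") |>
    filter(.data$n_support >= min_sup) |>
    arrange(.data$gene_id, .data$position)
}

cluster_ends <- function(ends, strand, win) {
  ends <- sort(ends)
  brk <- which(diff(ends) > win)
  cl <- rep(seq_len(length(brk) + 1), diff(c(0, brk, length(ends))))
  out <- lapply(split(ends, cl), function(e) {
    tab <- table(e)
    modal <- as.numeric(names(tab)[tab == max(tab)])
    pos <- if (strand == "+") max(modal) else min(modal)
    tibble(position = pos, n_support = length(e))
  })
  bind_rows(out)
}

#' Call genes with alternative polyadenylation
#'
#' A gene is an APA gene when it carries two or more detected cleavage
#' sites.
#'
#' @param sites tibble from [detect_polya_sites()].
#' @return list with `genes` (per gene: `n_sites`, `apa` flag) and
#'   `histogram` (genes by site count).
#' @export
call_apa_genes <- function(sites) {
  genes <- sites |>
    count(.data$gene_id, name = "n_sites") |>
    mutate(apa = .data$n_sites >= 2)
  histogram <- genes |> count(.data$n_sites, name = "n_genes")
  list(genes = genes, histogram = histogram,
       summary = tibble(n_sites = nrow(sites),
                        n_genes = nrow(genes),
                        n_apa_genes = sum(genes$apa)))
}

#' Nucleotide composition around poly(A) cleavage sites
#'
#' For every site, extracts the genomic sequence from `flank` nt upstream to
#' `flank` nt downstream of the cleavage position in transcript orientation
#' (reverse-complemented on `-`), then averages base composition per
#' position. Position 0 is the last transcribed base; negative positions are
#' transcribed (upstream), positive are genomic downstream. T is reported as
#' U. Sites closer than `flank` to a chromosome edge contribute `N` padding,
#' excluded from the affected columns' denominators.
#'
#' @param sites tibble from [detect_polya_sites()].
#' @param genome named [Biostrings::DNAStringSet] (or named character vector)
#'   of chromosome sequences.
#' @param thresholds [iso_thresholds()].
#' @return matrix of base fractions, rows `A`,`C`,`G`,`U`, columns positions
#'   `-flank` .. `+flank`; every fully-covered column sums to 1.
#' @export
polya_profile <- function(sites, genome, thresholds = iso_thresholds()) {
  flank <- thresholds$polya_flank
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  width <- 2L * flank + 1L
  counts <- matrix(0L, nrow = 5, ncol = width,
                   dimnames = list(c("A", "C", "G", "T", "N"), NULL))
  for (i in seq_len(nrow(sites))) {
    chrom <- sites$chrom[i]
    len <- Biostrings::width(genome[chrom])
    # cleavage coordinate: 0-based position of the last transcribed base
    p <- if (sites$strand[i] == "+") sites$position[i] - 1 else sites$position[i]
    lo <- p - flank; hi <- p + flank
    s_lo <- max(lo, 0); s_hi <- min(hi, len - 1)
    seq <- as.character(Biostrings::subseq(genome[[chrom]], s_lo + 1, s_hi + 1))
    seq <- paste0(strrep("N", s_lo - lo), seq, strrep("N", hi - s_hi))
    if (sites$strand[i] == "-") {
      seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    }
    bases <- strsplit(seq, "")[[1]]
    bases[!bases %in% c("A", "C", "G", "T")] <- "N"
    ix <- cbind(match(bases, rownames(counts)), seq_len(width))
    counts[ix] <- counts[ix] + 1L
  }
  denom <- matrix(rep(colSums(counts[1:4, , drop = FALSE]), each = 4),
                  nrow = 4)
  frac <- counts[1:4, , drop = FALSE] / ifelse(denom == 0, NA, denom)
  rownames(frac) <- c("A", "C", "G", "U")
  colnames(frac) <- as.character(seq(-flank, flank))
  class(frac) <- c("polya_profile", class(frac))
  frac
}
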