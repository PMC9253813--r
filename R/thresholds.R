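#' Pipeline thresholds
#'
#' Bundle of every numeric cutoff the pipeline uses, with the defaults the
#' method prescribes. All stage functions accept a `thresholds` argument so a
#' single object configures a whole run.
#'
#' @param min_locus_overlap_frac Two same-strand isoforms whose spans overlap
#'   by at least this fraction of the shorter span belong to one locus
#'   (inclusive bound).
#' @param min_support_reads An isoform is retained when backed by at least
#'   this many FLNC reads (inclusive).
#' @param min_single_read_identity A singleton isoform is retained when its
#'   best supporting read identity exceeds this (strict).
#' @param min_lncrna_len Minimum transcript length (nt) for a lncRNA candidate.
#' @param min_orf_aa Minimum ORF length in amino acids (inclusive).
#' @param fusion_min_gene_distance Minimum genomic distance (bp) between the
#'   two genes of an intra-chromosomal fusion.
#' @param fusion_min_gene_cov_frac Each fusion segment must cover more than
#'   this fraction of the read (strict).
#' @param fusion_min_total_cov Segments together must cover more than this
#'   fraction of the read (strict).
#' @param fusion_min_pe_support Minimum paired-end read pairs spanning the
#'   fusion junction (inclusive).
#' @param deg_fdr BH-adjusted q-value cutoff for differential expression.
#' @param deg_min_abs_logfc Minimum |log2 fold change| for a DEG call (strict).
#' @param specific_min_logfc Restorer-specific screen: log2 fold change R vs A
#'   and R vs B must both exceed this (strict).
#' @param specific_min_fpkm Restorer-specific screen: FPKM above this in every
#'   R replicate, below it in every A and B replicate (strict both ways).
#' @param polya_flank Half-width (nt) of the nucleotide profile window around
#'   poly(A) cleavage sites.
#' @param polya_cluster_window Single-linkage gap (nt) when clustering read 3'
#'   ends into cleavage sites.
#' @param polya_min_site_support Minimum read 3' ends per reported cleavage
#'   site (inclusive).
#' @param junction_tolerance Maximum donor/acceptor coordinate difference (nt)
#'   for two junctions to be considered identical during collapse; 0 demands
#'   exact equality.
#' @param min_sj_cov Minimum short-read count for a junction to count as
#'   Illumina-supported.
#' @param single_exon_overlap_frac Reciprocal span-overlap fraction collapsing
#'   two single-exon reads into one isoform (inclusive).
#' @param pid_floor Reads with best alignment identity below this are classed
#'   "low pid" in the mapping summary.
#' @param fickett_coding Fickett TESTCODE value above which a sequence votes
#'   coding.
#' @param fickett_noncoding Fickett TESTCODE value below which a sequence
#'   votes noncoding.
#'
#' @return A named list of class `iso_thresholds`.
#' @export
#' @examples
#' th <- iso_thresholds(junction_tolerance = 5)
#' th$min_support_reads
iso_thresholds <- function(min_locus_overlap_frac = 0.20,
                           min_support_reads = 2L,
                           min_single_read_identity = 0.99,
                           min_lncrna_len = 200L,
                           min_orf_aa = 100L,
                           fusion_min_gene_distance = 10000L,
                           fusion_min_gene_cov_frac = 0.10,
                           fusion_min_total_cov = 0.99,
                           fusion_min_pe_support = 2L,
                           deg_fdr = 0.05,
                           deg_min_abs_logfc = 1,
                           specific_min_logfc = 3,
                           specific_min_fpkm = 1,
                           polya_flank = 30L,
                           polya_cluster_window = 24L,
                           polya_min_site_support = 2L,
                           junction_tolerance = 0L,
                           min_sj_cov = 1L,
                           single_exon_overlap_frac = 0.50,
                           pid_floor = 0.90,
                           fickett_coding = 1.10,
                           fickett_noncoding = 0.95) {
  th <- as.list(environment())
  fracs <- c("min_locus_overlap_frac", "min_single_read_identity",
             "fusion_min_gene_cov_frac", "fusion_min_total_cov", "deg_fdr",
             "single_exon_overlap_frac", "pid_floor")
  for (f in fracs) {
    if (th[[f]] < 0 || th[[f]] > 1) {
      abort(sprintf("threshold `%s` must lie in [0, 1], got %s", f, th[[f]]))
    }
  }
  pos <- c("min_support_reads", "min_lncrna_len", "min_orf_aa",
           "fusion_min_gene_distance", "polya_flank", "polya_cluster_window",
           "polya_min_site_support")
  for (f in pos) {
    if (th[[f]] <= 0) abort(sprintf("threshold `%s` must be positive", f))
  }
  if (th$junction_tolerance < 0) abort("`junction_tolerance` must be >= 0")
  structure(th, class = c("iso_thresholds", "list"))
}

#' @export
print.iso_thresholds <- function(x, ...) {
  cat("<iso_thresholds>\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
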