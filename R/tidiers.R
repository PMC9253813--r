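# broom-style accessors for fitted/result objects.

#' Tidy a differential-expression screen
#'
#' @param x `iso_screen` from [deg_screen()].
#' @param ... unused.
#' @return tibble with one row per tested feature.
#' @export
#' @exportS3Method generics::tidy
tidy.iso_screen <- function(x, ...) {
  as_tibble(x) |>
    rename(estimate = "log2fc", p.value = "pvalue", q.value = "qvalue")
}

#' One-row summary of a differential-expression screen
#'
#' @param x `iso_screen` from [deg_screen()].
#' @param ... unused.
#' @return tibble: features tested, DEG counts, excluded features.
#' @export
#' @exportS3Method generics::glance
glance.iso_screen <- function(x, ...) {
  tibble(n_features = nrow(x),
         n_deg_up = sum(x$deg_up),
         n_deg_down = sum(x$deg_down),
         n_excluded = length(attr(x, "excluded") %||% character(0)))
}

#' Tidy a pipeline run
#'
#' @param x `iso_pipeline` from [run_pipeline()].
#' @param ... unused.
#' @return the classified isoform table (one row per isoform).
#' @export
#' @exportS3Method generics::tidy
tidy.iso_pipeline <- function(x, ...) {
  isoform_tsv(x$isoforms)
}

#' One-row summary of a pipeline run
#'
#' @param x `iso_pipeline` from [run_pipeline()].
#' @param ... unused.
#' @return tibble of headline counts: reads, isoforms, loci, novelty split,
#'   AS events, poly(A)/APA, fusions, lncRNA candidates.
#' @export
#' @exportS3Method generics::glance
glance.iso_pipeline <- function(x, ...) {
  tibble(
    n_reads = nrow(x$mapping$reads),
    n_isoforms = nrow(x$isoforms),
    n_loci = nrow(x$loci),
    n_known_isoforms = sum(x$isoforms$novelty == "known"),
    n_novel_isoforms = sum(x$isoforms$novelty != "known"),
    n_novel_loci = sum(x$loci$gene_call == "novel"),
    n_as_events = nrow(x$as$events),
    n_polya_sites = nrow(x$polya$sites),
    n_apa_genes = sum(x$polya$apa$genes$apa),
    n_fusions = nrow(x$fusions),
    n_lncrna = if (is.null(x$lncrna$calls) || nrow(x$lncrna$calls) == 0) 0L
      else sum(x$lncrna$calls$lncrna))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
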