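# End-to-end orchestration: mapping classification, collapse -> classify ->
# AS -> APA -> fusion -> lncRNA -> expression, plus the report writers.

#' Classify reads by mapping outcome
#'
#' Mirrors the standard reference-comparison table: each read falls in
#' exactly one class. `unmapped` - no mapped record; `multiple_best` - two or
#' more (primary or secondary) alignments tie on the best identity;
#' `low_pid` - best identity below `pid_floor`; else `high_quality`.
#' Supplementary records (split-read segments) are not counted as competing
#' alignments.
#'
#' @param alignments tibble from [read_alignments()].
#' @param thresholds [iso_thresholds()].
#' @return list with `reads` (read_id, class) and `summary` (class, n, pct).
#' @export
classify_mapping <- function(alignments, thresholds = iso_thresholds()) {
  aln <- alignments |> filter(!.data$supplementary)
  per_read <- aln |>
    group_by(.data$read_id) |>
    summarise(
      n_mapped = sum(.data$mapped),
      best = if (any(.data$mapped)) {
        suppressWarnings(max(.data$identity[.data$mapped], na.rm = TRUE))
      } else NA_real_,
      n_best = if (any(.data$mapped)) {
        sum(.data$mapped & !is.na(.data$identity) &
              .data$identity >= suppressWarnings(
                max(.data$identity[.data$mapped], na.rm = TRUE)) - 1e-9)
      } else 0L,
      .groups = "drop")
  cls <- with(per_read, ifelse(
    n_mapped == 0, "unmapped",
    ifelse(n_best >= 2, "multiple_best",
           ifelse(is.finite(best) & best < thresholds$pid_floor,
                  "low_pid", "high_quality"))))
  reads <- tibble(read_id = per_read$read_id, class = cls)
  lev <- c("unmapped", "multiple_best", "low_pid", "high_quality")
  summary <- tibble(class = lev,
                    n = vapply(lev, function(l) sum(cls == l), integer(1))) |>
    mutate(pct = fmt_pct(.data$n, nrow(reads)))
  list(reads = reads, summary = summary)
}

#' Run the full characterization pipeline
#'
#' Stages in order: read inputs, mapping classification, isoform collapse
#' (split/chimeric reads excluded and routed to fusion detection), 5'
#' degradation pruning, support filtering, locus assignment, novel gene /
#' novel isoform classification, full-length evaluation, AS event
#' enumeration, poly(A) site detection and APA calls, nucleotide profile,
#' fusion detection, lncRNA screening of novel isoforms, and (when counts
#' are supplied) the differential and restorer-specific expression screens.
#' The run is deterministic: identical inputs and thresholds give identical
#' results.
#'
#' @param genome path to a FASTA file or a named `DNAStringSet`.
#' @param annotation path to GFF3 or an annotation tibble.
#' @param alignments path to SAM/BAM or an alignment tibble.
#' @param counts optional path to a counts TSV (columns `transcript_id`,
#'   `length`, then sample columns `A1..A3, B1..B3, R1..R3`) or an
#'   equivalent tibble.
#' @param pe_support optional paired-end fusion-junction support (path or
#'   tibble: `gene_a`, `gene_b`, `n_pairs`).
#' @param illumina_junctions optional short-read junction tibble for the
#'   support filter.
#' @param homology_flags optional named logical vector of protein-homology
#'   hits for novel isoforms.
#' @param thresholds [iso_thresholds()].
#' @param outdir optional directory; when given, all report tables are
#'   written there via [write_report_tables()].
#' @return list of class `iso_pipeline` with elements `mapping`, `reads`
#'   (per-read chain info incl. full-length flags), `isoforms`, `loci`,
#'   `structure`, `as`, `polya`, `fusions`, `lncrna`, `screen`,
#'   `thresholds`.
#' @export
run_pipeline <- function(genome, annotation, alignments, counts = NULL,
                         pe_support = NULL, illumina_junctions = NULL,
                         homology_flags = NULL,
                         thresholds = iso_thresholds(), outdir = NULL) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  if (is.character(alignments)) alignments <- read_alignments(alignments)
  if (is.character(counts)) {
    counts <- readr::read_tsv(counts, show_col_types = FALSE)
  }
  if (is.character(pe_support)) {
    pe_support <- readr::read_tsv(pe_support, show_col_types = FALSE)
  }

  mapping <- classify_mapping(alignments, thresholds)

  # chimeric (split) reads never feed isoform building
  split_ids <- unique(alignments$read_id[alignments$supplementary])
  collapse_input <- alignments |> filter(!(.data$read_id %in% split_ids))

  isoforms <- collapse_isoforms(collapse_input, thresholds) |>
    prune_5prime_degraded() |>
    filter_supported(illumina_junctions, annotation, thresholds) |>
    assign_loci(thresholds)
  discarded <- attr(isoforms, "discarded")

  loci <- loci_table(isoforms) |>
    classify_genes(annotation, isoforms, thresholds)
  isoforms <- classify_isoforms(isoforms, loci, annotation) |>
    evaluate_full_length(annotation)

  reads <- read_level_table(collapse_input, isoforms, annotation)
  structure_summary <- summarize_structure(loci, annotation)
  as_res <- enumerate_as_events(isoforms)

  polya_in <- reads |>
    filter(!is.na(.data$gene_or_locus)) |>
    select(gene_id = "gene_or_locus", "chrom", "strand", "end3")
  sites <- detect_polya_sites(polya_in, thresholds)
  apa <- call_apa_genes(sites)
  profile <- if (nrow(sites) > 0) {
    polya_profile(sites, genome, thresholds)
  } else NULL

  fusions <- detect_fusions(alignments, annotation, pe_support, thresholds)

  lncrna <- lncrna_stage(isoforms, annotation, genome, homology_flags,
                         thresholds)

  screen <- NULL
  if (!is.null(counts)) screen <- expression_stage(counts, thresholds)

  res <- structure(list(
    mapping = mapping, reads = reads, isoforms = isoforms, loci = loci,
    discarded = discarded, structure = structure_summary, as = as_res,
    polya = list(sites = sites, apa = apa, profile = profile),
    fusions = fusions, lncrna = lncrna, screen = screen,
    thresholds = thresholds), class = "iso_pipeline")
  if (!is.null(outdir)) write_report_tables(res, outdir)
  res
}

# per-read chain info, gene assignment via the absorbing isoform, and
# read-level full-length status (5'-most donor matches an annotated
# transcript's first donor of the read's gene)
read_level_table <- function(collapse_input, isoforms, annotation) {
  aln <- collapse_input |>
    filter(.data$mapped, !.data$secondary, !.data$supplementary)
  if (nrow(aln) == 0) {
    return(tibble(read_id = character(), chrom = character(),
                  strand = character(), n_junctions = integer(),
                  end3 = numeric(), first_donor = numeric(),
                  isoform_id = character(), gene_or_locus = character(),
                  full_length = logical()))
  }
  chains <- map2(aln$blocks, aln$strand, build_splice_chain)
  aln <- aln |>
    mutate(n_junctions = vapply(chains, function(c) nrow(c$junctions),
                                integer(1)),
           end3 = vapply(chains, function(c) c$tes, numeric(1)),
           first_donor = vapply(seq_along(chains), function(i) {
             j <- chains[[i]]$junctions
             if (nrow(j) == 0) return(NA_real_)
             if (aln$strand[i] == "+") j[1, 1] else j[nrow(j), 2]
           }, numeric(1)))
  iso_map <- isoforms |>
    mutate(gene_or_locus = if_else(is.na(.data$gene_match),
                                   .data$locus_id, .data$gene_match)) |>
    select("isoform_id", "gene_or_locus", "gene_match",
           read_id = "support_reads") |>
    unnest("read_id")
  ann_first_donors <- lapply(split(seq_len(nrow(annotation)),
                                   annotation$gene_id), function(ix) {
    vapply(ix, function(i) {
      j <- blocks_to_junctions(annotation$exons[[i]])
      if (nrow(j) == 0) return(NA_real_)
      if (annotation$strand[i] == "+") j[1, 1] else j[nrow(j), 2]
    }, numeric(1))
  })
  out <- aln |>
    select("read_id", "chrom", "strand", "n_junctions", "end3",
           "first_donor") |>
    left_join(iso_map, by = "read_id")
  out$full_length <- vapply(seq_len(nrow(out)), function(i) {
    if (out$n_junctions[i] == 0) return(NA)
    g <- out$gene_match[i]
    if (is.na(g)) return(FALSE)
    out$first_donor[i] %in% ann_first_donors[[g]]
  }, logical(1))
  out |> select(-"gene_match")
}

lncrna_stage <- function(isoforms, annotation, genome, homology_flags,
                         thresholds) {
  novel <- isoforms |> filter(.data$novelty != "known")
  if (nrow(novel) == 0) {
    return(list(calls = tibble(), hexamer = NULL))
  }
  seqs <- vapply(seq_len(nrow(novel)), function(i) {
    blocks <- junctions_to_blocks(novel$start[i], novel$end[i],
                                  novel$junctions[[i]])
    extract_transcript_seq(genome, novel$chrom[i], novel$strand[i], blocks)
  }, character(1))
  names(seqs) <- novel$isoform_id
  hex <- train_hexamer_table(coding_training_seqs(annotation, genome,
                                                  thresholds),
                             intergenic_training_seqs(annotation, genome))
  calls <- call_lncrna(seqs, hex, homology_flags, thresholds)
  list(calls = calls, hexamer = hex)
}

# ORF regions of annotated transcripts serve as the coding training set
coding_training_seqs <- function(annotation, genome, thresholds,
                                 max_n = 150L) {
  ix <- head(seq_len(nrow(annotation)), max_n)
  out <- character(0)
  for (i in ix) {
    s <- extract_transcript_seq(genome, annotation$chrom[i],
                                annotation$strand[i], annotation$exons[[i]])
    o <- find_orfs(s, min_aa = thresholds$min_orf_aa)
    o <- o[o$has_start & o$has_stop, ]
    if (nrow(o) > 0) {
      out <- c(out, substr(s, o$start[1] + 1, o$end[1]))
    }
  }
  out
}

# deterministic intergenic tiling as the noncoding training set
intergenic_training_seqs <- function(annotation, genome, window = 500L,
                                     max_n = 150L) {
  spans <- annotation_gene_spans(annotation)
  out <- character(0)
  for (ch in names(genome)) {
    len <- Biostrings::width(genome[ch])
    gs <- spans[spans$chrom == ch, ]
    occupied <- gs[order(gs$start), c("start", "end"), drop = FALSE]
    cursor <- 0
    gaps <- list()
    for (i in seq_len(nrow(occupied))) {
      if (occupied$start[i] > cursor) {
        gaps[[length(gaps) + 1]] <- c(cursor, occupied$start[i])
      }
      cursor <- max(cursor, occupied$end[i])
    }
    if (cursor < len) gaps[[length(gaps) + 1]] <- c(cursor, len)
    for (g in gaps) {
      starts <- seq(g[1] + 200, g[2] - window - 200, by = 4 * window)
      starts <- starts[starts > 0]
      for (s in starts) {
        out <- c(out, as.character(Biostrings::subseq(genome[[ch]], s + 1,
                                                      s + window)))
        if (length(out) >= max_n) return(out)
      }
    }
  }
  out
}

expression_stage <- function(counts, thresholds) {
  sample_cols <- setdiff(names(counts), c("transcript_id", "length"))
  m <- as.matrix(counts[, sample_cols])
  rownames(m) <- counts$transcript_id
  fpkm <- compute_fpkm(m, counts$length)
  grp <- function(letter) sample_cols[startsWith(sample_cols, letter)]
  deg <- deg_screen(fpkm, grp("A"), grp("R"), thresholds = thresholds)
  spec <- r_specific_screen(fpkm, grp("A"), grp("B"), grp("R"),
                            thresholds = thresholds)
  list(fpkm = fpkm, deg = deg, r_specific = spec)
}

#' Write the pipeline's summary and result tables
#'
#' Emits fixed-column TSVs mirroring the standard report layout: mapping
#' classes, gene-structure length bins, full-length evaluation, novelty
#' partition, AS counts and events, poly(A) sites (TSV + BED6), APA
#' histogram, nucleotide profile, fusion candidates and summary, lncRNA
#' calls, expression screens, plus isoform models as BED12. All percentages
#' are printed half-up to two decimals; ratios with zero denominator print
#' `NA`.
#'
#' @param results `iso_pipeline` list from [run_pipeline()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_report_tables <- function(results, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) readr::write_tsv(x, file.path(outdir, name))

  w(results$mapping$summary, "mapping_summary.tsv")
  w(results$structure$length_bins, "structure_length_bins.tsv")
  w(results$structure$isoforms_per_locus, "isoforms_per_locus.tsv")
  w(full_length_table(results), "full_length.tsv")
  w(novelty_summary(results$isoforms, results$loci), "novelty_summary.tsv")
  w(results$as$counts, "as_counts.tsv")
  w(results$as$events, "as_events.tsv")
  w(results$polya$sites, "polya_sites.tsv")
  if (nrow(results$polya$sites) > 0) {
    bed6 <- with(results$polya$sites,
                 tibble(chrom = chrom,
                        start = ifelse(strand == "+", position - 1, position),
                        end = ifelse(strand == "+", position, position + 1),
                        name = gene_id, score = n_support, strand = strand))
    readr::write_tsv(bed6, file.path(outdir, "polya_sites.bed6"),
                     col_names = FALSE)
  }
  w(results$polya$apa$histogram, "apa_histogram.tsv")
  if (!is.null(results$polya$profile)) {
    prof <- as_tibble(results$polya$profile, rownames = "base")
    w(prof, "polya_profile.tsv")
  }
  w(results$fusions |> select(-"genes", -"cov_fracs"),
    "fusion_candidates.tsv")
  w(fusion_summary(results$fusions)$counts, "fusion_summary.tsv")
  if (!is.null(results$lncrna$calls) && nrow(results$lncrna$calls) > 0) {
    w(results$lncrna$calls, "lncrna.tsv")
  }
  if (!is.null(results$screen)) {
    w(as_tibble(results$screen$deg), "deg_screen.tsv")
    w(results$screen$r_specific, "r_specific.tsv")
  }
  w(isoform_tsv(results$isoforms), "isoforms.tsv")
  w(loci_table(results$isoforms) |> select(-"isoform_ids"), "loci.tsv")
  writeLines(isoform_bed12(results$isoforms),
             file.path(outdir, "isoforms.bed12"))
  invisible(outdir)
}

full_length_table <- function(results) {
  iso <- results$isoforms
  rd <- results$reads
  iso_multi <- iso$n_junctions > 0
  rd_multi <- rd$n_junctions > 0
  tibble(
    category = c("Multi-exon isoform", "Multi-exon FLNC"),
    total = c(sum(iso_multi), sum(rd_multi)),
    n_full_length = c(sum(iso$full_length[iso_multi], na.rm = TRUE),
                      sum(rd$full_length[rd_multi], na.rm = TRUE)),
    ratio_full_length = fmt_pct(.data$n_full_length, .data$total))
}

novelty_summary <- function(isoforms, loci) {
  tibble(
    known_isoforms = sum(isoforms$novelty == "known"),
    novel_isoforms_known_genes = sum(isoforms$novelty == "novel_of_known_gene"),
    novel_gene_isoforms = sum(isoforms$novelty == "novel_gene"),
    total_isoforms = nrow(isoforms),
    known_loci = sum(loci$gene_call == "known"),
    novel_loci = sum(loci$gene_call == "novel"),
    total_loci = nrow(loci))
}

isoform_tsv <- function(isoforms) {
  isoforms |>
    mutate(chain = map_chr(.data$junctions, function(j) {
      if (nrow(j) == 0) "." else
        paste(paste0(j[, 1], "-", j[, 2]), collapse = ",")
    }),
    support = map_chr(.data$support_reads, paste, collapse = ",")) |>
    select("isoform_id", "locus_id", "chrom", "strand", "start", "end",
           "tss", "tes", "n_junctions", "chain", "n_support", "support",
           "max_identity", "novelty", "novelty_reason", "gene_match",
           "full_length")
}

isoform_bed12 <- function(isoforms) {
  vapply(seq_len(nrow(isoforms)), function(i) {
    b <- junctions_to_blocks(isoforms$start[i], isoforms$end[i],
                             isoforms$junctions[[i]])
    sizes <- paste(b[, 2] - b[, 1], collapse = ",")
    starts <- paste(b[, 1] - isoforms$start[i], collapse = ",")
    paste(isoforms$chrom[i], isoforms$start[i], isoforms$end[i],
          isoforms$isoform_id[i], isoforms$n_support[i], isoforms$strand[i],
          isoforms$start[i], isoforms$end[i], "0", nrow(b), sizes, starts,
          sep = "\t")
  }, character(1))
}
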