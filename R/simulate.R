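# Synthetic transcriptome generator with full ground truth. Emits a toy
# genome, a reference annotation that deliberately omits the implanted novel
# transcripts, FLNC-style spliced alignments (with 5' degradation, identity
# variation, APA 3'-end variation, chimeric split reads, multi-mapping,
# low-identity and unmapped records), an A/B/R count matrix, and paired-end
# support for the implanted fusions - so every pipeline stage can be scored
# against known truth.

#' Simulation parameters
#'
#' Defaults emulate a desk-scale version of an anther Iso-Seq experiment:
#' mostly multi-exon genes, ~13% 5'-degraded reads (the complement of the
#' ~87% full-length rate typical of corrected FLNC data), post-correction
#' identities near 0.99, a minority of multi-APA genes, a few chimeric
#' fusion reads, ~1% intergenic noise reads, and negative-binomial count
#' noise (dispersion 0.1) around the A/B/R expression design.
#'
#' @param seed integer; fixes every downstream draw.
#' @param n_chroms,genes_per_chrom genome layout.
#' @param exons_per_gene,exon_len,intron_len,intergenic_gap integer ranges
#'   `c(min, max)` in exons / nt.
#' @param frac_novel_isoform_loci fraction of annotated multi-exon genes
#'   given an implanted unannotated splice variant.
#' @param frac_novel_genes novel (unannotated) genes per annotated gene.
#' @param frac_noncoding_novel fraction of novel genes that are noncoding
#'   (lncRNA-like: no long ORF, random composition).
#' @param as_event_mix named probabilities over ES/AA/AD/IR for implanted
#'   variants.
#' @param apa_site_probs probabilities of 1, 2, 3 cleavage sites per gene.
#' @param apa_site_spacing nt between implanted cleavage sites in the last
#'   exon.
#' @param apa_jitter read 3' ends are jittered uniformly within +/- this many
#'   nt of their cleavage site.
#' @param n_fusions,n_intra_fusions,reads_per_fusion,pe_pairs_per_fusion
#'   implanted chimeras: total count, how many intra-chromosomal, chimeric
#'   reads each, and simulated junction-spanning PE pairs each.
#' @param reads_per_transcript range of FLNC reads per transcript.
#' @param p_5prime_degradation probability a multi-junction read loses 5'
#'   junctions (truncated start inside a downstream exon).
#' @param identity_range,p_low_identity,low_identity_range alignment identity
#'   draws; a `p_low_identity` fraction gets `low_identity_range` instead.
#' @param p_multimap probability a read gains a tying secondary alignment.
#' @param p_unmapped fraction of reads emitted as unmapped records.
#' @param noise_read_frac intergenic single-exon noise reads, as a fraction
#'   of transcript reads.
#' @param n_R_specific_isoforms implanted novel isoforms expressed only in
#'   the restorer line.
#' @param frac_deg_genes,deg_fold fraction of features differentially
#'   expressed in R vs A, and their fold change.
#' @param baseline_fpkm_meanlog,baseline_fpkm_sdlog lognormal baseline FPKM.
#' @param nb_dispersion negative-binomial dispersion of counts (0 =
#'   noiseless rounding).
#' @param libsize per-sample library size (fragments).
#' @return named list of class `sim_params`.
#' @export
sim_params <- function(seed = 1L,
                       n_chroms = 2L,
                       genes_per_chrom = 20L,
                       exons_per_gene = c(2L, 6L),
                       exon_len = c(150L, 300L),
                       intron_len = c(80L, 400L),
                       intergenic_gap = c(12000L, 16000L),
                       frac_novel_isoform_loci = 0.30,
                       frac_novel_genes = 0.10,
                       frac_noncoding_novel = 0.50,
                       as_event_mix = c(ES = 0.30, AA = 0.25, AD = 0.20,
                                        IR = 0.25),
                       apa_site_probs = c(0.70, 0.20, 0.10),
                       apa_site_spacing = 150L,
                       apa_jitter = 5L,
                       n_fusions = 3L,
                       n_intra_fusions = 1L,
                       reads_per_fusion = 2L,
                       pe_pairs_per_fusion = 5L,
                       reads_per_transcript = c(3L, 8L),
                       p_5prime_degradation = 0.13,
                       identity_range = c(0.985, 1.0),
                       p_low_identity = 0.02,
                       low_identity_range = c(0.80, 0.90),
                       p_multimap = 0.01,
                       p_unmapped = 0.005,
                       noise_read_frac = 0.01,
                       n_R_specific_isoforms = 5L,
                       frac_deg_genes = 0.05,
                       deg_fold = 8,
                       baseline_fpkm_meanlog = log(20),
                       baseline_fpkm_sdlog = 0.6,
                       nb_dispersion = 0.1,
                       libsize = 1e6) {
  p <- as.list(environment())
  probs <- c(p$frac_novel_isoform_loci, p$frac_novel_genes,
             p$frac_noncoding_novel, p$p_5prime_degradation,
             p$p_low_identity, p$p_multimap, p$p_unmapped,
             p$noise_read_frac, p$as_event_mix, p$apa_site_probs)
  if (any(probs < 0 | probs > 1)) {
    abort("simulation probabilities must lie in [0, 1]")
  }
  for (r in list(p$exons_per_gene, p$exon_len, p$intron_len,
                 p$intergenic_gap, p$reads_per_transcript,
                 p$identity_range, p$low_identity_range)) {
    if (length(r) != 2 || any(r <= 0) || r[1] > r[2]) {
      abort("infeasible geometry: each range must be c(min, max) with 0 < min <= max")
    }
  }
  p$as_event_mix <- p$as_event_mix / sum(p$as_event_mix)
  p$apa_site_probs <- p$apa_site_probs / sum(p$apa_site_probs)
  structure(p, class = c("sim_params", "list"))
}

rint <- function(n, range) {
  if (range[1] == range[2]) rep(as.integer(range[1]), n) else
    sample(seq(range[1], range[2]), n, replace = TRUE)
}

# biased codon distribution (no stop codons): positional base preferences
# give coding sequence the asymmetry and hexamer bias real CDS has
sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(p1 = b, p2 = b, p3 = b, stringsAsFactors = FALSE)
  cod <- paste0(g$p1, g$p2, g$p3)
  keep <- !(cod %in% STOP_CODONS)
  w1 <- c(A = 0.35, C = 0.15, G = 0.35, T = 0.15)
  w2 <- c(A = 0.30, C = 0.25, G = 0.20, T = 0.25)
  w3 <- c(A = 0.15, C = 0.35, G = 0.30, T = 0.20)
  w <- w1[g$p1] * w2[g$p2] * w3[g$p3]
  list(codons = cod[keep], w = unname(w[keep]) / sum(w[keep]))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# coding mRNA: 5' UTR + ATG + biased codons + stop + 3' UTR, total length n
coding_mrna <- function(n, utr5 = 30L) {
  utr3 <- 45L
  n_cod <- max(10L, (n - utr5 - utr3 - 6L) %/% 3L)
  sc <- sense_codons()
  body <- paste(sample(sc$codons, n_cod, replace = TRUE, prob = sc$w),
                collapse = "")
  core <- paste0(random_dna(utr5), "ATG", body, "TAA")
  pad <- n - nchar(core)
  if (pad > 0) core <- paste0(core, random_dna(pad))
  list(seq = substr(core, 1, n), cds_start = utr5, cds_end = utr5 + 3L +
         3L * n_cod + 3L)
}

# noncoding sequence of length n with no ORF of >= max_aa amino acids
noncoding_rna <- function(n, max_aa = 99L) {
  for (i in 1:25) {
    s <- random_dna(n)
    if (nrow(find_orfs(s, min_aa = max_aa + 1L, both_strands = TRUE)) == 0) {
      return(s)
    }
  }
  s  # extremely unlikely fallback
}

#' Simulate a transcriptome with ground truth
#'
#' Builds the genome, annotation, transcripts (with implanted unannotated
#' splice variants, novel genes, APA sites, chimeric fusions and an A/B/R
#' expression design), generates FLNC-style alignments and counts, and
#' optionally writes `genome.fa`, `annotation.gff3`, `flnc.sam`,
#' `counts.tsv`, `pe_support.tsv` and `truth.json` to `outdir`. Identical
#' parameters (including `seed`) give byte-identical files.
#'
#' @param params [sim_params()].
#' @param outdir optional output directory (created if needed).
#' @return a `truth_set` list: `genome` (DNAStringSet), `annotation` (known
#'   transcripts), `transcripts` (all truth transcripts with labels),
#'   `reads` (read origins), `sam` (alignment records as written),
#'   `apa_sites`, `fusions`, `pe_support`, `expression` (design), `counts`,
#'   `files` (paths or NULL), `params`.
#' @export
simulate_truth_set <- function(params = sim_params(), outdir = NULL) {
  withr::local_seed(params$seed)
  layout <- sim_layout(params)
  genome <- sim_genome(layout, params)
  reads <- sim_reads(layout, params)
  layout$fusions <- reads$fusions
  expr <- sim_expression(layout, params)

  files <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    files <- list(
      genome = file.path(outdir, "genome.fa"),
      annotation = file.path(outdir, "annotation.gff3"),
      sam = file.path(outdir, "flnc.sam"),
      counts = file.path(outdir, "counts.tsv"),
      pe_support = file.path(outdir, "pe_support.tsv"),
      truth = file.path(outdir, "truth.json"))
    Biostrings::writeXStringSet(genome, files$genome)
    write_annotation(layout$annotation, files$annotation)
    write_sam(reads$sam, setNames(Biostrings::width(genome), names(genome)),
              files$sam)
    readr::write_tsv(expr$counts, files$counts)
    readr::write_tsv(layout$pe_support, files$pe_support)
    truth_json <- list(
      transcripts = layout$transcripts |>
        select("transcript_id", "gene_id", "chrom", "strand", "class",
               "expected_novelty", "coding", "r_specific", "length"),
      reads = reads$origin,
      apa_sites = layout$apa_sites,
      fusions = layout$fusions |> select(-"read_ids"),
      expression = expr$design)
    jsonlite::write_json(truth_json, files$truth, auto_unbox = TRUE,
                         digits = NA)
  }
  structure(list(genome = genome, annotation = layout$annotation,
                 transcripts = layout$transcripts, reads = reads$origin,
                 sam = reads$sam, apa_sites = layout$apa_sites,
                 fusions = layout$fusions, pe_support = layout$pe_support,
                 expression = expr$design, counts = expr$counts,
                 files = files, params = params),
            class = "truth_set")
}

# ---- gene/transcript layout ------------------------------------------------

sim_layout <- function(params) {
  p <- params
  genes <- list(); tx <- list()
  apa_sites <- list()
  chrom_names <- sprintf("chr%02d", seq_len(p$n_chroms))
  chrom_len <- setNames(integer(p$n_chroms), chrom_names)
  n_novel_per_chrom <- max(0L, round(p$frac_novel_genes * p$genes_per_chrom))
  noise_regions <- list()

  for (ci in seq_len(p$n_chroms)) {
    chrom <- chrom_names[ci]
    n_genes <- p$genes_per_chrom + n_novel_per_chrom
    novel_slots <- if (n_novel_per_chrom > 0) {
      sort(sample(seq_len(n_genes), n_novel_per_chrom))
    } else integer(0)
    cursor <- rint(1, p$intergenic_gap)
    for (gi in seq_len(n_genes)) {
      is_novel <- gi %in% novel_slots
      gene_id <- sprintf("%s_%sG%03d", chrom, if (is_novel) "NOV" else "",
                         gi)
      strand <- sample(c("+", "-"), 1)
      noncoding <- is_novel && runif(1) < p$frac_noncoding_novel
      n_ex <- if (is_novel) {
        if (noncoding) 1L else rint(1, c(2L, 3L))
      } else rint(1, p$exons_per_gene)
      ex_len <- rint(n_ex, p$exon_len)
      if (noncoding) ex_len <- rint(1, c(600L, 1000L))
      # coding novel genes must hold a reportable ORF (>= 100 aa + UTRs)
      if (is_novel && !noncoding) ex_len <- pmax(ex_len, 250L)
      n_sites <- if (is_novel) 1L else
        sample(seq_along(p$apa_site_probs), 1, prob = p$apa_site_probs)
      # the 3'-terminal exon (genomic last on '+', first on '-') must hold
      # every cleavage site with spacing
      min_last <- p$apa_site_spacing * n_sites + 60L
      term <- if (strand == "+") n_ex else 1L
      ex_len[term] <- max(ex_len[term], min_last)
      in_len <- if (n_ex > 1) rint(n_ex - 1, p$intron_len) else integer(0)
      starts <- cursor + cumsum(c(0L, ex_len[-n_ex] + in_len))
      exons <- cbind(start = starts, end = starts + ex_len)
      gene_end <- exons[n_ex, 2]
      # cleavage sites sit in the 3'-terminal exon, stepped back from the
      # transcript 3' end
      offs <- p$apa_site_spacing * (seq_len(n_sites) - 1L)
      sites <- if (strand == "+") gene_end - offs else exons[1, 1] + offs
      genes[[gene_id]] <- list(gene_id = gene_id, chrom = chrom,
                               strand = strand, exons = exons,
                               is_novel = is_novel, noncoding = noncoding,
                               sites = sort(sites))
      apa_sites[[gene_id]] <- tibble(gene_id = gene_id, chrom = chrom,
                                     strand = strand, position = sort(sites))
      mid_gap <- gene_end + rint(1, p$intergenic_gap)
      noise_regions[[length(noise_regions) + 1]] <-
        tibble(chrom = chrom, pos = gene_end + 3000L)
      cursor <- mid_gap
    }
    chrom_len[chrom] <- cursor + rint(1, p$intergenic_gap)
  }

  # base transcript per gene + implanted variants on eligible known genes
  tx_rows <- list()
  for (g in genes) {
    tid <- paste0(g$gene_id, ".1")
    tx_rows[[tid]] <- tibble(
      transcript_id = tid, gene_id = g$gene_id, chrom = g$chrom,
      strand = g$strand, exons = list(g$exons),
      class = if (g$is_novel) "novel_gene" else "known",
      expected_novelty = if (g$is_novel) "novel_gene" else "known",
      coding = !g$noncoding, as_type = NA_character_,
      as_start = NA_real_, as_end = NA_real_, r_specific = FALSE)
  }
  eligible <- names(genes)[vapply(genes, function(g) {
    !g$is_novel && nrow(g$exons) >= 3
  }, logical(1))]
  n_var <- round(p$frac_novel_isoform_loci * length(eligible))
  var_genes <- if (n_var > 0) sort(sample(eligible, n_var)) else character(0)
  for (gid in var_genes) {
    g <- genes[[gid]]
    type <- sample(names(p$as_event_mix), 1, prob = p$as_event_mix)
    v <- implant_variant(g, type)
    if (is.null(v)) next
    tid <- paste0(gid, ".v")
    tx_rows[[tid]] <- tibble(
      transcript_id = tid, gene_id = gid, chrom = g$chrom,
      strand = g$strand, exons = list(v$exons),
      class = "novel_isoform",
      # the novelty rule is splice-site based: skipping/retention variants
      # reuse annotated sites and are therefore known by rule
      expected_novelty = if (v$new_site) "novel_of_known_gene" else "known",
      coding = TRUE, as_type = v$type, as_start = v$start, as_end = v$end,
      r_specific = FALSE)
  }
  transcripts <- bind_rows(tx_rows)
  transcripts$length <- vapply(transcripts$exons,
                               function(e) sum(e[, 2] - e[, 1]), numeric(1))

  # restorer-specific labels: prefer genuinely novel features
  cand <- which(transcripts$expected_novelty != "known")
  if (length(cand) < p$n_R_specific_isoforms) {
    cand <- c(cand, setdiff(seq_len(nrow(transcripts)), cand))
  }
  if (p$n_R_specific_isoforms > 0) {
    transcripts$r_specific[sort(cand[seq_len(min(p$n_R_specific_isoforms,
                                                 length(cand)))])] <- TRUE
  }

  annotation <- transcripts |>
    filter(.data$class == "known") |>
    select("transcript_id", "gene_id", "chrom", "strand", "exons") |>
    mutate(n_exons = vapply(.data$exons, nrow, integer(1)), .before = "exons")
  annotation$cds <- vector("list", nrow(annotation))

  # fusion gene pairs among known genes, far apart by construction
  known_ids <- annotation$gene_id
  fusions <- sim_fusion_pairs(genes, known_ids, params)
  pe_support <- if (nrow(fusions) > 0) {
    tibble(gene_a = fusions$gene_a, gene_b = fusions$gene_b,
           n_pairs = p$pe_pairs_per_fusion)
  } else tibble(gene_a = character(), gene_b = character(),
                n_pairs = integer())

  list(genes = genes, transcripts = transcripts, annotation = annotation,
       apa_sites = bind_rows(apa_sites), fusions = fusions,
       pe_support = pe_support, chrom_len = chrom_len,
       noise_regions = bind_rows(noise_regions))
}

# structural variant of a gene's base transcript; returns NULL if infeasible
implant_variant <- function(g, type) {
  ex <- g$exons
  n <- nrow(ex)
  shift <- 15L
  mid_j <- max(1L, (n - 1L) %/% 2L)  # middle junction index
  if (type == "ES" && n >= 3) {
    k <- max(2L, n %/% 2L)  # internal exon to skip
    list(exons = ex[-k, , drop = FALSE], type = "ES", new_site = FALSE,
         start = ex[k, 1], end = ex[k, 2])
  } else if (type == "IR" && n >= 2) {
    # never retain the transcript-first intron: the variant's chain would be
    # a 5' suffix of the base chain and be absorbed by degradation pruning
    k <- if (n == 2) 1L else if (g$strand == "+") max(2L, mid_j) else
      min(n - 2L, mid_j)
    v <- ex
    v[k, 2] <- v[k + 1, 2]
    v <- v[-(k + 1), , drop = FALSE]
    list(exons = v, type = "IR", new_site = FALSE,
         start = ex[k, 2], end = ex[k + 1, 1])
  } else if (type %in% c("AA", "AD") && n >= 2) {
    k <- mid_j
    v <- ex
    # AA shifts the acceptor (intron 3' end in transcript orientation),
    # AD the donor; pick the genomic boundary accordingly
    move_gap_end <- (type == "AA") == (g$strand == "+")
    if (move_gap_end) v[k + 1, 1] <- v[k + 1, 1] + shift
    else v[k, 2] <- v[k, 2] - shift
    if (v[k, 2] - v[k, 1] < 30 || v[k + 1, 2] - v[k + 1, 1] < 30) {
      return(NULL)
    }
    list(exons = v, type = type, new_site = TRUE,
         start = min(ex[k, 2], v[k, 2]),
         end = max(ex[k + 1, 1], v[k + 1, 1]))
  } else NULL
}

sim_fusion_pairs <- function(genes, known_ids, params) {
  p <- params
  if (p$n_fusions == 0 || length(known_ids) < 4) {
    return(tibble(fusion_id = character(), gene_a = character(),
                  gene_b = character(), category = character(),
                  read_ids = list()))
  }
  info <- bind_rows(lapply(genes[known_ids], function(g) {
    tibble(gene_id = g$gene_id, chrom = g$chrom)
  }))
  used <- character(0)
  rows <- list()
  n_intra <- min(p$n_intra_fusions, p$n_fusions)
  for (i in seq_len(p$n_fusions)) {
    intra <- i <= n_intra
    avail <- info |> filter(!(.data$gene_id %in% used))
    pair <- NULL
    if (intra) {
      for (ch in unique(avail$chrom)) {
        g <- avail$gene_id[avail$chrom == ch]
        if (length(g) >= 2) { pair <- g[1:2]; break }
      }
    } else if (length(unique(avail$chrom)) >= 2) {
      ch <- sort(unique(avail$chrom))[1:2]
      pair <- c(avail$gene_id[avail$chrom == ch[1]][1],
                avail$gene_id[avail$chrom == ch[2]][1])
    }
    if (is.null(pair) || any(is.na(pair))) next
    used <- c(used, pair)
    rows[[i]] <- tibble(
      fusion_id = sprintf("FUS%02d", i),
      gene_a = min(pair), gene_b = max(pair),
      category = if (intra) "intra_chromosome" else "inter_chromosome",
      read_ids = list(character(0)))
  }
  bind_rows(rows)
}

# ---- genome sequence -------------------------------------------------------

sim_genome <- function(layout, params) {
  chrs <- lapply(names(layout$chrom_len), function(ch) {
    strsplit(random_dna(layout$chrom_len[[ch]]), "")[[1]]
  })
  names(chrs) <- names(layout$chrom_len)

  put <- function(chrom, start0, seq) {
    chrs[[chrom]][(start0 + 1):(start0 + nchar(seq))] <<-
      strsplit(seq, "")[[1]]
  }
  revcomp <- function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }

  # write base-transcript sequence into exon regions (coding genes get a
  # CDS; noncoding novels get ORF-free sequence)
  for (g in layout$genes) {
    ex <- g$exons
    total <- sum(ex[, 2] - ex[, 1])
    mr <- if (g$noncoding) list(seq = noncoding_rna(total)) else
      coding_mrna(total)
    s <- mr$seq
    genomic <- if (g$strand == "-") revcomp(s) else s
    off <- 0L
    for (i in seq_len(nrow(ex))) {
      w <- ex[i, 2] - ex[i, 1]
      put(g$chrom, ex[i, 1], substr(genomic, off + 1, off + w))
      off <- off + w
    }
  }

  # cleavage-site signal: transcript-upstream U(T)-rich 10-nt window and
  # >= 1 genomic adenosine directly downstream of each site
  u_rich <- function(n) {
    paste(ifelse(runif(n) < 0.8, "T",
                 sample(c("A", "C", "G"), n, replace = TRUE)),
          collapse = "")
  }
  for (i in seq_len(nrow(layout$apa_sites))) {
    st <- layout$apa_sites[i, ]
    if (st$strand == "+") {
      put(st$chrom, st$position - 10, u_rich(10))
      put(st$chrom, st$position, "AAA")
    } else {
      put(st$chrom, st$position + 1,
          revcomp(u_rich(10)))  # A-rich on the forward strand
      put(st$chrom, st$position - 3, "TTT")
    }
  }
  Biostrings::DNAStringSet(vapply(chrs, paste, character(1), collapse = ""))
}

# ---- reads -----------------------------------------------------------------

blocks_to_cigar <- function(blocks, lead_clip = 0L, tail_clip = 0L) {
  nb <- nrow(blocks)
  parts <- character(0)
  if (lead_clip > 0) parts <- c(parts, sprintf("%dS", lead_clip))
  for (i in seq_len(nb)) {
    parts <- c(parts, sprintf("%dM", blocks[i, 2] - blocks[i, 1]))
    if (i < nb) parts <- c(parts, sprintf("%dN", blocks[i + 1, 1] - blocks[i, 2]))
  }
  if (tail_clip > 0) parts <- c(parts, sprintf("%dS", tail_clip))
  paste(parts, collapse = "")
}

# truncate exon blocks to end at the 3' coordinate `end3` (strand-aware)
truncate_3prime <- function(blocks, strand, end3) {
  if (strand == "+") {
    keep <- blocks[, 1] < end3
    b <- blocks[keep, , drop = FALSE]
    b[nrow(b), 2] <- min(b[nrow(b), 2], end3)
  } else {
    keep <- blocks[, 2] > end3
    b <- blocks[keep, , drop = FALSE]
    b[1, 1] <- max(b[1, 1], end3)
  }
  b
}

# drop the 5'-most `k` junctions and start inside the first retained exon
degrade_5prime <- function(blocks, strand, k, offset) {
  nb <- nrow(blocks)
  if (strand == "+") {
    b <- blocks[(k + 1):nb, , drop = FALSE]
    b[1, 1] <- min(b[1, 1] + offset, b[1, 2] - 20L)
  } else {
    b <- blocks[1:(nb - k), , drop = FALSE]
    b[nrow(b), 2] <- max(b[nrow(b), 2] - offset, b[nrow(b), 1] + 20L)
  }
  b
}

sim_reads <- function(layout, params) {
  p <- params
  tx <- layout$transcripts
  sam <- list(); origin <- list()
  rid_n <- 0L
  next_rid <- function() {
    rid_n <<- rid_n + 1L
    sprintf("read/%06d/ccs", rid_n)
  }
  gene_sites <- split(layout$apa_sites$position, layout$apa_sites$gene_id)

  emit <- function(read_id, chrom, strand, blocks, identity,
                   flag_extra = 0L, lead_clip = 0L, tail_clip = 0L) {
    m_len <- sum(blocks[, 2] - blocks[, 1])
    nm <- as.integer(round((1 - identity) * m_len))
    flag <- flag_extra + if (strand == "-") 16L else 0L
    sam[[length(sam) + 1L]] <<- tibble(
      read_id = read_id, flag = flag, chrom = chrom, pos0 = blocks[1, 1],
      cigar = blocks_to_cigar(blocks, lead_clip, tail_clip), nm = nm)
  }

  for (ti in seq_len(nrow(tx))) {
    t <- tx[ti, ]
    g <- layout$genes[[t$gene_id]]
    sites <- gene_sites[[t$gene_id]]
    n_reads <- rint(1, p$reads_per_transcript)
    n_reads <- max(n_reads, 2L * length(sites))
    site_of <- rep_len(sites, n_reads)  # round robin keeps every site covered
    for (r in seq_len(n_reads)) {
      rid <- next_rid()
      if (runif(1) < p$p_unmapped) {
        sam[[length(sam) + 1L]] <- tibble(read_id = rid, flag = 4L,
                                          chrom = NA_character_,
                                          pos0 = NA_integer_,
                                          cigar = NA_character_,
                                          nm = NA_integer_)
        origin[[length(origin) + 1L]] <- tibble(
          read_id = rid, origin = "unmapped", transcript_id = t$transcript_id,
          degraded = FALSE, cleavage_site = NA_real_)
        next
      }
      jit <- if (p$apa_jitter > 0) {
        sample(seq(-p$apa_jitter, p$apa_jitter), 1)
      } else 0L
      end3 <- site_of[r] + if (t$strand == "+") jit else -jit
      blocks <- truncate_3prime(t$exons[[1]], t$strand, end3)
      degraded <- FALSE
      if (nrow(blocks) >= 3 && runif(1) < p$p_5prime_degradation) {
        k <- sample(seq_len(nrow(blocks) - 2L), 1)
        blocks <- degrade_5prime(blocks, t$strand, k,
                                 offset = sample(5:60, 1))
        degraded <- TRUE
      }
      identity <- if (runif(1) < p$p_low_identity) {
        runif(1, p$low_identity_range[1], p$low_identity_range[2])
      } else runif(1, p$identity_range[1], p$identity_range[2])
      emit(rid, t$chrom, t$strand, blocks, identity)
      if (runif(1) < p$p_multimap) {
        # tying secondary alignment elsewhere (same score)
        other <- layout$genes[[sample(names(layout$genes), 1)]]
        emit(rid, other$chrom, t$strand,
             blocks - blocks[1, 1] + other$exons[1, 1], identity,
             flag_extra = 256L)
      }
      origin[[length(origin) + 1L]] <- tibble(
        read_id = rid, origin = "transcript",
        transcript_id = t$transcript_id, degraded = degraded,
        cleavage_site = site_of[r])
    }
  }

  # chimeric fusion reads: two supplementary-linked records
  fus <- layout$fusions
  fus_read_ids <- vector("list", nrow(fus))
  for (fi in seq_len(nrow(fus))) {
    ga <- layout$genes[[fus$gene_a[fi]]]
    gb <- layout$genes[[fus$gene_b[fi]]]
    for (r in seq_len(p$reads_per_fusion)) {
      rid <- next_rid()
      frac_a <- runif(1, 0.40, 0.60)
      # 3' fragment of gene A + 5' fragment of gene B
      len_a_target <- round(frac_a * 1000)
      len_b_target <- 1000 - len_a_target
      blocks_a <- fragment_3prime(ga$exons, ga$strand, len_a_target)
      blocks_b <- fragment_5prime(gb$exons, gb$strand, len_b_target)
      len_a <- sum(blocks_a[, 2] - blocks_a[, 1])
      len_b <- sum(blocks_b[, 2] - blocks_b[, 1])
      identity <- runif(1, 0.992, 1)
      emit(rid, ga$chrom, ga$strand, blocks_a, identity,
           lead_clip = 0L, tail_clip = len_b)
      emit(rid, gb$chrom, gb$strand, blocks_b, identity,
           flag_extra = 2048L, lead_clip = len_a, tail_clip = 0L)
      fus_read_ids[[fi]] <- c(fus_read_ids[[fi]], rid)
      origin[[length(origin) + 1L]] <- tibble(
        read_id = rid, origin = "fusion", transcript_id = fus$fusion_id[fi],
        degraded = FALSE, cleavage_site = NA_real_)
    }
  }
  if (nrow(fus) > 0) fus$read_ids <- fus_read_ids
  layout$fusions <- fus

  # intergenic single-exon noise reads
  n_noise <- round(p$noise_read_frac * rid_n)
  if (n_noise > 0) {
    regions <- layout$noise_regions
    pick <- regions[rep_len(seq_len(nrow(regions)), n_noise), ]
    for (r in seq_len(n_noise)) {
      rid <- next_rid()
      start <- pick$pos[r]
      blocks <- cbind(start = start, end = start + 300L)
      emit(rid, pick$chrom[r], sample(c("+", "-"), 1), blocks,
           runif(1, 0.995, 1))
      origin[[length(origin) + 1L]] <- tibble(
        read_id = rid, origin = "noise", transcript_id = NA_character_,
        degraded = FALSE, cleavage_site = NA_real_)
    }
  }

  list(sam = bind_rows(sam), origin = bind_rows(origin),
       fusions = layout$fusions)
}

# 3'-terminal / 5'-terminal fragment of an exon chain with ~target nt
fragment_3prime <- function(blocks, strand, target) {
  if (strand == "+") take_last_blocks(blocks, target) else
    take_first_blocks(blocks, target)
}

fragment_5prime <- function(blocks, strand, target) {
  if (strand == "+") take_first_blocks(blocks, target) else
    take_last_blocks(blocks, target)
}

take_first_blocks <- function(blocks, target) {
  cum <- cumsum(blocks[, 2] - blocks[, 1])
  k <- which(cum >= target)[1]
  if (is.na(k)) k <- nrow(blocks)
  b <- blocks[seq_len(k), , drop = FALSE]
  excess <- max(0L, sum(b[, 2] - b[, 1]) - target)
  b[k, 2] <- b[k, 2] - excess
  b
}

take_last_blocks <- function(blocks, target) {
  n <- nrow(blocks)
  cum <- cumsum(rev(blocks[, 2] - blocks[, 1]))
  k <- which(cum >= target)[1]
  if (is.na(k)) k <- n
  b <- blocks[seq(n - k + 1, n), , drop = FALSE]
  excess <- max(0L, sum(b[, 2] - b[, 1]) - target)
  b[1, 1] <- b[1, 1] + excess
  b
}

# ---- expression design & counts -------------------------------------------

sim_expression <- function(layout, params) {
  p <- params
  tx <- layout$transcripts
  n <- nrow(tx)
  base <- exp(rnorm(n, p$baseline_fpkm_meanlog, p$baseline_fpkm_sdlog))
  fa <- fb <- fr <- base
  deg <- runif(n) < p$frac_deg_genes & !tx$r_specific
  fr[deg] <- fr[deg] * p$deg_fold
  fa[tx$r_specific] <- 0
  fb[tx$r_specific] <- 0
  fr[tx$r_specific] <- runif(sum(tx$r_specific), 5, 15)
  design <- tibble(transcript_id = tx$transcript_id, length = tx$length,
                   fpkm_a = fa, fpkm_b = fb, fpkm_r = fr,
                   # restorer-specific features are up-regulated R vs A by
                   # construction, so they count as true DEGs too
                   deg_r_vs_a = deg | tx$r_specific,
                   r_specific = tx$r_specific)

  draw <- function(fpkm) {
    mu <- fpkm * design$length / 1000 * (p$libsize / 1e6)
    if (p$nb_dispersion == 0) round(mu) else
      rnbinom(n, mu = mu, size = 1 / p$nb_dispersion)
  }
  samples <- c(paste0("A", 1:3), paste0("B", 1:3), paste0("R", 1:3))
  cnt <- sapply(seq_along(samples), function(s) {
    draw(switch(substr(samples[s], 1, 1), A = fa, B = fb, R = fr))
  })
  colnames(cnt) <- samples
  counts <- bind_cols(tibble(transcript_id = tx$transcript_id,
                             length = as.integer(tx$length)),
                      as_tibble(cnt))
  list(design = design, counts = counts)
}
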