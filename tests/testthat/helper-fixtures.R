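# Shared fixture builders and brute-force oracles. Everything is generated
# in code; no fixture files.

# one alignment record in the shape read_alignments() returns
make_aln <- function(read_id, chrom, strand, blocks, identity = 1,
                     mapped = TRUE, secondary = FALSE,
                     supplementary = FALSE, read_length = NULL,
                     aligned_read_span = 1) {
  bm <- matrix(as.numeric(blocks), ncol = 2,
               dimnames = list(NULL, c("start", "end")))
  if (is.null(read_length)) read_length <- sum(bm[, 2] - bm[, 1])
  tibble::tibble(
    read_id = read_id, flag = 0L, mapped = mapped, chrom = chrom,
    strand = strand, blocks = list(bm),
    span_start = bm[1, 1], span_end = bm[nrow(bm), 2],
    n_blocks = nrow(bm), read_length = as.integer(read_length),
    aligned_read_span = aligned_read_span, identity = identity,
    secondary = secondary, supplementary = supplementary)
}

# minimal isoform row for AS / classification tests
make_iso <- function(id, chrom, strand, exons, locus_id = "L1",
                     n_support = 2L, max_identity = 1) {
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  j <- isocraft:::blocks_to_junctions(exons)
  sc <- build_splice_chain(exons, strand)
  tibble::tibble(
    isoform_id = id, chrom = chrom, strand = strand,
    start = exons[1, 1], end = exons[nrow(exons), 2],
    tss = sc$tss, tes = sc$tes, n_junctions = nrow(j),
    junctions = list(j), single_exon = nrow(j) == 0,
    support_reads = list(paste0(id, "_r", seq_len(n_support))),
    n_support = n_support, max_identity = max_identity,
    locus_id = locus_id)
}

# annotation tibble from a list of list(tid, gid, chrom, strand, exons, cds)
make_annotation <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    ex <- matrix(as.numeric(r$exons), ncol = 2,
                 dimnames = list(NULL, c("start", "end")))
    tibble::tibble(transcript_id = r$tid, gene_id = r$gid, chrom = r$chrom,
                   strand = r$strand, n_exons = nrow(ex), exons = list(ex),
                   cds = list(r$cds %||% NULL))
  }))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# brute-force chain grouping: all-pairs comparison, transitive closure
oracle_collapse_groups <- function(chroms, strands, chains) {
  n <- length(chains)
  same <- function(i, j) {
    identical(chroms[i], chroms[j]) && identical(strands[i], strands[j]) &&
      nrow(chains[[i]]) == nrow(chains[[j]]) &&
      all(chains[[i]] == chains[[j]])
  }
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (same(i, j) && lab[i] != lab[j]) {
        lab[lab == lab[j]] <- lab[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

# brute-force ORF enumeration: every ATG -> next in-frame stop; keep maximal
# (first ATG after the previous stop) complete ORFs of >= min_aa
oracle_orfs <- function(seq, min_aa) {
  seq <- toupper(seq)
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  for (f in 0:2) {
    starts <- seq(f + 1, n - 2, by = 3)
    if (length(starts) == 0) next
    codons <- substring(seq, starts, starts + 2)
    prev_stop <- 0
    i <- 1
    while (i <= length(codons)) {
      if (codons[i] %in% stops) { prev_stop <- i; i <- i + 1; next }
      if (codons[i] == "ATG") {
        later_stops <- which(codons %in% stops)
        nxt <- later_stops[later_stops > i]
        if (length(nxt) > 0) {
          aa <- nxt[1] - i
          # maximal: no earlier ATG in (prev_stop, i)
          earlier <- which(codons == "ATG")
          earlier <- earlier[earlier > prev_stop & earlier < i]
          if (length(earlier) == 0 && aa >= min_aa) {
            out[[length(out) + 1]] <- data.frame(
              frame = f, start = f + 3 * (i - 1), end = f + 3 * nxt[1],
              aa_length = aa)
          }
          # jump to after this stop
          prev_stop <- nxt[1]
          i <- nxt[1] + 1
          next
        }
      }
      i <- i + 1
    }
  }
  if (length(out) == 0) {
    return(data.frame(frame = integer(), start = integer(),
                      end = integer(), aa_length = integer()))
  }
  do.call(rbind, out)
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# cached noiseless simulation shared by several test files
noiseless_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- sim_params(seed = 11, n_chroms = 3, genes_per_chrom = 15,
                      p_5prime_degradation = 0, identity_range = c(1, 1),
                      p_low_identity = 0, p_multimap = 0, p_unmapped = 0,
                      noise_read_frac = 0, apa_jitter = 0, nb_dispersion = 0)
      dir <- file.path(tempdir(), "isocraft-noiseless")
      tr <- simulate_truth_set(p, outdir = dir)
      res <- run_pipeline(file.path(dir, "genome.fa"),
                          file.path(dir, "annotation.gff3"),
                          file.path(dir, "flnc.sam"),
                          counts = file.path(dir, "counts.tsv"),
                          pe_support = file.path(dir, "pe_support.tsv"))
      cache <<- list(truth = tr, res = res, dir = dir)
    }
    cache
  }
})
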