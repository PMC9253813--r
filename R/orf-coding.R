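# ORF prediction, Fickett TESTCODE + hexamer coding-potential scoring, and
# lncRNA candidate calling for novel isoforms.

#' Extract the spliced transcript sequence of an isoform
#'
#' Concatenates exonic genomic sequence in transcript orientation
#' (reverse-complemented on `-`).
#'
#' @param genome named [Biostrings::DNAStringSet] or named character vector.
#' @param chrom,strand location of the isoform.
#' @param blocks exon `start`/`end` matrix (0-based half-open, sorted).
#' @return character scalar, the transcript sequence 5'->3'.
#' @export
extract_transcript_seq <- function(genome, chrom, strand, blocks) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  parts <- vapply(seq_len(nrow(blocks)), function(i) {
    as.character(Biostrings::subseq(genome[[chrom]], blocks[i, 1] + 1,
                                    blocks[i, 2]))
  }, character(1))
  s <- paste(parts, collapse = "")
  if (strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find open reading frames in a transcript sequence
#'
#' Scans the three forward frames of the already-oriented transcript. For
#' each frame, reports maximal complete ORFs (the first ATG after the
#' previous stop, through the next in-frame stop) of at least `min_aa` amino
#' acids, 3'-partial ORFs that run off the sequence end without a stop, and
#' 5'-partial spans (frame start to first stop with no usable ATG) -
#' partial calls are flagged `is_complete = FALSE`. Set `both_strands = TRUE`
#' for six-frame search on strand-unknown single-exon isoforms.
#'
#' @param seq nucleotide string (A/C/G/T/N).
#' @param min_aa minimum ORF length in amino acids, inclusive; the stop codon
#'   is not counted.
#' @param both_strands also scan the reverse complement.
#' @return tibble: `frame` (0..2, negative for reverse strand), `start`,
#'   `end` (0-based half-open, in input-sequence coordinates on the scanned
#'   strand), `aa_length`, `has_start`, `has_stop`, `is_complete`.
#' @export
find_orfs <- function(seq, min_aa = 100L, both_strands = FALSE) {
  seq <- toupper(seq)
  out <- orf_scan_frames(seq, min_aa, rev = FALSE)
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    out <- bind_rows(out, orf_scan_frames(rc, min_aa, rev = TRUE))
  }
  out |> arrange(desc(.data$aa_length), .data$frame, .data$start)
}

orf_scan_frames <- function(seq, min_aa, rev = FALSE) {
  n <- nchar(seq)
  res <- list()
  for (f in 0:2) {
    n_cod <- (n - f) %/% 3
    if (n_cod < 1) next
    codons <- substring(seq, f + 1 + 3 * (seq_len(n_cod) - 1),
                        f + 3 * seq_len(n_cod))
    is_stop <- codons %in% STOP_CODONS
    is_atg <- codons == "ATG"
    stop_pos <- which(is_stop)
    seg_bounds <- c(0L, stop_pos, if (length(stop_pos) == 0 ||
                                      stop_pos[length(stop_pos)] < n_cod)
      n_cod + 1L)
    for (s in seq_len(length(seg_bounds) - 1)) {
      lo <- seg_bounds[s] + 1L              # first codon after prev stop
      hi <- seg_bounds[s + 1]               # stop codon index, or n_cod+1
      has_stop <- hi <= n_cod
      seg_end <- hi - 1L                    # last sense codon
      if (seg_end < lo) next
      atg <- which(is_atg[lo:seg_end])
      if (length(atg) > 0) {
        first_atg <- lo + atg[1] - 1L
        aa <- seg_end - first_atg + 1L
        if (aa >= min_aa) {
          res[[length(res) + 1]] <- tibble(
            frame = if (rev) -f else f,
            start = f + 3 * (first_atg - 1L),
            end = f + 3 * (if (has_stop) hi else seg_end),
            aa_length = aa, has_start = TRUE, has_stop = has_stop,
            is_complete = has_stop)
        }
      } else if (s == 1) {
        # 5'-partial: runs from the frame start, no ATG
        aa <- seg_end - lo + 1L
        if (aa >= min_aa) {
          res[[length(res) + 1]] <- tibble(
            frame = if (rev) -f else f,
            start = f, end = f + 3 * (if (has_stop) hi else seg_end),
            aa_length = aa, has_start = FALSE, has_stop = has_stop,
            is_complete = FALSE)
        }
      }
    }
  }
  if (length(res) == 0) {
    return(tibble(frame = integer(), start = integer(), end = integer(),
                  aa_length = integer(), has_start = logical(),
                  has_stop = logical(), is_complete = logical()))
  }
  bind_rows(res)
}

# Fickett (1982) TESTCODE lookup tables: probability that a window with the
# given position-asymmetry / composition value is coding, plus the weights
# reflecting each parameter's discriminating power.
FICKETT_POSITION_PROB <- list(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
FICKETT_POSITION_WEIGHT <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
FICKETT_POSITION_BREAKS <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0)
FICKETT_CONTENT_PROB <- list(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.50, 0.69, 0.46, 0.31),
  G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
  T = c(0.28, 0.24, 0.26, 0.33, 0.26, 0.31, 0.41, 0.56, 0.79, 0.51))
FICKETT_CONTENT_WEIGHT <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
FICKETT_CONTENT_BREAKS <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19,
                            0.17, 0)

fickett_lookup <- function(value, breaks, probs) {
  probs[which(value >= breaks)[1]]
}

#' Fickett TESTCODE coding-potential statistic
#'
#' Computes the classic TESTCODE score from eight sequence parameters: for
#' each base, its positional asymmetry across the three codon positions
#' (`max count / (min count + 1)`) and its overall composition, each mapped
#' through the published probability tables and combined with the published
#' weights. Higher is more coding-like; by construction of the tables the
#' score lies between the weighted minima and maxima (about 0.29-1.40).
#' Sequences shorter than 200 nt are still scored but flagged unreliable.
#'
#' @param seq nucleotide string.
#' @return scalar score with attribute `reliable` (FALSE below 200 nt).
#' @export
fickett_score <- function(seq) {
  seq <- toupper(seq)
  bases <- strsplit(seq, "")[[1]]
  bases <- bases[bases %in% c("A", "C", "G", "T")]
  n <- length(bases)
  if (n < 3) abort("sequence too short for a Fickett score")
  pos <- (seq_len(n) - 1L) %% 3L
  score <- 0
  for (b in c("A", "C", "G", "T")) {
    cnt <- vapply(0:2, function(p) sum(bases == b & pos == p), numeric(1))
    posval <- max(cnt) / (min(cnt) + 1)
    content <- sum(cnt) / n
    score <- score +
      FICKETT_POSITION_WEIGHT[[b]] *
        fickett_lookup(posval, FICKETT_POSITION_BREAKS,
                       FICKETT_POSITION_PROB[[b]]) +
      FICKETT_CONTENT_WEIGHT[[b]] *
        fickett_lookup(content, FICKETT_CONTENT_BREAKS,
                       FICKETT_CONTENT_PROB[[b]])
  }
  structure(score, reliable = n >= 200)
}

#' Train a hexamer usage table
#'
#' Tabulates in-frame (step 3) hexamer frequencies over coding sequences and
#' sliding (step 1) hexamer frequencies over noncoding sequences, with
#' add-one smoothing, for the hexamer log-likelihood-ratio score.
#'
#' @param coding_seqs character vector of CDS sequences (frame 0).
#' @param noncoding_seqs character vector of noncoding sequences.
#' @return list of two named probability vectors over the 4096 hexamers.
#' @export
train_hexamer_table <- function(coding_seqs, noncoding_seqs) {
  all_hex <- hexamer_universe()
  count_hex <- function(seqs, step) {
    tab <- setNames(rep(1, length(all_hex)), all_hex)  # add-one smoothing
    for (s in seqs) {
      s <- toupper(s)
      n <- nchar(s)
      if (n < 6) next
      starts <- seq(1, n - 5, by = step)
      hx <- substring(s, starts, starts + 5)
      hx <- hx[!grepl("[^ACGT]", hx)]
      t2 <- table(hx)
      tab[names(t2)] <- tab[names(t2)] + as.numeric(t2)
    }
    tab / sum(tab)
  }
  list(coding = count_hex(coding_seqs, 3L),
       noncoding = count_hex(noncoding_seqs, 1L))
}

hexamer_universe <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)
  apply(g[, 6:1], 1, paste, collapse = "")
}

#' Hexamer log-likelihood-ratio score
#'
#' Mean log(coding/noncoding) probability over in-frame hexamers, maximized
#' over the three forward frames. Positive values are coding-like.
#'
#' @param seq nucleotide string.
#' @param hex_table list from [train_hexamer_table()].
#' @return scalar log-likelihood ratio.
#' @export
hexamer_score <- function(seq, hex_table) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 6) return(0)
  best <- -Inf
  for (f in 0:2) {
    starts <- seq(1 + f, n - 5, by = 3)
    if (length(starts) == 0) next
    hx <- substring(seq, starts, starts + 5)
    hx <- hx[!grepl("[^ACGT]", hx)]
    if (length(hx) == 0) next
    llr <- mean(log(hex_table$coding[hx] / hex_table$noncoding[hx]))
    if (llr > best) best <- llr
  }
  if (is.finite(best)) best else 0
}

#' Combined coding-potential verdict
#'
#' Transparent two-voter rule: Fickett TESTCODE votes coding above
#' `fickett_coding` (default 1.10) and noncoding below `fickett_noncoding`
#' (default 0.95); the hexamer LLR votes by sign. The verdict is `coding` or
#' `noncoding` when both voters agree, `ambiguous` otherwise.
#'
#' @param seqs named character vector of transcript sequences.
#' @param hex_table list from [train_hexamer_table()].
#' @param thresholds [iso_thresholds()].
#' @return tibble: `id`, `fickett`, `hexamer_llr`, `verdict`.
#' @export
coding_potential <- function(seqs, hex_table,
                             thresholds = iso_thresholds()) {
  ids <- names(seqs) %||% as.character(seq_along(seqs))
  fick <- vapply(seqs, function(s) as.numeric(fickett_score(s)), numeric(1))
  hexl <- vapply(seqs, hexamer_score, numeric(1), hex_table = hex_table)
  f_vote <- ifelse(fick > thresholds$fickett_coding, "coding",
                   ifelse(fick < thresholds$fickett_noncoding, "noncoding",
                          "ambiguous"))
  h_vote <- ifelse(hexl > 0, "coding", "noncoding")
  verdict <- ifelse(f_vote == h_vote, f_vote, "ambiguous")
  tibble(id = ids, fickett = unname(fick), hexamer_llr = unname(hexl),
         verdict = verdict)
}

#' Call lncRNA candidates among novel isoforms
#'
#' A novel isoform is a lncRNA candidate when it is at least `min_lncrna_len`
#' nt long, carries no protein homology flag, has no ORF of `min_orf_aa`
#' or more amino acids, and its coding-potential verdict is not `coding`
#' (`ambiguous` counts as noncoding for candidacy and is logged as such).
#' Each exclusion's reason is recorded.
#'
#' @param seqs named character vector of novel-isoform sequences.
#' @param hex_table list from [train_hexamer_table()].
#' @param homology_flags optional named logical vector; `TRUE` marks a
#'   protein-database hit (isoform excluded regardless of scores).
#' @param thresholds [iso_thresholds()].
#' @return tibble: `id`, `length`, `longest_orf_aa`, `fickett`,
#'   `hexamer_llr`, `verdict`, `lncrna`, `exclusion_reason` (`NA` for
#'   candidates).
#' @export
call_lncrna <- function(seqs, hex_table, homology_flags = NULL,
                        thresholds = iso_thresholds()) {
  ids <- names(seqs) %||% as.character(seq_along(seqs))
  len <- nchar(seqs)
  hom <- rep(FALSE, length(seqs))
  if (!is.null(homology_flags)) {
    hom <- unname(homology_flags[ids])
    hom[is.na(hom)] <- FALSE
  }
  longest_orf <- vapply(seqs, function(s) {
    o <- find_orfs(s, min_aa = 1L)
    if (nrow(o) == 0) 0L else as.integer(max(o$aa_length))
  }, integer(1))
  cp <- coding_potential(setNames(seqs, ids), hex_table, thresholds)
  reason <- rep(NA_character_, length(seqs))
  reason[cp$verdict == "coding"] <- "coding_potential"
  reason[longest_orf >= thresholds$min_orf_aa] <- "orf"
  reason[hom] <- "homology"
  reason[len < thresholds$min_lncrna_len] <- "length"
  tibble(id = ids, length = unname(len), longest_orf_aa = unname(longest_orf),
         fickett = cp$fickett, hexamer_llr = cp$hexamer_llr,
         verdict = cp$verdict, lncrna = is.na(reason),
         exclusion_reason = reason)
}
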