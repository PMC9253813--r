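#' Read spliced long-read alignments from SAM/BAM
#'
#' Loads GMAP/minimap2-style spliced alignments into a tidy table, one row per
#' alignment record. Reference-consuming CIGAR runs (`M`, `=`, `X`, `D`) are
#' merged into exonic blocks; `N` opens a new block. Identity is computed from
#' the `NM` tag as matches over aligned columns (insertions and deletions
#' count as mismatches); records without `NM` get `NA` identity. Unmapped
#' records are kept (they feed the unmapped-read analysis), flagged with
#' `mapped = FALSE`.
#'
#' @param path SAM or BAM file. SAM input is converted in a temporary
#'   directory via [Rsamtools::asBam()].
#' @return tibble with columns `read_id`, `flag`, `mapped`, `chrom`, `strand`,
#'   `blocks` (list column of `start`/`end` matrices, 0-based half-open),
#'   `span_start`, `span_end`, `n_blocks`, `read_length`,
#'   `aligned_read_span`, `identity`, `secondary`, `supplementary`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) abort(paste0("alignment file not found: ", path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(Rsamtools::asBam(path, destination = dest,
                                             overwrite = TRUE,
                                             indexDestination = FALSE))
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "cigar"),
    tag = "NM")
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(res$qname)
  if (n == 0) {
    warn("alignment file contains no records")
    return(empty_alignments())
  }
  flag <- res$flag
  mapped <- bitwAnd(flag, 4L) == 0L
  nm <- res$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, n)

  parsed <- parse_cigar_blocks(res$cigar, res$pos, mapped)
  identity <- ifelse(is.na(nm) | parsed$aligned_cols == 0, NA_real_,
                     1 - nm / parsed$aligned_cols)
  tibble(
    read_id = res$qname,
    flag = flag,
    mapped = mapped,
    chrom = ifelse(mapped, as.character(res$rname), NA_character_),
    strand = ifelse(mapped, as.character(res$strand), NA_character_),
    blocks = parsed$blocks,
    span_start = parsed$span_start,
    span_end = parsed$span_end,
    n_blocks = parsed$n_blocks,
    read_length = parsed$read_length,
    aligned_read_span = parsed$aligned_read_span,
    identity = identity,
    secondary = bitwAnd(flag, 256L) != 0L,
    supplementary = bitwAnd(flag, 2048L) != 0L
  )
}

empty_alignments <- function() {
  tibble(read_id = character(), flag = integer(), mapped = logical(),
         chrom = character(), strand = character(), blocks = list(),
         span_start = integer(), span_end = integer(), n_blocks = integer(),
         read_length = integer(), aligned_read_span = double(),
         identity = double(), secondary = logical(), supplementary = logical())
}

# Walk CIGAR strings into genomic blocks. pos is 1-based (SAM); internal
# blocks come out 0-based half-open.
parse_cigar_blocks <- function(cigar, pos, mapped) {
  n <- length(cigar)
  blocks <- vector("list", n)
  span_start <- span_end <- n_blocks <- read_length <- rep(NA_integer_, n)
  aligned_read <- aligned_cols <- rep(NA_real_, n)
  lens_all <- stringr::str_extract_all(cigar, "\\d+")
  ops_all <- stringr::str_extract_all(cigar, "[MIDNSHP=X]")
  for (i in seq_len(n)) {
    if (!mapped[i] || is.na(cigar[i]) || cigar[i] == "*") next
    lens <- as.integer(lens_all[[i]])
    ops <- ops_all[[i]]
    ref <- pos[i] - 1L
    bs <- integer(0); be <- integer(0)
    cur_start <- ref
    open <- FALSE
    r_len <- 0L; a_read <- 0L; a_cols <- 0L
    for (k in seq_along(ops)) {
      op <- ops[k]; L <- lens[k]
      if (op %in% c("M", "=", "X")) {
        if (!open) { cur_start <- ref; open <- TRUE }
        ref <- ref + L; r_len <- r_len + L; a_read <- a_read + L
        a_cols <- a_cols + L
      } else if (op == "D") {
        if (!open) { cur_start <- ref; open <- TRUE }
        ref <- ref + L; a_cols <- a_cols + L
      } else if (op == "N") {
        if (open) { bs <- c(bs, cur_start); be <- c(be, ref); open <- FALSE }
        ref <- ref + L
      } else if (op == "I") {
        r_len <- r_len + L; a_read <- a_read + L; a_cols <- a_cols + L
      } else if (op %in% c("S", "H")) {
        r_len <- r_len + L
      }
    }
    if (open) { bs <- c(bs, cur_start); be <- c(be, ref) }
    m <- cbind(start = bs, end = be)
    blocks[[i]] <- m
    span_start[i] <- bs[1]
    span_end[i] <- be[length(be)]
    n_blocks[i] <- length(bs)
    read_length[i] <- r_len
    aligned_read[i] <- if (r_len > 0) a_read / r_len else NA_real_
    aligned_cols[i] <- a_cols
  }
  list(blocks = blocks, span_start = span_start, span_end = span_end,
       n_blocks = n_blocks, read_length = read_length,
       aligned_read_span = aligned_read, aligned_cols = aligned_cols)
}

# Minimal SAM writer used by the simulator: records is a tibble with columns
# read_id, flag, chrom, pos0 (0-based), cigar, nm (NA allowed). Sequences are
# omitted ('*'); block structure and identity live in CIGAR + NM.
write_sam <- function(records, chrom_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                     as.integer(chrom_lengths)), con)
  opt <- ifelse(is.na(records$nm), "", sprintf("\tNM:i:%d", records$nm))
  writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*%s",
                     records$read_id, records$flag,
                     ifelse(is.na(records$chrom), "*", records$chrom),
                     ifelse(is.na(records$pos0), 0L, records$pos0 + 1L),
                     ifelse(is.na(records$chrom), 0L, 60L),
                     ifelse(is.na(records$cigar), "*", records$cigar),
                     opt), con)
  invisible(path)
}
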