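# Collapse FLNC alignments into isoforms, prune 5'-degraded redundancy, apply
# the three-way support filter, and assign isoforms to strand-specific loci.

#' Extract the splice chain of one alignment
#'
#' The splice chain of a spliced alignment is the ordered list of its
#' junctions (the gaps between consecutive exonic blocks, genomic
#' coordinates), plus the strand-oriented transcript ends: `tss` is the 5'
#' genomic end (block start on `+`, block end on `-`) and `tes` the 3' end.
#'
#' @param blocks two-column `start`/`end` matrix of exonic blocks (0-based
#'   half-open, sorted).
#' @param strand `"+"` or `"-"`.
#' @return list with `junctions` (matrix, possibly 0-row), `tss`, `tes`.
#' @export
#' @examples
#' build_splice_chain(cbind(start = c(100, 300), end = c(200, 400)), "+")
build_splice_chain <- function(blocks, strand) {
  stopifnot(nrow(blocks) >= 1, strand %in% c("+", "-"))
  j <- blocks_to_junctions(blocks)
  if (strand == "+") {
    list(junctions = j, tss = blocks[1, 1], tes = blocks[nrow(blocks), 2])
  } else {
    list(junctions = j, tss = blocks[nrow(blocks), 2], tes = blocks[1, 1])
  }
}

#' Collapse reads into isoforms by splice-chain identity
#'
#' Multi-exon reads sharing the same junction chain (every donor and acceptor
#' within `junction_tolerance`, default 0 = identical) collapse into one
#' isoform. Single-exon reads, which have no junctions to compare, collapse
#' when their spans overlap reciprocally by at least
#' `single_exon_overlap_frac` on the same strand. The isoform's TSS is the
#' 5'-most supporting end; its TES is the modal supporting 3' end (ties going
#' downstream). Only primary alignments of non-split reads should be passed
#' in; `run_pipeline()` handles that routing.
#'
#' @param alignments tibble from [read_alignments()] (mapped records).
#' @param thresholds [iso_thresholds()].
#' @return tibble with one row per isoform: `isoform_id`, `chrom`, `strand`,
#'   `start`, `end`, `tss`, `tes`, `n_junctions`, `junctions` (list column),
#'   `single_exon`, `support_reads` (list column), `n_support`,
#'   `max_identity`.
#' @export
collapse_isoforms <- function(alignments, thresholds = iso_thresholds()) {
  aln <- alignments |>
    filter(.data$mapped, !.data$secondary, !.data$supplementary)
  if (nrow(aln) == 0) return(empty_isoforms())
  tol <- thresholds$junction_tolerance

  chains <- map2(aln$blocks, aln$strand, build_splice_chain)
  aln <- aln |>
    mutate(n_junctions = vapply(chains, function(c) nrow(c$junctions), integer(1)),
           tss = vapply(chains, function(c) c$tss, numeric(1)),
           tes = vapply(chains, function(c) c$tes, numeric(1)),
           junctions = map(chains, "junctions"))

  multi <- aln |> filter(.data$n_junctions > 0)
  single <- aln |> filter(.data$n_junctions == 0)

  groups <- list()
  if (nrow(multi) > 0) {
    if (tol == 0) {
      key <- pmap_chr3(multi$chrom, multi$strand, multi$junctions, chain_key)
      groups <- c(groups, split(seq_len(nrow(multi)), key))
    } else {
      lab <- tolerant_chain_groups(multi, tol)
      groups <- c(groups, split(seq_len(nrow(multi)), lab))
    }
    groups <- lapply(groups, function(ix) list(rows = multi[ix, ], single = FALSE))
  }
  if (nrow(single) > 0) {
    lab <- single_exon_groups(single, thresholds$single_exon_overlap_frac)
    sg <- lapply(split(seq_len(nrow(single)), lab),
                 function(ix) list(rows = single[ix, ], single = TRUE))
    groups <- c(groups, sg)
  }

  iso <- map(groups, function(g) {
    r <- g$rows
    strand <- r$strand[1]
    tes_tab <- table(r$tes)
    modal <- as.numeric(names(tes_tab)[tes_tab == max(tes_tab)])
    tes <- if (strand == "+") max(modal) else min(modal)
    tibble(
      chrom = r$chrom[1],
      strand = strand,
      start = min(r$span_start),
      end = max(r$span_end),
      tss = if (strand == "+") min(r$tss) else max(r$tss),
      tes = tes,
      n_junctions = r$n_junctions[1],
      junctions = list(r$junctions[[which.max(r$n_junctions)]]),
      single_exon = g$single,
      support_reads = list(sort(r$read_id)),
      n_support = nrow(r),
      max_identity = suppressWarnings(max(r$identity, na.rm = TRUE))
    )
  }) |> bind_rows()
  iso$max_identity[!is.finite(iso$max_identity)] <- NA_real_
  iso <- iso |>
    mutate(.key = pmap_chr3(.data$chrom, .data$strand, .data$junctions, chain_key)) |>
    arrange(.data$chrom, .data$start, .data$strand, .data$.key, .data$end) |>
    select(-".key")
  iso |>
    mutate(isoform_id = make_ids("ISO", nrow(iso)), .before = 1)
}

pmap_chr3 <- function(a, b, c, f) {
  vapply(seq_along(a), function(i) f(a[[i]], b[[i]], c[[i]]), character(1))
}

empty_isoforms <- function() {
  tibble(isoform_id = character(), chrom = character(), strand = character(),
         start = numeric(), end = numeric(), tss = numeric(), tes = numeric(),
         n_junctions = integer(), junctions = list(), single_exon = logical(),
         support_reads = list(), n_support = integer(), max_identity = numeric())
}

# group multi-exon reads whose chains match junction-for-junction within tol;
# greedy positional pairing (chains must have equal junction counts)
tolerant_chain_groups <- function(multi, tol) {
  n <- nrow(multi)
  grp_key <- paste(multi$chrom, multi$strand, multi$n_junctions)
  from <- integer(0); to <- integer(0)
  for (ix in split(seq_len(n), grp_key)) {
    if (length(ix) < 2) next
    for (a in seq_along(ix)[-length(ix)]) {
      for (b in seq(a + 1, length(ix))) {
        ja <- multi$junctions[[ix[a]]]; jb <- multi$junctions[[ix[b]]]
        if (all(abs(ja - jb) <= tol)) {
          from <- c(from, ix[a]); to <- c(to, ix[b])
        }
      }
    }
  }
  components_from_edges(n, from, to)
}

# reciprocal-overlap grouping of single-exon reads
single_exon_groups <- function(single, frac) {
  n <- nrow(single)
  lab <- rep(NA_integer_, n)
  off <- 0L
  for (ix in split(seq_len(n), paste(single$chrom, single$strand))) {
    s <- single$span_start[ix]; e <- single$span_end[ix]
    prs <- pairs_overlapping(s, e)
    keep <- logical(nrow(prs))
    for (k in seq_len(nrow(prs))) {
      i <- prs[k, 1]; j <- prs[k, 2]
      ov <- overlap_len(s[i], e[i], s[j], e[j])
      keep[k] <- ov >= frac * (e[i] - s[i]) && ov >= frac * (e[j] - s[j])
    }
    comp <- components_from_edges(length(ix), prs[keep, 1], prs[keep, 2])
    lab[ix] <- comp + off
    off <- off + length(ix)
  }
  lab
}

#' Remove 5'-degraded redundant isoforms
#'
#' An isoform X is a 5'-degradation artifact of Y when X's entire junction
#' chain is a suffix (in 5'-to-3' transcript order) of Y's longer chain on the
#' same chromosome and strand, and X's 5' end lies inside Y's span. Such X are
#' removed and their supporting reads credited to Y. The rule compares splice
#' sites, so it applies only to spliced (multi-exon) fragments.
#'
#' @param isoforms tibble from [collapse_isoforms()].
#' @return pruned isoform tibble; absorbed support is merged into the
#'   retaining isoform.
#' @export
prune_5prime_degraded <- function(isoforms) {
  if (nrow(isoforms) == 0) return(isoforms)
  iso <- isoforms
  # transcript-order junction string per isoform
  tx_chain <- function(i) {
    j <- iso$junctions[[i]]
    if (nrow(j) == 0) return(character(0))
    keys <- paste0(j[, 1], "-", j[, 2])
    if (iso$strand[i] == "-") rev(keys) else keys
  }
  chains <- lapply(seq_len(nrow(iso)), tx_chain)
  # index every proper suffix of every chain
  suffix_index <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(iso))) {
    ch <- chains[[i]]
    k <- length(ch)
    if (k < 2) next
    for (s in 2:k) {
      key <- paste(iso$chrom[i], iso$strand[i],
                   paste(ch[s:k], collapse = ","), sep = "|")
      suffix_index[[key]] <- c(get0(key, envir = suffix_index,
                                    ifnotfound = NULL), i)
    }
  }
  absorbed_by <- rep(NA_integer_, nrow(iso))
  for (i in seq_len(nrow(iso))) {
    ch <- chains[[i]]
    if (length(ch) < 1) next
    key <- paste(iso$chrom[i], iso$strand[i], paste(ch, collapse = ","),
                 sep = "|")
    cand <- get0(key, envir = suffix_index, ifnotfound = NULL)
    cand <- cand[!is.na(cand) & cand != i]
    if (length(cand) == 0) next
    # X's 5' end must lie within Y's span
    inside <- iso$tss[i] >= iso$start[cand] & iso$tss[i] < iso$end[cand]
    cand <- cand[inside]
    if (length(cand) == 0) next
    ord <- order(-lengths(chains)[cand], iso$start[cand],
                 iso$isoform_id[cand])
    absorbed_by[i] <- cand[ord[1]]
  }
  # follow absorption chains (Y itself may be absorbed by a longer Z)
  resolve <- function(i) {
    seen <- integer(0)
    while (!is.na(absorbed_by[i]) && !(i %in% seen)) {
      seen <- c(seen, i)
      i <- absorbed_by[i]
    }
    i
  }
  drop <- which(!is.na(absorbed_by))
  if (length(drop) == 0) return(iso)
  for (i in drop) {
    y <- resolve(i)
    iso$support_reads[[y]] <- sort(unique(c(iso$support_reads[[y]],
                                            iso$support_reads[[i]])))
    iso$n_support[y] <- length(iso$support_reads[[y]])
    iso$max_identity[y] <- max(iso$max_identity[y], iso$max_identity[i],
                               na.rm = TRUE)
  }
  iso[-drop, ]
}

#' Apply the three-way isoform support filter
#'
#' An isoform is retained when any of three evidence clauses holds: at least
#' `min_support_reads` supporting FLNC reads; a single supporting read whose
#' identity exceeds `min_single_read_identity`; or every junction present in
#' the short-read (Illumina) junction set or the reference annotation. The
#' junction clause requires at least one junction - junction evidence cannot
#' vouch for a single-exon isoform.
#'
#' @param isoforms tibble from [prune_5prime_degraded()].
#' @param illumina_junctions optional tibble with columns `chrom`, `strand`,
#'   `start`, `end` and optionally `count` (short-read support per junction);
#'   junctions with `count < min_sj_cov` are ignored.
#' @param annotation optional annotation tibble ([read_annotation()]).
#' @param thresholds [iso_thresholds()].
#' @return retained isoforms; the discarded rows with their filter reason are
#'   attached as `attr(, "discarded")`.
#' @export
filter_supported <- function(isoforms, illumina_junctions = NULL,
                             annotation = NULL,
                             thresholds = iso_thresholds()) {
  if (nrow(isoforms) == 0) {
    attr(isoforms, "discarded") <- tibble(isoform_id = character(),
                                          filter_reason = character())
    return(isoforms)
  }
  keys <- character(0)
  if (!is.null(illumina_junctions) && nrow(illumina_junctions) > 0) {
    sj <- illumina_junctions
    if (!is.null(sj$count)) sj <- sj[sj$count >= thresholds$min_sj_cov, ]
    keys <- c(keys, paste(sj$chrom, sj$strand, paste0(sj$start, "-", sj$end),
                          sep = "|"))
  }
  if (!is.null(annotation) && nrow(annotation) > 0) {
    keys <- c(keys, annotation_junction_keys(annotation))
  }
  keys <- unique(keys)

  junctions_supported <- vapply(seq_len(nrow(isoforms)), function(i) {
    j <- isoforms$junctions[[i]]
    if (nrow(j) == 0) return(FALSE)
    all(paste(isoforms$chrom[i], isoforms$strand[i],
              paste0(j[, 1], "-", j[, 2]), sep = "|") %in% keys)
  }, logical(1))

  by_reads <- isoforms$n_support >= thresholds$min_support_reads
  by_identity <- !is.na(isoforms$max_identity) &
    isoforms$max_identity > thresholds$min_single_read_identity
  retained <- by_reads | by_identity | junctions_supported

  out <- isoforms[retained, ]
  attr(out, "discarded") <- tibble(
    isoform_id = isoforms$isoform_id[!retained],
    filter_reason = "insufficient_support")
  out
}

#' Assign isoforms to gene loci
#'
#' Builds a graph connecting isoforms on the same chromosome and strand whose
#' spans overlap by at least `min_locus_overlap_frac` of the shorter span
#' (inclusive), then takes connected components as loci, so locus membership
#' is transitive. Locus ids are assigned deterministically by leftmost
#' coordinate.
#'
#' @param isoforms retained isoform tibble.
#' @param thresholds [iso_thresholds()].
#' @return the input with a `locus_id` column added.
#' @export
assign_loci <- function(isoforms, thresholds = iso_thresholds()) {
  if (nrow(isoforms) == 0) return(mutate(isoforms, locus_id = character(0)))
  frac <- thresholds$min_locus_overlap_frac
  n <- nrow(isoforms)
  comp <- rep(NA_integer_, n)
  off <- 0L
  for (ix in split(seq_len(n), paste(isoforms$chrom, isoforms$strand))) {
    s <- isoforms$start[ix]; e <- isoforms$end[ix]
    prs <- pairs_overlapping(s, e)
    keep <- logical(nrow(prs))
    for (k in seq_len(nrow(prs))) {
      i <- prs[k, 1]; j <- prs[k, 2]
      ov <- overlap_len(s[i], e[i], s[j], e[j])
      keep[k] <- ov >= frac * min(e[i] - s[i], e[j] - s[j])
    }
    comp[ix] <- components_from_edges(length(ix), prs[keep, 1], prs[keep, 2]) + off
    off <- off + length(ix)
  }
  # order loci by leftmost member coordinate
  lstart <- tapply(isoforms$start, comp, min)
  lchrom <- tapply(isoforms$chrom, comp, function(x) x[1])
  lstrand <- tapply(isoforms$strand, comp, function(x) x[1])
  ord <- order(lchrom, lstart, lstrand)
  rank <- match(as.character(comp), names(lstart)[ord])
  isoforms |>
    mutate(locus_id = sprintf("LOC%06d", rank))
}

#' Summarise loci
#'
#' @param isoforms tibble with `locus_id` (from [assign_loci()]).
#' @return one row per locus: span, strand, member isoforms.
#' @export
loci_table <- function(isoforms) {
  isoforms |>
    group_by(.data$locus_id) |>
    summarise(chrom = first(.data$chrom), strand = first(.data$strand),
              start = min(.data$start), end = max(.data$end),
              n_isoforms = n(),
              isoform_ids = list(sort(.data$isoform_id)),
              .groups = "drop") |>
    arrange(.data$locus_id)
}
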